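test_that("generators are deterministic and respect intensity bounds", {
  spec <- stimulus_spec(kind = "crossing_bars", n_frames = 40L)
  a <- crossing_bars(spec, mt_params())
  b <- crossing_bars(spec, mt_params())
  expect_identical(a, b)
  expect_gte(min(a$frames$frames), 0)
  expect_lte(max(a$frames$frames), 1)
})

test_that("zero contrast produces constant background frames", {
  spec <- stimulus_spec(kind = "crossing_bars", contrasts = c(0, 0),
                        n_frames = 10L)
  st <- crossing_bars(spec, mt_params())
  expect_true(all(st$frames$frames == 0))
})

test_that("bar centroids translate at the specified speed", {
  p <- mt_params()
  spec <- stimulus_spec(kind = "crossing_bars", speed = 2, n_frames = 80L,
                        fade_in = 0)
  st <- crossing_bars(spec, p)
  cen_x <- function(m) mean(col(m)[m])
  drift <- cen_x(st$gt$on_bar1[, , 80]) - cen_x(st$gt$on_bar1[, , 1])
  expected <- 79 * spec$speed * p$dt / p$deg_per_pixel   # pixels
  expect_equal(drift, expected, tolerance = 0.15)
  # bar 2 moves the opposite way
  drift2 <- cen_x(st$gt$on_bar2[, , 80]) - cen_x(st$gt$on_bar2[, , 1])
  expect_equal(drift2, -expected, tolerance = 0.15)
})

test_that("ground-truth masks are consistent", {
  st <- default_bars()
  T <- dim(st$frames$frames)[3]
  for (t in c(1L, T %/% 2L, T)) {
    expect_false(any(st$gt$intrinsic[, , t] & st$gt$extrinsic[, , t]))
    # mid-edge points lie on a bar
    expect_true(all(st$gt$mid_edge[, , t] <=
                      (st$gt$on_bar1[, , t] | st$gt$on_bar2[, , t])))
  }
  expect_identical(st$gt$true_dir, c(1L, 5L))  # right, left
})

test_that("occluded plaid hides every intrinsic terminator", {
  pl <- default_plaid()
  expect_false(any(pl$gt$intrinsic))
  # occluded region is painted background
  T <- dim(pl$frames$frames)[3]
  for (t in c(1L, T)) {
    fr <- pl$frames$frames[, , t]
    expect_true(all(fr[pl$gt$occluder] == 0))
  }
  # frames identical to the unoccluded stimulus inside the aperture
  spec <- stimulus_spec(kind = "crossing_bars")
  open <- crossing_bars(spec, mt_params())
  inside <- !pl$gt$occluder
  expect_equal(pl$frames$frames[, , 50][inside],
               open$frames$frames[, , 50][inside], tolerance = 1e-12)
})

test_that("an undersized occluder raises a geometry error", {
  spec <- stimulus_spec(kind = "occluded_plaid", occluder_radius = 6)
  expect_error(occluded_plaid(spec, mt_params()), "occluder")
})

test_that("bars leaving the frame raise a geometry error naming the frame", {
  spec <- stimulus_spec(kind = "crossing_bars", speed = 40, n_frames = 100L)
  expect_error(crossing_bars(spec, mt_params()), "frame [0-9]+")
})

test_that("a stationary bar is constant and has two terminator clusters", {
  spec <- stimulus_spec(kind = "single_bar", orientations = 135,
                        directions = 0, speed = 0, n_frames = 10L,
                        fade_in = 0)
  st <- single_bar(spec, mt_params())
  expect_identical(st$frames$frames[, , 1], st$frames$frames[, , 10])
  # two connected terminator components: count via flood fill on the mask
  m <- st$gt$intrinsic[, , 5]
  lab <- matrix(0L, nrow(m), ncol(m)); nl <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && lab[i, j] == 0L) {
      nl <- nl + 1L
      queue <- list(c(i, j)); lab[i, j] <- nl
      while (length(queue) > 0) {
        q <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- q[1] + di; jj <- q[2] + dj
          if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
              m[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nl
            queue <- c(queue, list(c(ii, jj)))
          }
        }
      }
    }
  }
  expect_identical(nl, 2L)
})

test_that("a grating drifts rigidly with the stated period", {
  p <- mt_params()
  # one temporal period = 1/(f * speed) time units; choose speed so that it
  # is an integer number of frames: 25 frames at dt = 0.01
  speed <- 1 / (p$f * 25 * p$dt)
  spec <- stimulus_spec(kind = "grating", grating_direction = 0,
                        grating_speed = speed, n_frames = 30L)
  fs <- grating(spec, p)
  expect_equal(fs$frames[, , 26], fs$frames[, , 1], tolerance = 1e-9)
  expect_gte(min(fs$frames), 0)
  expect_lte(max(fs$frames), 1)
})
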