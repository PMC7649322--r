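make_trace <- function(v_mt, p = mt_params()) {
  structure(list(v_mt = v_mt, dt = p$dt,
                 ms_per_time_unit = p$ms_per_time_unit,
                 mode = "component", params = p, format_version = 1L),
            class = "simulation_trace")
}

static_bar_gt <- function() {
  spec <- stimulus_spec(kind = "single_bar", orientations = 135,
                        directions = 0, speed = 0, n_frames = 6L,
                        size = 32L, bar_length = 5, fade_in = 0)
  single_bar(spec, mt_params())$gt
}

test_that("decoding picks the dominant channel with documented tie rule", {
  z <- array(0, c(8, 8, 8))
  d <- decode_directions(z)
  expect_true(all(d$label == 0L))
  one <- z; one[3, 3, 4] <- 0.8
  d1 <- decode_directions(one)
  expect_identical(d1$label[3, 3], 4L)
  expect_equal(d1$margin[3, 3], 0.8)
  # tie: lower channel index wins
  tie <- z; tie[3, 3, 2] <- 0.6; tie[3, 3, 7] <- 0.6
  expect_identical(decode_directions(tie)$label[3, 3], 2L)
  # at-threshold activity is "none"
  sub <- z; sub[3, 3, 1] <- 0.05
  expect_identical(decode_directions(sub)$label[3, 3], 0L)
})

test_that("decoding is equivariant under channel relabelling", {
  v <- random_activity(8, 8, 8, seed = 5)
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  d0 <- decode_directions(v)
  dp <- decode_directions(v[, , perm])
  # label k in the permuted decode corresponds to channel perm[k]
  relabel <- ifelse(dp$label == 0L, 0L, perm[dp$label])
  expect_identical(as.vector(relabel), as.vector(d0$label))
  expect_equal(dp$margin, d0$margin)
})

test_that("latency reports the first criterion crossing in milliseconds", {
  gt <- static_bar_gt()
  H <- dim(gt$on_bar1)[1]
  v <- array(0, c(H, H, 8, 6))
  for (t in 3:6) v[, , 1, t][gt$on_bar1[, , t]] <- 0.8  # correct from step 3
  rep <- time_to_disambiguation(make_trace(v), gt)
  expect_identical(rep$latency_steps, 3L)
  expect_equal(rep$latency_ms, 30)
  expect_equal(rep$trajectory[2], 0)
  expect_equal(rep$trajectory[4], 1)
  # a never-correct trace reports NA ("never")
  rep2 <- time_to_disambiguation(make_trace(array(0, c(H, H, 8, 6))), gt)
  expect_true(is.na(rep2$latency_steps))
})

test_that("latency is monotone in the criterion", {
  gt <- static_bar_gt()
  H <- dim(gt$on_bar1)[1]
  v <- array(0, c(H, H, 8, 6))
  onb <- which(gt$on_bar1[, , 1])
  # correctness grows over time: half the bar at step 2, all at step 5
  half <- onb[seq_len(length(onb) %/% 2)]
  for (t in 2:6) { s <- v[, , 1, t]; s[half] <- 0.8; v[, , 1, t] <- s }
  for (t in 5:6) { s <- v[, , 1, t]; s[onb] <- 0.8; v[, , 1, t] <- s }
  tr <- make_trace(v)
  lat <- vapply(c(0.2, 0.5, 0.95),
                function(cr) time_to_disambiguation(tr, gt, cr)$latency_steps,
                integer(1))
  expect_true(all(diff(lat) >= 0))
})

test_that("terminator-edge ratios handle uniform and degenerate maps", {
  gt <- static_bar_gt()
  H <- dim(gt$on_bar1)[1]
  uni <- array(0.4, c(H, H, 8))
  term <- gt$intrinsic[, , 1]; edge <- gt$mid_edge[, , 1]
  expect_equal(terminator_edge_ratio(uni, term, edge), 1)
  only_term <- array(0, c(H, H, 8))
  only_term[, , 1][term] <- 1
  expect_identical(terminator_edge_ratio(only_term, term, edge), Inf)
  expect_error(terminator_edge_ratio(uni, matrix(FALSE, H, H), edge), "empty")
})

test_that("plaid classification separates pattern from component motion", {
  spec <- stimulus_spec(kind = "crossing_bars", speed = 0, n_frames = 4L,
                        fade_in = 0)
  gt <- crossing_bars(spec, mt_params())$gt
  H <- dim(gt$on_bar1)[1]
  onb <- gt$on_bar1[, , 4] | gt$on_bar2[, , 4]
  up <- array(0, c(H, H, 8, 4)); up[, , 3, 4][onb] <- 0.7
  expect_identical(pattern_component_class(make_trace(up), gt)$class,
                   "pattern")
  obl <- array(0, c(H, H, 8, 4))
  obl[, , 2, 4][gt$on_bar1[, , 4]] <- 0.7
  obl[, , 4, 4][gt$on_bar2[, , 4]] <- 0.7
  expect_identical(pattern_component_class(make_trace(obl), gt)$class,
                   "component")
  mx <- array(0, c(H, H, 8, 4)); mx[, , 1, 4][onb] <- 0.7
  expect_identical(pattern_component_class(make_trace(mx), gt)$class,
                   "mixed")
})
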