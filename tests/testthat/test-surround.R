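test_that("local contrast reproduces hand-computed cases", {
  p <- mt_params()
  expect_true(all(local_contrast(matrix(0.4, 16, 16), p) == 0))
  # single bright pixel: 48 unit differences over M = 49 at that pixel
  fr <- matrix(0, 16, 16); fr[8, 8] <- 1
  expect_equal(local_contrast(fr, p)[8, 8], 48 / 49, tolerance = 1e-12)
  # unit checkerboard: 24 opposite-parity neighbours in a 7x7 window
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(local_contrast(cb, p)[8, 8], 24 / 49, tolerance = 1e-12)
})

test_that("contrast and discontinuity match brute-force double loops", {
  p <- mt_params()
  set.seed(21)
  fr <- matrix(runif(16 * 16), 16, 16)
  L <- local_contrast(fr, p)
  direct <- matrix(0, 16, 16)
  for (y in 1:16) for (x in 1:16) {
    s <- 0
    for (i in -3:3) for (j in -3:3) {
      yy <- y + i; xx <- x + j
      if (yy >= 1 && yy <= 16 && xx >= 1 && xx <= 16)
        s <- s + abs(fr[y, x] - fr[yy, xx])
    }
    direct[y, x] <- s / 49
  }
  expect_equal(L, direct, tolerance = 1e-12)

  v_cx <- random_activity(16, 16, 8, seed = 22)
  D <- motion_discontinuity(v_cx, p)
  angs <- mtsurround:::dir_angles(8) * pi / 180
  directD <- array(0, c(16, 16, 8))
  for (th in 1:8) for (y in 1:16) for (x in 1:16) {
    s <- 0
    for (i in -3:3) for (j in -3:3) {
      yy <- y + i; xx <- x + j
      if (yy >= 1 && yy <= 16 && xx >= 1 && xx <= 16)
        for (ps in 1:8)
          s <- s + (1 - cos(angs[ps] - angs[th])) * v_cx[yy, xx, ps]
    }
    directD[y, x, th] <- min(1, s / (10 * 49))
  }
  expect_equal(D, directD, tolerance = 1e-10)
})

test_that("discontinuity reproduces the analytic window cases", {
  p <- mt_params()
  z <- array(0, c(15, 15, 8))
  expect_true(all(motion_discontinuity(z, p) == 0))
  # opposite channel at 1 everywhere: (1 - cos(pi)) * 49 / 490 = 0.2
  a <- z; a[, , 5] <- 1
  expect_equal(motion_discontinuity(a, p)[8, 8, 1], 0.2, tolerance = 1e-12)
  # all channels at 1: sum over psi of (1 - cos) = 8 -> 0.8
  b <- array(1, c(15, 15, 8))
  expect_equal(motion_discontinuity(b, p)[8, 8, 1], 0.8, tolerance = 1e-12)
})

test_that("chi takes its closed-form values and honours the centre gate", {
  p <- mt_params()
  # crossover: Lambda = c_r, Delta = 0 gives exactly zero
  expect_equal(surround_modulation(0.2, 0, p = p), 0, tolerance = 1e-12)
  # facilitatory at zero contrast: 2 S(-2) - 1
  expect_equal(surround_modulation(0, 0, p = p), 2 * plogis(-2) - 1,
               tolerance = 1e-12)
  expect_equal(surround_modulation(0, 0, p = p), -0.76159416,
               tolerance = 1e-7)
  # inactive centre nullifies the field regardless of inputs
  L <- matrix(runif(25), 5, 5)
  D <- array(runif(25 * 8), c(5, 5, 8))
  v0 <- array(0, c(5, 5, 8))
  expect_true(all(surround_modulation(L, D, v0, p) == 0))
  # centres at or below T_mt count as inactive
  vt <- array(p$T_mt, c(5, 5, 8))
  expect_true(all(surround_modulation(L, D, vt, p) == 0))
})

test_that("chi is bounded and strictly increasing in contrast and discontinuity", {
  p <- mt_params()
  s <- seq(0, 1, length.out = 101)
  chiL <- surround_modulation(s, 0, p = p)
  chiD <- surround_modulation(0, s, p = p)
  expect_true(all(diff(chiL) > 0))
  expect_true(all(diff(chiD) > 0))
  grid <- expand.grid(L = seq(0, 1, by = 0.05), D = seq(0, 1, by = 0.05))
  chi <- surround_modulation(grid$L, grid$D, p = p)
  expect_true(all(chi > -1))
  expect_true(all(chi < p$k - 1))
  # monotone in each argument across the full grid
  m <- matrix(chi, 21, 21)
  expect_true(all(apply(m, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) > 0))))
})

test_that("the contrast crossover sits at c_r for any valid parameter set", {
  expect_equal(chi_crossover_contrast(mt_params()), 0.2, tolerance = 1e-9)
  p2 <- mt_params(c_r = 0.35)
  expect_equal(chi_crossover_contrast(p2), 0.35, tolerance = 1e-9)
})

test_that("sweep curves cover the sections used for reporting", {
  sw <- sweep_chi(mt_params(), n = 51L)
  expect_named(sw, c("delta_sweep", "lambda_sweep"))
  expect_identical(nrow(sw$delta_sweep), 51L)
  expect_equal(sw$lambda_sweep$chi[sw$lambda_sweep$Lambda == 0.2], 0,
               tolerance = 1e-12)
  # the discontinuity crossover with the printed constants: Delta = 1/6
  f <- approxfun(sw$delta_sweep$Delta, sw$delta_sweep$chi)
  root <- uniroot(f, c(0, 1))$root
  expect_equal(root, 1 / 6, tolerance = 1e-3)
})
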