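# Complex V1 front end: spatiotemporal motion-energy filtering in eight
# directions. Quadrature Gabor pairs are combined with a fast (order 6) and
# a slow (order 9) multi-stage low-pass temporal filter; the delay between
# the two temporal channels provides the direction selectivity, opponent
# channels are subtracted, the result half-wave rectified and read out as
# an amplitude (square root of the opponent energy). The amplitude readout
# compresses the dynamic range so that the weak but veridical motion
# signals at line terminators stay within reach of the model's activity
# thresholds instead of being squared away relative to edge responses.

#' Biphasic temporal filter weights
#'
#' Samples `g_n(t) = (t/tau)^n exp(-t/tau) * [1/n! - (t/tau)^2/(n+2)!]` at
#' `t = 0, dt, ..., t_max`. The filter is low-pass with a delayed negative
#' lobe; orders 6 and 9 give the fast and slow channels of the motion
#' detector.
#'
#' @param n filter order (the model uses 6 and 9).
#' @param tau_g time constant (time units).
#' @param dt sampling step.
#' @param t_max last sample; must be late enough that the kernel has decayed
#'   below 1e-6 of its peak magnitude.
#' @return numeric vector of weights, first element `g_n(0) = 0`.
#' @export
temporal_kernel <- function(n, tau_g, dt, t_max = 0.5) {
  stopifnot(n >= 1, tau_g > 0, dt > 0, t_max > dt)
  t <- seq(0, t_max, by = dt)
  s <- t / tau_g
  w <- s^n * exp(-s) * (1 / factorial(n) - s^2 / factorial(n + 2))
  if (abs(w[length(w)]) > 1e-6 * max(abs(w)))
    stop("t_max too small: temporal kernel has not decayed at the window end",
         call. = FALSE)
  w
}

#' Quadrature Gabor bank for the eight direction channels
#'
#' For each direction the carrier axis points along the motion the channel
#' prefers (perpendicular to the edge it responds to). Phases `even`
#' (cosine) and `odd` (sine, antisymmetric along the carrier) form a
#' quadrature pair. Channels 180 degrees apart share the even kernel and
#' have sign-flipped odd kernels.
#'
#' @param p an [mt_params()] object (`f`, `sigma_x`, `sigma_y`,
#'   `deg_per_pixel`).
#' @param radius kernel half-width in pixels; default covers 4 SDs.
#' @return a list with one element per direction, each holding `even` and
#'   `odd` weight matrices and the direction angle `theta`.
#' @export
gabor_bank <- function(p = mt_params(), radius = NULL) {
  if (is.null(radius))
    radius <- as.integer(ceiling(4 * max(p$sigma_x, p$sigma_y) /
                                   p$deg_per_pixel))
  idx <- seq(-radius, radius)
  # kernel grid in degrees; rows grow downward so dy_up = -row offset
  dx <- matrix(rep(idx * p$deg_per_pixel, each = length(idx)),
               length(idx), length(idx))
  dy <- matrix(rep(-idx * p$deg_per_pixel, times = length(idx)),
               length(idx), length(idx))
  lapply(dir_angles(p$N), function(th) {
    a <- th * pi / 180
    u <- dx * cos(a) + dy * sin(a)    # along preferred motion
    v <- -dx * sin(a) + dy * cos(a)   # along the preferred edge
    env <- exp(-(u^2 / (2 * p$sigma_x^2) + v^2 / (2 * p$sigma_y^2)))
    list(theta = th,
         even = env * cos(2 * pi * p$f * u),
         odd  = env * sin(2 * pi * p$f * u))
  })
}

# causal zero-padded temporal convolution of a T x M matrix with weights w
.tfilter <- function(X, w) {
  lw <- length(w)
  Xp <- rbind(matrix(0, lw - 1L, ncol(X)), X)
  Y <- stats::filter(Xp, w, method = "convolution", sides = 1)
  matrix(Y[lw:(lw - 1L + nrow(X)), ], nrow = nrow(X))
}

# unnormalised opponent motion energy, H x W x N x T
.opponent_energy <- function(fs, p, t_max = 0.5) {
  d <- dim(fs); H <- d[1]; W <- d[2]; T <- d[3]
  bank <- gabor_bank(p)
  gf <- temporal_kernel(p$n_fast, p$tau_g, p$dt, t_max)
  gs <- temporal_kernel(p$n_slow, p$tau_g, p$dt, t_max)
  half <- p$N %/% 2L
  out <- array(0, c(H, W, p$N, T))
  for (dch in seq_len(half)) {
    ke <- bank[[dch]]$even; ko <- bank[[dch]]$odd
    Se <- matrix(0, T, H * W); So <- matrix(0, T, H * W)
    for (t in seq_len(T)) {
      Se[t, ] <- as.vector(filter2_same(fs[, , t], ke))
      So[t, ] <- as.vector(filter2_same(fs[, , t], ko))
    }
    Ef <- .tfilter(Se, gf); Es <- .tfilter(Se, gs)
    Of <- .tfilter(So, gf); Os <- .tfilter(So, gs)
    Epos <- (Ef - Os)^2 + (Of + Es)^2   # prefers motion toward theta
    Eneg <- (Ef + Os)^2 + (Of - Es)^2   # prefers theta + 180
    opp <- Epos - Eneg
    out[, , dch, ] <- array(t(pmax(opp, 0)), c(H, W, T))
    out[, , dch + half, ] <- array(t(pmax(-opp, 0)), c(H, W, T))
  }
  out
}

# cache for the frozen normalisation constant
.cal_cache <- new.env(parent = emptyenv())

#' Motion-energy normalisation constant
#'
#' The raw opponent energy is scaled so that a full-contrast drifting
#' grating at the model's spatial frequency produces a map maximum of 1.
#' The constant is computed once per parameter set (on a rightward grating
#' at the package's default stimulus speed) and cached; it is deterministic.
#'
#' @param p an [mt_params()] object.
#' @param speed calibration drift speed (deg per time unit).
#' @return positive scalar.
#' @export
v1_calibration <- function(p = mt_params(), speed = 2) {
  key <- paste(params_hash(p), format(speed), sep = "/")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  spec <- stimulus_spec(kind = "grating", grating_direction = 0,
                        grating_speed = speed, grating_contrast = 1,
                        size = 48L, n_frames = 80L)
  fs <- grating(spec, p)$frames
  z <- max(.opponent_energy(fs, p))
  if (z <= 0) stop("calibration produced no motion energy", call. = FALSE)
  .cal_cache[[key]] <- z
  z
}

#' Complex V1 direction-selective responses
#'
#' Runs the full motion-energy cascade on a frame sequence: quadrature
#' Gabor filtering, fast/slow temporal filtering, opponent subtraction,
#' half-wave rectification, amplitude (square-root) readout and
#' normalisation to `[0, 1]`.
#'
#' By default the map is normalised to the maximum opponent energy of the
#' sequence itself, making the front end contrast-insensitive (complex V1
#' units in this model are not contrast coders; contrast enters the model
#' only through the ECRF stream and the local-contrast field). This puts
#' the strongest edge responses at 1 for any stimulus, which is the scale
#' on which the model's activity thresholds (`rho_cx`, `rho_es`) are
#' defined. Pass `calibration = v1_calibration(p)` to normalise instead by
#' the frozen full-contrast grating constant (useful when comparing
#' absolute energies across stimuli).
#'
#' @param frames a `frame_sequence` (see [stimulus_spec()] generators).
#' @param p an [mt_params()] object.
#' @param calibration positive normalisation constant, or `NULL` (default)
#'   for per-sequence normalisation.
#' @param saturation half-saturation constant of the compressive output
#'   nonlinearity `v = a (1 + s) / (a + s)` applied to the normalised
#'   amplitude `a` (Naka-Rushton form, scaled so that a = 1 maps to 1).
#'   Complex-cell responses saturate; the compression keeps weak veridical
#'   terminator signals within a factor ~2 of the strong edge responses.
#'   `Inf` disables it.
#' @param floor response floor subtracted from the normalised amplitude
#'   (and rescaled) before the compression: filter skirts below the floor
#'   are silenced rather than amplified by the saturating nonlinearity.
#' @param div_norm semi-saturation constant of the divisive surround
#'   normalisation `v / (div_norm + pool)`, where `pool` is the
#'   Gaussian-weighted mean of same-channel activity over the 17 x 17
#'   neighbourhood. Divisive normalisation is what renders the front end
#'   contrast-insensitive, and it equalises compact terminator responses
#'   (small pools) against extended edge responses (large pools), giving
#'   the veridical terminator signals the prominence the model requires.
#'   `Inf` disables it.
#' @return H x W x N x T array of activities in `[0, 1]`, with attribute
#'   `valid`, a logical H x W matrix that is `FALSE` on the border ring of
#'   half-kernel width where zero padding contaminates the response.
#' @export
complex_v1_response <- function(frames, p = mt_params(),
                                calibration = NULL, saturation = Inf,
                                floor = 0.25, div_norm = 0.05) {
  stopifnot(inherits(frames, "frame_sequence"))
  fs <- frames$frames
  raw <- .opponent_energy(fs, p)
  if (is.null(calibration)) {
    # normalise to the steady-state maximum: the first frames carry a large
    # stimulus-onset transient (the temporal filters start from an empty
    # history) that would otherwise set the scale
    T <- dim(fs)[3]
    skip <- min(T %/% 2L, 25L)
    calibration <- max(raw[, , , (skip + 1L):T])
    if (calibration <= 0) calibration <- max(raw)
    if (calibration <= 0) calibration <- 1  # blank input stays all-zero
  }
  out <- clip01(sqrt(raw / calibration))
  if (is.finite(div_norm)) {
    d <- dim(out)
    idx <- -8:8
    gk <- outer(idx, idx, function(i, j) exp(-(i^2 + j^2) / (2 * 2.5^2)))
    gk <- gk / sum(gk)
    for (t in seq_len(d[4])) for (n in seq_len(d[3])) {
      pool <- filter2_same(out[, , n, t], gk)
      out[, , n, t] <- out[, , n, t] / (div_norm + pmax(pool, 0))
    }
    T <- d[4]
    skip <- min(T %/% 2L, 25L)
    z <- max(out[, , , (skip + 1L):T])
    if (z > 0) out <- out / z
    out <- clip01(out)
  }
  if (floor > 0) out <- pmax(out - floor, 0) / (1 - floor)
  if (is.finite(saturation))
    out <- out * (1 + saturation) / (out + saturation)
  # confine responses to image regions with local contrast: the units'
  # receptive fields are small (1 deg centres), so activity several pixels
  # away from any luminance structure is filter-skirt spread, not signal;
  # without this support gate such skirt pixels sit in the low-contrast
  # facilitatory-surround zone and self-ignite the MT sheet
  for (t in seq_len(dim(out)[4])) {
    support <- local_contrast(fs[, , t], p) >= p$c_r
    out[, , , t] <- out[, , , t] * as.vector(support)
  }
  # flush numerical residue (FFT noise, filter skirts): background units
  # must be exactly silent or the centre-gated surround self-excites them
  out[out < 1e-6] <- 0
  radius <- as.integer(ceiling(4 * max(p$sigma_x, p$sigma_y) /
                                 p$deg_per_pixel))
  H <- dim(fs)[1]; W <- dim(fs)[2]
  valid <- matrix(FALSE, H, W)
  if (H > 2 * radius && W > 2 * radius)
    valid[(radius + 1):(H - radius), (radius + 1):(W - radius)] <- TRUE
  attr(out, "valid") <- valid
  out
}
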