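# Adaptive surround modulation of MT neurons: the modulation field chi is a
# saturating sigmoidal function of local image contrast (Lambda), motion
# discontinuity (Delta) and a coherency term (alpha * beta). Positive chi
# suppresses the centre (antagonistic surround), negative chi facilitates
# it (integrative surround); the switch sits at the contrast threshold c_r.

#' Local contrast field
#'
#' `Lambda(x, y) = sum_{7x7 window} |I(x, y) - I(x+i, y+j)| / M` with
#' `M = 49`: the mean absolute intensity difference between a pixel and its
#' surround. Out-of-frame neighbours are treated as having the centre's
#' intensity (they contribute zero).
#'
#' @param frame H x W intensity matrix in `[0, 1]`.
#' @param p an [mt_params()] object.
#' @return H x W contrast map in `[0, 1)`.
#' @export
local_contrast <- function(frame, p = mt_params()) {
  r <- 3L  # M = 49 = (2r+1)^2
  H <- nrow(frame); W <- ncol(frame)
  acc <- matrix(0, H, W)
  for (i in -r:r) for (j in -r:r) {
    if (i == 0L && j == 0L) next
    # shifted copy; out-of-frame entries take the centre value -> |diff| = 0
    sh <- frame
    src_r <- intersect(seq_len(H), seq_len(H) + i)
    src_c <- intersect(seq_len(W), seq_len(W) + j)
    sh[src_r - i, src_c - j] <- frame[src_r, src_c]
    acc <- acc + abs(frame - sh)
  }
  acc / p$M
}

#' Motion-discontinuity field
#'
#' `Delta(x, y, theta) = sum_{7x7} sum_psi (1 - cos(psi - theta)) *
#' v_cx(x+i, y+j, psi) / (10 M)`, clipped to `[0, 1]`: a direction-weighted
#' census of complex V1 activity in the surround, large where neighbours
#' signal motion away from the channel's preferred direction.
#'
#' @param v_cx H x W x N complex V1 activity (one step).
#' @param p an [mt_params()] object.
#' @return H x W x N discontinuity map in `[0, 1]`.
#' @export
motion_discontinuity <- function(v_cx, p = mt_params()) {
  r <- 3L
  win <- box_sum_channels(v_cx, r)         # window sums per channel
  angs <- dir_angles(p$N) * pi / 180
  Wmat <- 1 - cos(outer(angs, angs, "-"))  # weight[theta, psi]
  d <- dim(v_cx)
  flat <- matrix(win, nrow = d[1] * d[2], ncol = d[3])
  out <- flat %*% t(Wmat) / (10 * p$M)
  clip01(array(out, d))
}

#' Surround modulation field chi
#'
#' `chi = k * S(a * (k (Lambda - c_r) - 1 + b Delta + alpha * beta)) - 1`
#' with the logistic `S(t) = 1 / (1 + exp(-t))`, `alpha = 1 - (Lambda -
#' c_r)` (coherency from contrast) and `beta = 1 - Delta` (coherency from
#' motion). The sign convention makes chi increase with both contrast and
#' discontinuity: with `Delta = 0` the inner term reduces to
#' `Lambda - c_r`, so the surround switches from facilitatory (chi < 0) to
#' antagonistic (chi > 0) exactly at `Lambda = c_r`. `k = 2` bounds chi in
#' `(-1, 1)`. The field is gated by the centre: wherever the centre MT unit
#' is inactive chi is 0.
#'
#' @param Lambda H x W contrast map (or scalar/vector for sweeps).
#' @param Delta H x W x N discontinuity map (or conformable numeric).
#' @param v_mt centre MT activity, same shape as `Delta`; `NULL` treats the
#'   centre as active everywhere (used for analytic sweeps). A centre
#'   counts as active when its activity exceeds the MT activity threshold
#'   `T_mt`: below it the surround is silent, so numerically negligible
#'   activity cannot bootstrap itself through background facilitation.
#' @param p an [mt_params()] object.
#' @return chi with the shape of `Delta`, values in `(-1, k - 1)`.
#' @export
surround_modulation <- function(Lambda, Delta, v_mt = NULL, p = mt_params()) {
  # broadcast the H x W contrast map across the N direction channels
  if (is.matrix(Lambda) && length(dim(Delta)) == 3L &&
      all(dim(Lambda) == dim(Delta)[1:2]))
    Lambda <- array(rep(Lambda, dim(Delta)[3L]), dim(Delta))
  alpha <- 1 - (Lambda - p$c_r)
  beta <- 1 - Delta
  inner <- p$k * (Lambda - p$c_r) - 1 + p$b * Delta + alpha * beta
  chi <- p$k * stats::plogis(abs(p$a) * inner) - 1
  if (!is.null(v_mt)) chi <- chi * (v_mt > p$T_mt)
  chi
}

#' Surround sweep curves
#'
#' One-dimensional sections through the modulation surface with an active
#' centre: `chi(Delta)` at `Lambda = 0` and `chi(Lambda)` at `Delta = 0`.
#'
#' @param p an [mt_params()] object.
#' @param n number of sample points.
#' @return list of two data frames, `delta_sweep` with columns
#'   `(Delta, chi)` and `lambda_sweep` with columns `(Lambda, chi)`.
#' @export
sweep_chi <- function(p = mt_params(), n = 201L) {
  s <- seq(0, 1, length.out = n)
  list(
    delta_sweep = data.frame(Delta = s,
                             chi = surround_modulation(0, s, p = p)),
    lambda_sweep = data.frame(Lambda = s,
                              chi = surround_modulation(s, 0, p = p)))
}

#' Contrast at which the surround changes sign
#'
#' Root of `chi(Lambda) = 0` at `Delta = 0` with an active centre, found
#' numerically; analytically this equals `c_r`.
#'
#' @param p an [mt_params()] object.
#' @param tol root-finding tolerance.
#' @return the crossover contrast.
#' @export
chi_crossover_contrast <- function(p = mt_params(), tol = 1e-12) {
  stats::uniroot(function(L) surround_modulation(L, 0, p = p),
                 interval = c(0, 1), tol = tol)$root
}
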