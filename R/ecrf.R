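# ECRF V1 units: luminance-sensitive, orientation-selective form responses
# with suppressive surrounds, modelled as oriented difference-of-Gaussians.
# Their responses are strong at a bar's own end-points (intrinsic
# terminators) and suppressed at occlusion junctions (extrinsic
# terminators), which lets them gate motion signals by form.

#' Oriented difference-of-Gaussians kernel
#'
#' `R(x, y) = A_c exp(-(x_o^2/s_xc^2 + y_o^2/s_yc^2)) -
#'  A_s exp(-(x_o^2/s_xs^2 + y_o^2/s_ys^2))` with `(x_o, y_o)` the pixel
#' coordinates rotated by the orientation. The squared SDs appear directly
#' in the denominators (no factor 2), matching the model's definition.
#'
#' @param o orientation in degrees (0 = horizontal preferred edge).
#' @param p an [mt_params()] object.
#' @param radius kernel half-width in pixels; default covers the surround
#'   to below 1e-6 of the peak.
#' @return square weight matrix with odd dimensions.
#' @export
dog_kernel <- function(o, p = mt_params(), radius = NULL) {
  if (is.null(radius)) {
    smax <- max(p$sigma_xs, p$sigma_ys)
    radius <- as.integer(ceiling(4 * smax / p$deg_per_pixel))
  }
  idx <- seq(-radius, radius)
  dx <- matrix(rep(idx * p$deg_per_pixel, each = length(idx)),
               length(idx), length(idx))
  dy <- matrix(rep(-idx * p$deg_per_pixel, times = length(idx)),
               length(idx), length(idx))
  a <- o * pi / 180
  # x_o across the preferred edge, y_o along it
  xo <- dx * cos(a) + dy * sin(a)
  yo <- -dx * sin(a) + dy * cos(a)
  p$A_c * exp(-(xo^2 / p$sigma_xc^2 + yo^2 / p$sigma_yc^2)) -
    p$A_s * exp(-(xo^2 / p$sigma_xs^2 + yo^2 / p$sigma_ys^2))
}

#' ECRF orientation channel angles
#' @param p an [mt_params()] object.
#' @return numeric vector of `p$O` angles in degrees.
#' @export
ecrf_orientations <- function(p = mt_params()) (seq_len(p$O) - 1L) * (180 / p$O)

#' ECRF form responses to one frame
#'
#' Convolves the frame with the oriented DoG bank and half-wave rectifies;
#' responses below 1e-9 are flushed to zero so the downstream strict-zero
#' gate is not opened by rounding noise.
#'
#' @param frame H x W intensity matrix in `[0, 1]`.
#' @param p an [mt_params()] object.
#' @return H x W x O non-negative array with attribute `valid` marking the
#'   border ring contaminated by zero padding.
#' @export
ecrf_response <- function(frame, p = mt_params()) {
  angs <- ecrf_orientations(p)
  H <- nrow(frame); W <- ncol(frame)
  ks <- lapply(angs, dog_kernel, p = p)
  out <- array(0, c(H, W, p$O))
  for (i in seq_along(ks)) out[, , i] <- pmax(filter2_same(frame, ks[[i]]), 0)
  out[out < 1e-9] <- 0
  radius <- (nrow(ks[[1]]) - 1L) %/% 2L
  valid <- matrix(FALSE, H, W)
  if (H > 2 * radius && W > 2 * radius)
    valid[(radius + 1):(H - radius), (radius + 1):(W - radius)] <- TRUE
  attr(out, "valid") <- valid
  out
}

#' Gate motion signals by form activity
#'
#' `kappa(x, y, theta) = v_cx(x, y, theta)` wherever the summed ECRF
#' response over orientations is high, 0 elsewhere. This is the
#' form-motion interaction drive to MT, whose role is to strengthen the
#' influence of intrinsic terminators relative to both extrinsic
#' terminators and plain contour edges: oriented DoG units respond most
#' strongly at line ends (where their suppressive flanks are least
#' stimulated) and are suppressed at occlusion junctions, so gating on
#' strong form activity concentrates the drive at intrinsic terminators.
#'
#' @param v_cx H x W x N complex V1 activity (one step).
#' @param v_cs H x W x O ECRF activity for the same frame.
#' @param threshold_frac the gate opens where the summed form response
#'   exceeds this fraction of its map maximum. `0` reproduces the plain
#'   "any form activity" gate (which treats every contour point alike and
#'   abolishes terminator discrimination).
#' @return H x W x N gated field.
#' @export
gated_motion <- function(v_cx, v_cs, threshold_frac = 0.65) {
  form <- apply(v_cs, c(1, 2), sum)
  thr <- threshold_frac * max(form)
  open <- if (thr > 0) form > thr else form > 0
  v_cx * as.vector(open)   # recycles over the direction dimension
}
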