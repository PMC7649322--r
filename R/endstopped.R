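# End-stopped V1 units: shunting dynamics with thresholded Gaussian lateral
# inhibition. Extended edges recruit strong lateral inhibition from their
# like-tuned neighbours and are suppressed; contour end-points (terminators)
# survive, providing the unambiguous motion signals MT integrates.

#' Lateral inhibitory connectivity weights
#'
#' Discretized Gaussian over a 17 x 17 patch (indices -8..8), centre unit
#' excluded: a neuron is not inhibited by its own complex-cell input. The
#' wide patch is what discriminates extended contours from compact
#' terminator clusters: a unit on a long edge accumulates inhibition from
#' the whole strip of like-tuned active neighbours, while a unit in a
#' small terminator blob is inhibited only by the blob itself.
#'
#' @param radius patch radius in grid units.
#' @param sd Gaussian SD in grid units.
#' @param peak weight of the nearest neighbours (sets the overall scale of
#'   lateral inhibition; the connectivity shape is fixed, its strength is
#'   a model constant chosen so that edge responses equilibrate below the
#'   end-stopped threshold while terminator responses stay above it).
#' @return (2 radius + 1) square weight matrix with a zero centre.
#' @export
endstopped_mu <- function(radius = 8L, sd = 2.5, peak = 0.1) {
  idx <- seq(-radius, radius)
  g <- outer(idx, idx, function(i, j) exp(-(i^2 + j^2) / (2 * sd^2)))
  g[radius + 1L, radius + 1L] <- 0
  peak * g
}

#' Lateral inhibition field onto end-stopped units
#'
#' For each location and direction, sums Gaussian-weighted complex V1
#' activity over the 7 x 7 neighbourhood, where a neighbour contributes only
#' if its own activity exceeds the threshold `rho_cx`; out-of-frame
#' neighbours contribute zero.
#'
#' @param v_cx H x W x N complex V1 activity (one time step).
#' @param p an [mt_params()] object.
#' @param mu connectivity weights, default [endstopped_mu()].
#' @return H x W x N inhibition field (non-negative).
#' @export
inhibition_field <- function(v_cx, p = mt_params(), mu = endstopped_mu()) {
  gated <- v_cx * (v_cx > p$rho_cx)
  out <- v_cx
  for (n in seq_len(dim(v_cx)[3L]))
    out[, , n] <- filter2_same(gated[, , n], mu)
  pmax(out, 0)  # guard tiny FFT negatives
}

#' One Euler step of the end-stopped shunting dynamics
#'
#' `dv/dt = (1 - v) * Gescx1 * v_cx - v * (tau_es + Gescx2 * Gamma)`:
#' excitation saturates as v approaches 1 and inhibition shunts v toward 0,
#' so the continuous dynamics cannot leave `[0, 1]`. The Euler update is
#' clipped as a numerical guard.
#'
#' @param v_es H x W x N current end-stopped activity.
#' @param v_cx H x W x N complex V1 drive at this step.
#' @param Gamma inhibition field from [inhibition_field()]; computed from
#'   `v_cx` if missing.
#' @param p an [mt_params()] object.
#' @return updated H x W x N activity in `[0, 1]`.
#' @export
endstopped_step <- function(v_es, v_cx, Gamma = NULL, p = mt_params()) {
  if (is.null(Gamma)) Gamma <- inhibition_field(v_cx, p)
  dv <- (1 - v_es) * (p$Gescx1 * v_cx) -
    v_es * (p$tau_es + p$Gescx2 * Gamma)
  v_new <- v_es + p$dt * dv
  if (max(v_new) > 1.1 || min(v_new) < -0.1)
    warning("end-stopped update overshoots [0,1] by more than 0.1; ",
            "dt may be too large for stability", call. = FALSE)
  clip01(v_new)
}

#' Equilibrium of the end-stopped dynamics (closed form)
#'
#' Setting the shunting equation to zero gives
#' `v* = G1 v_cx / (G1 v_cx + tau_es + G2 Gamma)`. Used as an independent
#' check of the integrated dynamics.
#'
#' @param v_cx complex V1 drive (scalar or array).
#' @param Gamma inhibition (same shape).
#' @param p an [mt_params()] object.
#' @return equilibrium activity.
#' @export
endstopped_equilibrium <- function(v_cx, Gamma, p = mt_params()) {
  e <- p$Gescx1 * v_cx
  e / (e + p$tau_es + p$Gescx2 * Gamma)
}
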