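# Recurrent MT sheet: 8 direction channels per location, driven by the
# three V1 streams (complex, end-stopped, ECRF-gated) and modulated by the
# adaptive surround, with same-location and long-range inter-directional
# inhibition applied after a fixed delay through a ring buffer.

#' Lateral excitation between neighbouring MT neurons
#'
#' For each location and direction, the 7 x 7 window sum of same-direction
#' MT activity, passed through two gates: the neighbourhood (excluding the
#' centre's own activity) must exceed the MT threshold, and the summed ECRF
#' activity at the location must be positive (form support). Either gate
#' closed gives zero. In pattern mode the form gate is forced open so that
#' terminator signals can propagate without ECRF support.
#'
#' @param v_mt H x W x N MT activity.
#' @param v_cs H x W x O ECRF activity for the current frame, or `NULL`.
#' @param p an [mt_params()] object.
#' @param force_gate_open bypass the ECRF gate (pattern mode).
#' @return H x W x N non-negative field.
#' @export
lateral_excitation <- function(v_mt, v_cs, p = mt_params(),
                               force_gate_open = FALSE) {
  S <- box_sum_channels(v_mt, 3L)
  cond <- (S - v_mt) > p$T_mt
  if (!force_gate_open) {
    if (is.null(v_cs)) stop("v_cs required unless the gate is forced open",
                            call. = FALSE)
    open <- apply(v_cs, c(1, 2), sum) > 0
    cond <- cond & as.vector(open)
  }
  S * cond
}

#' Same-location inter-directional inhibition
#'
#' `gamma(x, y, theta) = sum_{phi != theta} v_mt(x, y, phi)`: each channel
#' is inhibited by all other channels at its own location, the substrate of
#' the winner-take-all competition.
#'
#' @param v_mt H x W x N MT activity.
#' @return H x W x N non-negative field.
#' @export
interdirectional_inhibition <- function(v_mt) {
  tot <- apply(v_mt, c(1, 2), sum)
  sweep(-v_mt, c(1, 2), tot, "+")
}

#' Long-range inter-directional inhibition
#'
#' `xi(x, y, theta) = sum_{phi != theta} mean_{|i|,|j| <= phi_extent}
#' v_mt(x+i, y+j, phi)`: activity in other direction channels anywhere in a
#' (2 phi + 1)^2 neighbourhood (13 x 13 at defaults) inhibits the centre,
#' sharpening propagating motion fronts. The spatial sum is normalised by
#' the window area, in line with the model's other windowed quantities
#' (the contrast and discontinuity fields are normalised by their window
#' size M): the unnormalised 7 x 169-term sum would be two orders of
#' magnitude larger than every other term in the rate equation and
#' extinguishes all structured activity in a delayed limit cycle.
#'
#' @param v_mt H x W x N MT activity.
#' @param p an [mt_params()] object (`phi` sets the window radius).
#' @return H x W x N non-negative field, bounded by `N - 1`.
#' @export
longrange_inhibition <- function(v_mt, p = mt_params()) {
  r <- as.integer(p$phi)
  boxed <- box_sum_channels(v_mt, r) / (2 * r + 1)^2
  tot <- apply(boxed, c(1, 2), sum)
  sweep(-boxed, c(1, 2), tot, "+")
}

#' Piecewise-linear saturation
#'
#' Identity on `[0, 1]`, clipped outside: keeps activities in range.
#' @param x numeric.
#' @return clipped values.
#' @export
h_saturation <- function(x) clip01(x)

#' Initialise the MT state
#'
#' @param H,W grid size.
#' @param p an [mt_params()] object.
#' @return an `mt_state` list: `v_mt` (H x W x N zeros) and the delay ring
#'   buffer (`T_in / dt` slots of past activity, zero before warm-up).
#' @export
mt_state_init <- function(H, W, p = mt_params()) {
  n_delay <- as.integer(round(p$T_in / p$dt))
  structure(list(
    v_mt = array(0, c(H, W, p$N)),
    buffer = vector("list", n_delay),
    buf_pos = 0L,
    n_delay = n_delay), class = "mt_state")
}

# fetch v_mt from T_in in the past (NULL -> zeros before warm-up)
.delayed_state <- function(state) {
  if (state$n_delay == 0L) return(state$v_mt)
  slot <- (state$buf_pos %% state$n_delay) + 1L
  state$buffer[[slot]]
}

#' One integration step of the MT dynamics
#'
#' Computes the drive `rhs = Gmtcx v_cx + Gmtes v_es' + Gmtmt_ex lambda +
#' Gcsmt kappa - Gmtmt_inter gamma(t - T_in) - Gmtmt3 xi(t - T_in) -
#' tau_mt v_mt - chi`, where `v_es'` is end-stopped activity rectified at
#' `rho_es`, the inhibition fields are computed from the buffered activity
#' `T_in` in the past, and `chi` is the surround field gated by the current
#' centre activity. The state update is `v <- h(v + dt * rhs)` with the
#' piecewise-linear saturation `h` (a literal reading that saturates the
#' derivative instead is available via `p$literal_h_on_derivative`).
#'
#' @param state an `mt_state`.
#' @param v_cx,v_es H x W x N complex and end-stopped V1 activity.
#' @param kappa ECRF-gated V1 drive ([gated_motion()]).
#' @param Lambda H x W local contrast for the current frame.
#' @param Delta H x W x N motion discontinuity for the current step.
#' @param v_cs H x W x O ECRF activity (lateral-excitation gate), or `NULL`
#'   with `force_gate_open = TRUE`.
#' @param p an [mt_params()] object.
#' @param Gcsmt_eff effective ECRF-drive gain (mode-dependent).
#' @param force_gate_open pattern-mode switch for the lateral gate.
#' @return list: updated `state` and the surround field `chi` applied.
#' @export
mt_step <- function(state, v_cx, v_es, kappa, Lambda, Delta, v_cs,
                    p = mt_params(), Gcsmt_eff = p$Gcsmt,
                    force_gate_open = FALSE) {
  v_mt <- state$v_mt
  v_del <- .delayed_state(state)
  if (is.null(v_del)) {
    gam <- array(0, dim(v_mt)); xi <- array(0, dim(v_mt))
  } else {
    gam <- interdirectional_inhibition(v_del)
    xi <- longrange_inhibition(v_del, p)
  }
  lam <- lateral_excitation(v_mt, v_cs, p, force_gate_open)
  chi <- surround_modulation(Lambda, Delta, v_mt, p)
  # rho_es acts as an all-or-none transmission threshold: end-stopped
  # activity above it is relayed at full strength (the stream is sparse
  # and carries only unambiguous terminator motion), below it not at all
  ves_eff <- if (isTRUE(p$apply_rho_es)) (v_es > p$rho_es) * 1 else v_es
  rhs <- p$Gmtcx * v_cx + p$Gmtes * ves_eff + p$Gmtmt_ex * lam +
    Gcsmt_eff * kappa - p$Gmtmt_inter * gam - p$Gmtmt3 * xi -
    p$tau_mt * v_mt - chi
  if (!all(is.finite(rhs)))
    stop("non-finite drive encountered in MT update", call. = FALSE)
  v_new <- if (isTRUE(p$literal_h_on_derivative))
    clip01(v_mt + p$dt * h_saturation(rhs)) else h_saturation(v_mt + p$dt * rhs)
  # advance ring buffer: store the state that was current at this step
  if (state$n_delay > 0L) {
    slot <- (state$buf_pos %% state$n_delay) + 1L
    state$buffer[[slot]] <- v_mt
    state$buf_pos <- state$buf_pos + 1L
  }
  state$v_mt <- v_new
  list(state = state, chi = chi)
}

#' Run the full V1-to-MT pipeline on a stimulus
#'
#' Computes the three V1 streams for every frame, then integrates the MT
#' sheet one step per frame. `mode = "component"` uses the full ECRF drive
#' (`Gcsmt` from the parameter set) and the form-gated lateral excitation;
#' `mode = "pattern"` removes the ECRF drive (`Gcsmt = 0`) and forces the
#' lateral gate open, so motion signals from the occlusion junction
#' propagate and the sheet converges on the pattern direction.
#'
#' @param frames a `frame_sequence`.
#' @param p an [mt_params()] object.
#' @param mode `"component"` or `"pattern"`.
#' @param Gcsmt_pattern ECRF-drive gain used in pattern mode (default 0; the
#'   strength of the form connection is a continuous dial).
#' @param store_chi keep the per-step surround field in the trace.
#' @param progress print per-step progress.
#' @return a `simulation_trace`: `v_mt` (H x W x N x T), optional `chi`
#'   (same shape), final `v_es`, the last `mt_state` (with delay buffer,
#'   resume-capable), and metadata (`mode`, `params`, `params_hash`).
#' @export
run_model <- function(frames, p = mt_params(),
                      mode = c("component", "pattern"),
                      Gcsmt_pattern = 0, store_chi = TRUE,
                      progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(frames, "frame_sequence"))
  fs <- frames$frames
  H <- dim(fs)[1]; W <- dim(fs)[2]; T <- dim(fs)[3]
  Gcsmt_eff <- if (mode == "pattern") Gcsmt_pattern else p$Gcsmt
  force_open <- mode == "pattern"

  v_cx_all <- complex_v1_response(frames, p)
  v_es <- array(0, c(H, W, p$N))
  state <- mt_state_init(H, W, p)
  v_mt_all <- array(0, c(H, W, p$N, T))
  chi_all <- if (store_chi) array(0, c(H, W, p$N, T)) else NULL

  # per-frame form and contrast fields (frames repeat work only if they
  # change; stimuli here change every frame, so compute per step)
  prev_frame <- NULL; v_cs <- NULL; Lambda <- NULL
  for (t in seq_len(T)) {
    fr <- fs[, , t]
    if (is.null(prev_frame) || !identical(fr, prev_frame)) {
      v_cs <- ecrf_response(fr, p)
      Lambda <- local_contrast(fr, p)
      prev_frame <- fr
    }
    v_cx <- v_cx_all[, , , t]
    Gamma <- inhibition_field(v_cx, p)
    v_es <- endstopped_step(v_es, v_cx, Gamma, p)
    kappa <- gated_motion(v_cx, v_cs)
    Delta <- motion_discontinuity(v_cx, p)
    res <- mt_step(state, v_cx, v_es, kappa, Lambda, Delta, v_cs, p,
                   Gcsmt_eff = Gcsmt_eff, force_gate_open = force_open)
    state <- res$state
    if (!all(is.finite(state$v_mt)))
      stop(sprintf("non-finite MT activity at step %d", t), call. = FALSE)
    v_mt_all[, , , t] <- state$v_mt
    if (store_chi) chi_all[, , , t] <- res$chi
    if (progress) message(sprintf("step %d / %d", t, T))
  }
  structure(list(
    v_mt = v_mt_all, chi = chi_all, v_es = v_es, state = state,
    mode = mode, dt = p$dt, ms_per_time_unit = p$ms_per_time_unit,
    params = p, params_hash = params_hash(p),
    format_version = 1L), class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  d <- dim(x$v_mt)
  cat(sprintf("<simulation_trace> %s mode, %d x %d grid, %d directions, %d steps\n",
              x$mode, d[1], d[2], d[3], d[4]))
  invisible(x)
}
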