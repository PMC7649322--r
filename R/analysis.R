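# Analysis metrics: direction decoding, disambiguation latency, terminator
# selectivity and pattern/component classification of simulation traces.

#' Decode the dominant direction per location
#'
#' Argmax over the N direction channels wherever the maximum exceeds the
#' activity threshold; ties break to the lowest channel index. Locations at
#' or below threshold are labelled 0 ("none").
#'
#' @param snapshot H x W x N activity array (one time step).
#' @param threshold decode threshold (default 0.05).
#' @return list: `label` (H x W integer matrix, 0 = none) and `margin`
#'   (H x W matrix, winner minus runner-up; equals the winner when only one
#'   channel is active).
#' @export
decode_directions <- function(snapshot, threshold = 0.05) {
  d <- dim(snapshot)
  flat <- matrix(snapshot, nrow = d[1] * d[2], ncol = d[3])
  win <- max.col(flat, ties.method = "first")
  mx <- flat[cbind(seq_len(nrow(flat)), win)]
  flat[cbind(seq_len(nrow(flat)), win)] <- -Inf
  second <- apply(flat, 1L, max)
  label <- ifelse(mx > threshold, win, 0L)
  margin <- ifelse(mx > threshold, mx - pmax(second, 0), 0)
  list(label = matrix(as.integer(label), d[1], d[2]),
       margin = matrix(margin, d[1], d[2]))
}

#' Fraction of on-bar locations decoded to their true direction
#'
#' @param v_mt_t H x W x N snapshot.
#' @param gt ground truth from a two-bar or single-bar generator.
#' @param t frame index for the masks.
#' @param threshold decode threshold.
#' @return scalar in `[0, 1]`.
#' @keywords internal
.fraction_correct <- function(v_mt_t, gt, t, threshold = 0.05) {
  dec <- decode_directions(v_mt_t, threshold)$label
  masks <- list(gt$on_bar1[, , t])
  dirs <- gt$true_dir[1]
  if (!is.null(gt$on_bar2)) {
    masks <- c(masks, list(gt$on_bar2[, , t]))
    dirs <- c(dirs, gt$true_dir[2])
  }
  n_tot <- 0L; n_ok <- 0L
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (i == 2L) m <- m & !masks[[1L]]  # junction pixels scored with bar 1
    n_tot <- n_tot + sum(m)
    n_ok <- n_ok + sum(dec[m] == dirs[i])
  }
  if (n_tot == 0L) stop("empty on-bar masks", call. = FALSE)
  n_ok / n_tot
}

#' Time to disambiguation of the motion signals
#'
#' Per step, the fraction of on-bar locations whose decoded direction
#' equals their bar's true direction; the latency is the first step at
#' which this trajectory reaches the criterion, converted to milliseconds
#' via the trace's time mapping. The criterion (default: 90% of on-bar
#' locations correct) is reported alongside the latency.
#'
#' @param trace a `simulation_trace`.
#' @param gt ground truth from the stimulus generator.
#' @param criterion required fraction correct (default 0.9).
#' @param threshold decode threshold passed to [decode_directions()].
#' @return list: `latency_steps` (integer or `NA` for "never"),
#'   `latency_ms`, `trajectory` (per-step fraction correct), `criterion`,
#'   `threshold`.
#' @export
time_to_disambiguation <- function(trace, gt, criterion = 0.9,
                                   threshold = 0.05) {
  T <- dim(trace$v_mt)[4]
  traj <- vapply(seq_len(T), function(t)
    .fraction_correct(trace$v_mt[, , , t], gt, t, threshold), numeric(1))
  hit <- which(traj >= criterion)
  steps <- if (length(hit) > 0L) hit[1] else NA_integer_
  list(latency_steps = steps,
       latency_ms = if (is.na(steps)) NA_real_
                    else steps * trace$dt * trace$ms_per_time_unit,
       trajectory = traj, criterion = criterion, threshold = threshold)
}

#' Terminator-to-mid-edge activity ratio
#'
#' Mean activity (summed over channels) over the terminator mask divided by
#' the mean over the mid-edge mask. A ratio far above 1 is the end-stopping
#' signature: activity concentrated at contour end-points.
#'
#' @param map H x W x N activity snapshot (or H x W matrix).
#' @param term_mask,edge_mask logical H x W masks.
#' @return scalar ratio; `Inf` when the mid-edge mean is zero but the
#'   terminator mean is not.
#' @export
terminator_edge_ratio <- function(map, term_mask, edge_mask) {
  if (!any(term_mask) || !any(edge_mask))
    stop("terminator or mid-edge mask is empty", call. = FALSE)
  act <- if (length(dim(map)) == 3L) apply(map, c(1, 2), sum) else map
  num <- mean(act[term_mask]); den <- mean(act[edge_mask])
  if (den == 0) {
    if (num == 0) stop("both masks have zero activity", call. = FALSE)
    return(Inf)
  }
  num / den
}

#' Classify a plaid run as pattern or component motion
#'
#' Sums steady-state (final-step) on-bar activity per direction channel.
#' If the upward channel carries the largest mass the run is `"pattern"`;
#' if the two oblique channels (up-left and up-right) carry the two largest
#' masses it is `"component"`; anything else is `"mixed"`.
#'
#' @param trace a `simulation_trace` from an occluded-plaid run.
#' @param gt plaid ground truth.
#' @param t step at which to classify (default: last).
#' @return list: `class` label, `mass` (per-channel on-bar activity mass).
#' @export
pattern_component_class <- function(trace, gt, t = dim(trace$v_mt)[4]) {
  on_bar <- gt$on_bar1[, , t] | gt$on_bar2[, , t]
  if (!any(on_bar)) stop("empty on-bar mask", call. = FALSE)
  N <- dim(trace$v_mt)[3]
  mass <- vapply(seq_len(N), function(n)
    sum(trace$v_mt[, , n, t][on_bar]), numeric(1))
  names(mass) <- paste0("dir", dir_angles(N))
  up <- which(dir_angles(N) == 90)        # channel 3
  obl <- which(dir_angles(N) %in% c(45, 135))
  top2 <- order(mass, decreasing = TRUE)[1:2]
  cls <- if (setequal(top2, obl) && all(mass[obl] > 0)) "component"
         else if (which.max(mass) == up && mass[up] > 0) "pattern"
         else "mixed"
  list(class = cls, mass = mass)
}

#' First step at which the upward channel dominates, per location
#'
#' Used to examine the propagation of pattern motion from the occlusion
#' junction: the time at which each location's decoded direction first
#' becomes upward (and stays decodable), `NA` where it never does.
#'
#' @param trace a `simulation_trace`.
#' @param threshold decode threshold.
#' @return H x W matrix of step indices (`NA` = never).
#' @export
upward_onset_map <- function(trace, threshold = 0.05) {
  d <- dim(trace$v_mt)
  up <- which(dir_angles(d[3]) == 90)
  onset <- matrix(NA_integer_, d[1], d[2])
  for (t in seq_len(d[4])) {
    dec <- decode_directions(trace$v_mt[, , , t], threshold)$label
    new <- is.na(onset) & dec == up
    onset[new] <- t
  }
  onset
}
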