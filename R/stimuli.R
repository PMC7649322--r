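# Procedural stimulus generation: crossing bars, occluded plaids, single
# bars and drifting gratings, each with ground-truth masks for analysis.
#
# Geometry is done in degrees with the origin at the frame centre, x to the
# right and y upward; rendering converts to matrix rows (downward). Bars are
# drawn with a one-pixel coverage ramp at their borders (smooth sub-pixel
# motion); the ground-truth masks are the exact binary rectangles.

#' Describe a stimulus
#'
#' Collects the geometry and kinematics of one of the four stimulus kinds.
#' All lengths are in degrees of visual angle and speeds in degrees per time
#' unit. Defaults give a 64 x 64 frame (16 x 16 deg at 0.25 deg per pixel)
#' with two 10-deg bars of width 0.5 deg crossing at the centre. Bars are
#' rendered with a one-pixel coverage ramp at their borders so that
#' sub-pixel translation is smooth (continuous motion for the energy
#' filters); the ground-truth masks are the binary rectangles.
#'
#' @param kind one of `"crossing_bars"`, `"occluded_plaid"`, `"single_bar"`,
#'   `"grating"`.
#' @param orientations bar orientations in degrees (counter-clockwise from
#'   horizontal). Two values for bar stimuli, one for `single_bar`.
#' @param directions motion direction of each bar in degrees (0 = rightward,
#'   90 = upward).
#' @param speed translation speed, deg per time unit.
#' @param contrasts intensity of each bar in `[0, 1]` (background is 0).
#' @param bar_length,bar_width bar dimensions in degrees.
#' @param size frame height/width in pixels.
#' @param n_frames number of frames (one frame per integration step).
#' @param occluder_radius radius (deg) of the circular aperture used by
#'   `occluded_plaid`; everything outside is painted background, hiding the
#'   bars' intrinsic terminators.
#' @param grating_direction,grating_speed,grating_contrast drifting-grating
#'   parameters (spatial frequency comes from `mt_params()$f`).
#' @param terminator_radius radius (deg) of the ground-truth terminator
#'   disks.
#' @return a `stimulus_spec` list.
#' @export
stimulus_spec <- function(kind = c("crossing_bars", "occluded_plaid",
                                   "single_bar", "grating"),
                          orientations = c(135, 45),
                          directions = c(0, 180),
                          speed = 0.5,
                          contrasts = c(0.8, 0.8),
                          bar_length = 10,
                          bar_width = 0.5,
                          size = 64L,
                          n_frames = 300L,
                          occluder_radius = 3,
                          grating_direction = 0,
                          grating_speed = 2,
                          grating_contrast = 1,
                          terminator_radius = 0.75,
                          fade_in = 0.1) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, orientations = orientations,
               directions = directions, speed = speed,
               contrasts = contrasts, bar_length = bar_length,
               bar_width = bar_width, size = as.integer(size),
               n_frames = as.integer(n_frames),
               occluder_radius = occluder_radius,
               grating_direction = grating_direction,
               grating_speed = grating_speed,
               grating_contrast = grating_contrast,
               terminator_radius = terminator_radius,
               fade_in = fade_in)
  stopifnot(spec$speed >= 0, all(spec$contrasts >= 0 & spec$contrasts <= 1),
            spec$size >= 32L, spec$n_frames >= 2L)
  if (kind %in% c("crossing_bars", "occluded_plaid") &&
      abs((orientations[1] - orientations[2]) %% 180) < 1e-9)
    stop("two-bar stimuli need distinct orientations", call. = FALSE)
  structure(spec, class = "stimulus_spec")
}

#' Frame sequence container
#' @param frames H x W x T array of intensities in `[0, 1]`.
#' @param deg_per_pixel grid scale.
#' @param dt time units per frame.
#' @return a `frame_sequence` object.
#' @keywords internal
frame_sequence <- function(frames, deg_per_pixel, dt) {
  stopifnot(length(dim(frames)) == 3L, min(frames) >= 0, max(frames) <= 1)
  structure(list(frames = frames, deg_per_pixel = deg_per_pixel, dt = dt),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d x %d px, %d frames, %g deg/px, dt = %g\n",
              d[1], d[2], d[3], x$deg_per_pixel, x$dt))
  invisible(x)
}

# pixel-centre coordinate grids in degrees (y up)
.coord_grids <- function(size, dpp) {
  c0 <- (size + 1) / 2
  x <- matrix(rep((seq_len(size) - c0) * dpp, each = size), size, size)
  y <- matrix(rep((c0 - seq_len(size)) * dpp, times = size), size, size)
  list(x = x, y = y)
}

# logical mask of a bar: centre (deg), orientation o (deg), length, width
.bar_mask <- function(g, centre, o, len, wdt) {
  co <- cos(o * pi / 180); so <- sin(o * pi / 180)
  s <- (g$x - centre[1]) * co + (g$y - centre[2]) * so
  n <- -(g$x - centre[1]) * so + (g$y - centre[2]) * co
  abs(s) <= len / 2 & abs(n) <= wdt / 2
}

# pixel coverage of a bar with a one-pixel linear ramp at the borders, so
# that sub-pixel translation moves the rendered intensity smoothly instead
# of in whole-pixel jumps (motion-energy filters need continuous motion)
.bar_coverage <- function(g, centre, o, len, wdt, px) {
  co <- cos(o * pi / 180); so <- sin(o * pi / 180)
  s <- (g$x - centre[1]) * co + (g$y - centre[2]) * so
  n <- -(g$x - centre[1]) * so + (g$y - centre[2]) * co
  covn <- clip01((wdt / 2 - abs(n)) / px + 0.5)
  covs <- clip01((len / 2 - abs(s)) / px + 0.5)
  covn * covs
}

.bar_endpoints <- function(centre, o, len) {
  u <- c(cos(o * pi / 180), sin(o * pi / 180))
  list(centre + (len / 2) * u, centre - (len / 2) * u)
}

# smooth onset ramp: a step onset excites every direction channel
# broadly (broadband transient); fading the stimulus in keeps the motion
# channels clean from the start
.fade_ramp <- function(t_units, fade_in) {
  if (fade_in <= 0 || t_units >= fade_in) return(1)
  0.5 * (1 - cos(pi * t_units / fade_in))
}

# map a direction angle to the nearest of the N channels (1-based index)
.dir_channel <- function(angle_deg, N = 8L) {
  1L + (as.integer(round((angle_deg %% 360) / (360 / N))) %% N)
}

.disk_mask <- function(g, centre, radius) {
  (g$x - centre[1])^2 + (g$y - centre[2])^2 <= radius^2
}

# intersection point of the two bar centre-lines (deg), or NULL if parallel
.line_intersection <- function(c1, o1, c2, o2) {
  u1 <- c(cos(o1 * pi / 180), sin(o1 * pi / 180))
  u2 <- c(cos(o2 * pi / 180), sin(o2 * pi / 180))
  A <- cbind(u1, -u2)
  if (abs(det(A)) < 1e-12) return(NULL)
  t <- solve(A, c2 - c1)
  c1 + t[1] * u1
}

#' Generate a two-bar (crossing bars / occluded plaid) stimulus
#'
#' Two bright bars on a dark background translate in opposite horizontal
#' directions; with the default orientations (135 and 45 deg) their crossing
#' junction drifts upward, the classic plaid configuration. When the two
#' contrasts differ the brighter bar is drawn on top at the junction
#' (occlusion reading of transparent overlap). `occluded_plaid` additionally
#' paints everything outside a circular aperture with the background
#' intensity, hiding the four intrinsic terminators every frame.
#'
#' @param spec a [stimulus_spec()] of kind `crossing_bars` or
#'   `occluded_plaid`.
#' @param p an [mt_params()] object (grid and time conventions).
#' @return a list with elements `frames` (a `frame_sequence`) and `gt`
#'   (ground truth: per-frame logical masks `on_bar1`, `on_bar2`,
#'   `intrinsic`, `extrinsic`, `mid_edge`, plus `true_dir` channels).
#' @export
crossing_bars <- function(spec, p = mt_params()) {
  if (!spec$kind %in% c("crossing_bars", "occluded_plaid"))
    stop("spec kind must be crossing_bars or occluded_plaid", call. = FALSE)
  occluded <- identical(spec$kind, "occluded_plaid")
  size <- spec$size; T <- spec$n_frames
  g <- .coord_grids(size, p$deg_per_pixel)
  half <- size * p$deg_per_pixel / 2
  frames <- array(0, c(size, size, T))
  mk <- function() array(FALSE, c(size, size, T))
  gt <- list(on_bar1 = mk(), on_bar2 = mk(), intrinsic = mk(),
             extrinsic = mk(), mid_edge = mk(),
             true_dir = c(.dir_channel(spec$directions[1], p$N),
                          .dir_channel(spec$directions[2], p$N)))
  v1 <- dir_vector(spec$directions[1]); v1 <- c(v1[1], -v1[2])  # y up
  v2 <- dir_vector(spec$directions[2]); v2 <- c(v2[1], -v2[2])
  aperture <- if (occluded) .disk_mask(g, c(0, 0), spec$occluder_radius)
              else matrix(TRUE, size, size)
  order_idx <- order(spec$contrasts)  # dimmer first, brighter on top
  # centre the trajectory: bars start half the total excursion behind the
  # frame centre so the configuration stays central throughout the run
  half_exc <- (T - 1) * p$dt * spec$speed / 2
  for (t in seq_len(T)) {
    dt_off <- (t - 1) * p$dt * spec$speed - half_exc
    c1 <- c(0, 0) + v1 * dt_off
    c2 <- c(0, 0) + v2 * dt_off
    centres <- list(c1, c2)
    masks <- list(
      .bar_mask(g, c1, spec$orientations[1], spec$bar_length, spec$bar_width),
      .bar_mask(g, c2, spec$orientations[2], spec$bar_length, spec$bar_width))
    eps <- c(.bar_endpoints(c1, spec$orientations[1], spec$bar_length),
             .bar_endpoints(c2, spec$orientations[2], spec$bar_length))
    if (!occluded) {
      for (e in eps)
        if (any(abs(e) > half))
          stop(sprintf("bar exits frame at frame %d", t), call. = FALSE)
    }
    jx <- .line_intersection(c1, spec$orientations[1], c2,
                             spec$orientations[2])
    if (is.null(jx) || any(abs(jx) > half))
      stop(sprintf("bars do not intersect within the frame at frame %d", t),
           call. = FALSE)
    ramp <- .fade_ramp((t - 1) * p$dt, spec$fade_in)
    fr <- matrix(0, size, size)
    for (i in order_idx) {
      cov <- .bar_coverage(g, centres[[i]], spec$orientations[i],
                           spec$bar_length, spec$bar_width, p$deg_per_pixel)
      fr <- fr * (1 - cov) + ramp * spec$contrasts[i] * cov  # later bar occludes
    }
    fr[!aperture] <- 0
    frames[, , t] <- fr
    gt$on_bar1[, , t] <- masks[[1]] & aperture
    gt$on_bar2[, , t] <- masks[[2]] & aperture
    term <- matrix(FALSE, size, size)
    if (!occluded) {
      for (e in eps) term <- term | .disk_mask(g, e, spec$terminator_radius)
      term <- term & (masks[[1]] | masks[[2]])
    } else {
      # aperture must actually hide the terminators
      for (e in eps)
        if (sqrt(sum(e^2)) <= spec$occluder_radius)
          stop(sprintf(
            "occluder smaller than terminator excursion at frame %d", t),
            call. = FALSE)
    }
    junc <- .disk_mask(g, jx, spec$terminator_radius) &
      (masks[[1]] | masks[[2]]) & aperture
    gt$intrinsic[, , t] <- term & !junc
    gt$extrinsic[, , t] <- junc & !term
    far <- .far_from_terminators(g, c(eps, list(jx)),
                                 3 * p$deg_per_pixel)
    gt$mid_edge[, , t] <- (gt$on_bar1[, , t] | gt$on_bar2[, , t]) & far
  }
  if (occluded) gt$occluder <- !aperture
  list(frames = frame_sequence(frames, p$deg_per_pixel, p$dt), gt = gt)
}

.far_from_terminators <- function(g, points, min_dist) {
  far <- matrix(TRUE, nrow(g$x), ncol(g$x))
  for (pt in points)
    far <- far & ((g$x - pt[1])^2 + (g$y - pt[2])^2 > min_dist^2)
  far
}

#' @rdname crossing_bars
#' @export
occluded_plaid <- function(spec, p = mt_params()) {
  if (!identical(spec$kind, "occluded_plaid"))
    stop("spec kind must be occluded_plaid", call. = FALSE)
  crossing_bars(spec, p)
}

#' Generate a single translating bar
#'
#' Validation stimulus: one bar, two intrinsic terminators, no junction.
#'
#' @inheritParams crossing_bars
#' @return as [crossing_bars()]: `frames` plus ground truth with masks
#'   `on_bar1`, `intrinsic`, `mid_edge` and the true direction channel.
#' @export
single_bar <- function(spec, p = mt_params()) {
  if (!identical(spec$kind, "single_bar"))
    stop("spec kind must be single_bar", call. = FALSE)
  size <- spec$size; T <- spec$n_frames
  g <- .coord_grids(size, p$deg_per_pixel)
  half <- size * p$deg_per_pixel / 2
  frames <- array(0, c(size, size, T))
  mk <- function() array(FALSE, c(size, size, T))
  gt <- list(on_bar1 = mk(), intrinsic = mk(), mid_edge = mk(),
             true_dir = .dir_channel(spec$directions[1], p$N))
  v1 <- dir_vector(spec$directions[1]); v1 <- c(v1[1], -v1[2])
  half_exc <- (T - 1) * p$dt * spec$speed / 2
  for (t in seq_len(T)) {
    c1 <- v1 * ((t - 1) * p$dt * spec$speed - half_exc)
    eps <- .bar_endpoints(c1, spec$orientations[1], spec$bar_length)
    for (e in eps)
      if (any(abs(e) > half))
        stop(sprintf("bar exits frame at frame %d", t), call. = FALSE)
    m <- .bar_mask(g, c1, spec$orientations[1], spec$bar_length,
                   spec$bar_width)
    cov <- .bar_coverage(g, c1, spec$orientations[1], spec$bar_length,
                         spec$bar_width, p$deg_per_pixel)
    frames[, , t] <- .fade_ramp((t - 1) * p$dt, spec$fade_in) *
      spec$contrasts[1] * cov
    gt$on_bar1[, , t] <- m
    term <- matrix(FALSE, size, size)
    for (e in eps) term <- term | .disk_mask(g, e, spec$terminator_radius)
    gt$intrinsic[, , t] <- term & m
    gt$mid_edge[, , t] <- m & .far_from_terminators(g, eps,
                                                    3 * p$deg_per_pixel)
  }
  list(frames = frame_sequence(frames, p$deg_per_pixel, p$dt), gt = gt)
}

#' Generate a drifting sinusoidal grating
#'
#' Full-field grating at the model's preferred spatial frequency, drifting
#' rigidly; used to validate and calibrate the motion-energy front end.
#'
#' @inheritParams crossing_bars
#' @param p an [mt_params()] object; `p$f` sets the spatial frequency.
#' @return a `frame_sequence` (no ground-truth masks).
#' @export
grating <- function(spec, p = mt_params()) {
  if (!identical(spec$kind, "grating"))
    stop("spec kind must be grating", call. = FALSE)
  size <- spec$size; T <- spec$n_frames
  g <- .coord_grids(size, p$deg_per_pixel)
  a <- spec$grating_direction * pi / 180
  u <- g$x * cos(a) + g$y * sin(a)  # coordinate along drift direction
  frames <- array(0, c(size, size, T))
  for (t in seq_len(T)) {
    ph <- 2 * pi * p$f * (u - spec$grating_speed * (t - 1) * p$dt)
    frames[, , t] <- 0.5 + 0.5 * spec$grating_contrast * cos(ph)
  }
  frame_sequence(frames, p$deg_per_pixel, p$dt)
}

#' Dispatch a stimulus spec to its generator
#' @inheritParams crossing_bars
#' @return see the individual generators.
#' @export
make_stimulus <- function(spec, p = mt_params()) {
  switch(spec$kind,
         crossing_bars = crossing_bars(spec, p),
         occluded_plaid = occluded_plaid(spec, p),
         single_bar = single_bar(spec, p),
         grating = grating(spec, p))
}
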