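# Instrument-frame targeting cues: lateral/depth decomposition of the
# tip-to-target displacement, the per-frame visual cue state, dwell-based
# target capture, and replay of recorded navigation streams.

#' Instrument pose (tip + orthonormal axes)
#'
#' The instrument frame encodes the surgeon's viewpoint: the z axis runs
#' longitudinally along the instrument (tip-forward), the x-y axes span
#' the transverse plane.  Movement along z is "depth" (in/out), movement
#' in x-y is "lateral".
#'
#' @param tip tip position (mm).
#' @param axes 3x3 matrix whose *columns* are the unit axes
#'   `(x_hat, y_hat, z_hat)`; must be orthonormal and right-handed within
#'   1e-9.  A tracked sensor rotation matrix can be passed directly.
#' @return object of class `instrument_pose`.
#' @export
instrument_pose <- function(tip, axes) {
  tip <- vec3(tip)
  axes <- as.matrix(axes)
  if (!.is_rotation(axes))
    stop("axes must form a right-handed orthonormal triad (within 1e-9)",
         call. = FALSE)
  structure(list(tip = tip, axes = axes), class = "instrument_pose")
}

#' Decompose the tip-to-target displacement into lateral and depth
#'
#' With displacement `delta = target - tip`: `depth = delta . z_hat`
#' (signed; positive means the target lies ahead of the tip, negative
#' means the tip has overreached it) and `lateral = (delta . x_hat,
#' delta . y_hat)` in instrument x-y coordinates.  By construction
#' `lateral_norm^2 + depth^2 = |delta|^2`.
#'
#' @param pose an [instrument_pose()].
#' @param target target position (mm).
#' @return object of class `tip_displacement`: `lateral` (2-vector mm),
#'   `depth` (signed mm), `lateral_norm`, `total`.
#' @export
decompose_displacement <- function(pose, target) {
  stopifnot(inherits(pose, "instrument_pose"))
  delta <- vec3(target) - pose$tip
  comp <- drop(t(pose$axes) %*% delta)
  structure(list(lateral = comp[1:2], depth = comp[3],
                 lateral_norm = sqrt(sum(comp[1:2]^2)),
                 total = sqrt(sum(delta^2))),
            class = "tip_displacement")
}

#' Visual display parameters
#'
#' Scaling and range parameters of the targeting display; pixel scales
#' are adjusted to the surgeon's preference so small instrument motions
#' are emphasized.
#'
#' @param lateral_scale px per mm of lateral displacement (default 20).
#' @param depth_scale px of circle diameter per mm of depth (default 20).
#' @param in_range_radius lateral distance (mm) within which the precise
#'   blob display is used; beyond it the display degrades to an
#'   orientation arrow (default 10).
#' @param zero_tolerance depth magnitude (mm) below which the depth
#'   circle vanishes / the cues are considered overlapping (default
#'   0.05, so the "at target" state is reachable with floating-point
#'   streams).
#' @param out_of_range_circle_diameter constant circle diameter (px)
#'   displayed while out of range (default 120).
#' @return object of class `display_params`.
#' @export
display_params <- function(lateral_scale = 20, depth_scale = 20,
                           in_range_radius = 10, zero_tolerance = 0.05,
                           out_of_range_circle_diameter = 120) {
  p <- list(lateral_scale = lateral_scale, depth_scale = depth_scale,
            in_range_radius = in_range_radius,
            zero_tolerance = zero_tolerance,
            out_of_range_circle_diameter = out_of_range_circle_diameter)
  if (any(unlist(p) <= 0))
    stop("all display parameters must be positive", call. = FALSE)
  structure(p, class = "display_params")
}

#' Per-frame visual cue state
#'
#' Computes the complete cue geometry for one frame, as data (never
#' pixels):
#' * **in range** (`lateral_norm <= in_range_radius`; ties go in range):
#'   a blob offset `lateral_scale * lateral` px from the target square,
#'   a depth circle of diameter `depth_scale * |depth|` px that vanishes
#'   when `|depth| <= zero_tolerance`, blinking iff the tip has
#'   overreached the target (`depth < -zero_tolerance`);
#' * **out of range**: the blob is absent, an arrow points toward the
#'   target at `atan2(lateral_y, lateral_x)`, and the depth circle is
#'   held at a constant diameter.
#'
#' A pure function: identical inputs give identical outputs.
#'
#' @param d a [decompose_displacement()] result.
#' @param params a [display_params()].
#' @return object of class `cue_state` with fields `mode`
#'   (`"in_range"`/`"out_of_range"`), `blob_offset_px` (2-vector or NULL),
#'   `circle_diameter_px`, `circle_visible`, `blink`, `arrow_direction`
#'   (radians or NA).
#' @export
cue_state <- function(d, params = display_params()) {
  stopifnot(inherits(d, "tip_displacement"), inherits(params, "display_params"))
  out_of_range <- d$lateral_norm > params$in_range_radius
  circle_visible <- abs(d$depth) > params$zero_tolerance
  blink <- d$depth < -params$zero_tolerance
  if (out_of_range) {
    st <- list(mode = "out_of_range", blob_offset_px = NULL,
               circle_diameter_px = params$out_of_range_circle_diameter,
               circle_visible = circle_visible, blink = blink,
               arrow_direction = atan2(d$lateral[2], d$lateral[1]))
  } else {
    st <- list(mode = "in_range",
               blob_offset_px = params$lateral_scale * d$lateral,
               circle_diameter_px = params$depth_scale * abs(d$depth),
               circle_visible = circle_visible, blink = blink,
               arrow_direction = NA_real_)
  }
  structure(st, class = "cue_state")
}

#' @export
print.cue_state <- function(x, ...) {
  if (x$mode == "in_range")
    cat(sprintf("Cue [in range]: blob (%.1f, %.1f) px, circle %.1f px%s%s\n",
                x$blob_offset_px[1], x$blob_offset_px[2],
                x$circle_diameter_px,
                if (!x$circle_visible) " (hidden)" else "",
                if (x$blink) " BLINK (overreach)" else ""))
  else
    cat(sprintf("Cue [out of range]: arrow %.1f deg, circle %.1f px (constant)%s\n",
                x$arrow_direction * 180 / pi, x$circle_diameter_px,
                if (x$blink) " BLINK (overreach)" else ""))
  invisible(x)
}

#' Dwell-based target capture
#'
#' Stores a position when the tracked tip is held still: the earliest
#' time window of duration at least `dwell_time` whose positions all lie
#' within `stability_radius` of the window mean.  Evaluated by a two-pass
#' sliding scan (grow the window to the required duration, then verify
#' every sample against the window mean).
#'
#' @param time numeric vector (s), strictly nondecreasing.
#' @param positions K x 3 matrix of tip positions (mm).
#' @param stability_radius maximum excursion from the window mean (mm),
#'   default 1.
#' @param dwell_time required hold duration (s), default 2 ("several
#'   seconds").
#' @return object of class `captured_target` (`position`, `dwell_start`,
#'   `dwell_end`, `spread`) or `NULL` when no window qualifies.
#' @export
dwell_capture <- function(time, positions, stability_radius = 1,
                          dwell_time = 2) {
  positions <- as.matrix(positions)
  if (is.unsorted(time)) stop("stream must be time-sorted", call. = FALSE)
  if (length(time) != nrow(positions))
    stop("time and positions disagree in length", call. = FALSE)
  n <- length(time)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && time[j] - time[i] < dwell_time) j <- j + 1L
    if (j > n) break
    w <- i:j
    ctr <- colMeans(positions[w, , drop = FALSE])
    dd <- sqrt(rowSums(sweep(positions[w, , drop = FALSE], 2, ctr)^2))
    if (max(dd) <= stability_radius)
      return(structure(list(position = vec3(ctr), dwell_start = time[i],
                            dwell_end = time[j], spread = max(dd)),
                       class = "captured_target"))
    j <- j - 1L   # re-examine from the next start
  }
  NULL
}

#' @export
print.captured_target <- function(x, ...) {
  cat(sprintf("Captured target (%.2f, %.2f, %.2f) mm over %.1f-%.1f s, spread %.3f mm\n",
              x$position[1], x$position[2], x$position[3],
              x$dwell_start, x$dwell_end, x$spread))
  invisible(x)
}

#' Replay a navigation stream against a target
#'
#' Applies the lateral/depth decomposition and the cue computation to
#' every frame of a recorded (or simulated) pose stream and summarizes
#' the localization episode: final tip-to-target distance (mm), path
#' length (cm, the trajectory sum of consecutive tip displacements) and
#' duration (s).
#'
#' @param stream list with `time` (s), `positions` (K x 3 tip positions,
#'   mm) and either `rotations` (list of 3x3 instrument-axis matrices,
#'   e.g. from [read_pose_stream()]) or a single fixed `axes` matrix.
#' @param target target position (mm).
#' @param params a [display_params()].
#' @return object of class `navigation_replay`: `frames` (data frame with
#'   per-frame time, lateral/depth components, mode and cue geometry) and
#'   `summary` (`final_distance_mm`, `path_length_cm`, `duration_s`).
#' @export
replay_navigation <- function(stream, target, params = display_params()) {
  pos <- as.matrix(stream$positions)
  n <- nrow(pos)
  if (is.null(n) || n < 1L) stop("empty stream", call. = FALSE)
  time <- stream$time %||% seq_len(n)
  axes_of <- function(i) {
    if (!is.null(stream$rotations)) stream$rotations[[i]]
    else stream$axes %||% diag(3)
  }
  target <- vec3(target)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- decompose_displacement(instrument_pose(pos[i, ], axes_of(i)), target)
    s <- cue_state(d, params)
    rows[[i]] <- data.frame(
      time = time[i], lateral_x = d$lateral[1], lateral_y = d$lateral[2],
      lateral_norm = d$lateral_norm, depth = d$depth, mode = s$mode,
      circle_diameter_px = s$circle_diameter_px,
      circle_visible = s$circle_visible, blink = s$blink,
      arrow_direction = s$arrow_direction)
  }
  frames <- do.call(rbind, rows)
  path_mm <- if (n > 1) sum(sqrt(rowSums(diff(pos)^2))) else 0
  structure(list(
    frames = frames,
    summary = list(
      final_distance_mm = sqrt(sum((target - pos[n, ])^2)),
      path_length_cm = path_mm / 10,
      duration_s = time[n] - time[1])
  ), class = "navigation_replay")
}

#' @export
print.navigation_replay <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Navigation replay: %d frames over %.2f s\n", nrow(x$frames),
              s$duration_s))
  cat(sprintf("  path length %.2f cm, final distance to target %.3f mm\n",
              s$path_length_cm, s$final_distance_mm))
  invisible(x)
}
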