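# Synthetic-session generator: a nasopharyngeal fiducial cluster with a
# distant brainstem target, screw check-points, two-space localization
# noise and instrument trajectories, so that registration, error models,
# detection, targeting and assessment are all testable end-to-end.

#' Synthetic navigation session specification
#'
#' Defaults emulate the geometry the navigation concept is designed for:
#' a compact 4-fiducial nasopharyngeal cluster (about 25 mm extent), a
#' surgical target about 70 mm from the cluster centroid (the
#' foramen-of-Luschka distance from the nasopharynx), 8 skull screws for
#' TRE checks, and localization noise of 0.1 mm RMS in image space
#' (fiducial centroid detection) plus 0.7 mm RMS for the electromagnetic
#' tracker.
#'
#' @param n_fiducials number of fiducials (>= 3), default 4.
#' @param cluster_extent fiducial cluster diameter (mm), default 25.
#' @param target_offset target distance from the cluster centroid (mm),
#'   default 70.
#' @param n_screws number of screw check-points, default 8.
#' @param screw_range distance band of screws from the cluster centroid
#'   (mm), default `c(40, 90)`.
#' @param fle_image image-space fiducial localization RMS error (mm),
#'   default 0.1.
#' @param fle_emt tracker-space localization RMS error (mm), default 0.7.
#' @param n_touches pointer touches per screw, default 3.
#' @param trajectory instrument trajectory kind: `"straight"` approach,
#'   `"dwell"` (jittered hold at the target) or `"excursion"` (enters the
#'   lateral range from outside).
#' @param speed instrument speed for the straight approach (mm/s),
#'   default 5.
#' @param rate stream sampling rate (Hz), default 10.
#' @return object of class `session_spec`.
#' @export
session_spec <- function(n_fiducials = 4, cluster_extent = 25,
                         target_offset = 70, n_screws = 8,
                         screw_range = c(40, 90), fle_image = 0.1,
                         fle_emt = 0.7, n_touches = 3,
                         trajectory = c("straight", "dwell", "excursion"),
                         speed = 5, rate = 10) {
  trajectory <- match.arg(trajectory)
  if (n_fiducials < 3) stop("n_fiducials must be >= 3", call. = FALSE)
  if (cluster_extent <= 0 || target_offset <= 0 || speed <= 0 || rate <= 0)
    stop("all lengths and rates must be positive", call. = FALSE)
  if (target_offset <= cluster_extent / 2)
    stop("infeasible geometry: target would lie inside the fiducial cluster",
         call. = FALSE)
  structure(list(n_fiducials = n_fiducials, cluster_extent = cluster_extent,
                 target_offset = target_offset, n_screws = n_screws,
                 screw_range = screw_range, fle_image = fle_image,
                 fle_emt = fle_emt, n_touches = n_touches,
                 trajectory = trajectory, speed = speed, rate = rate),
            class = "session_spec")
}

.runif_sphere <- function(n, radius) {
  # uniform in a ball of given radius
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * radius * stats::runif(n)^(1 / 3)
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate a complete navigation session
#'
#' Draws a fiducial cluster, target, screws and a ground-truth
#' patient-to-image transform; produces noiseless and noisy point sets in
#' both spaces (per-axis noise sd = RMS / sqrt(3), isotropic), pointer
#' touches on every screw, an instrument pose stream of the requested
#' trajectory kind, and a phantom-volume specification for the fiducial
#' detector.  Deterministic for a given seed.
#'
#' @param spec a [session_spec()].
#' @param seed integer RNG seed.
#' @return object of class `synthetic_session`; see Details.
#' @details Elements: `transform` (ground-truth patient-to-image
#'   [rigid_transform()]), `image_fids`/`patient_fids` (noisy,
#'   patient labels shuffled), `image_fids_true`/`patient_fids_true`,
#'   `true_mapping` (patient label -> image label),
#'   `target_image`/`target_patient`, `image_screws_true`,
#'   `image_screws`, `patient_screws_true`, `touches` (data frame),
#'   `stream` (list: time, rotations, positions, in patient space),
#'   `phantom_spec` (arguments for [generate_phantom()]), `spec`, `seed`.
#' @export
simulate_session <- function(spec = session_spec(), seed = 1) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(seed)
  n <- spec$n_fiducials
  # image-space geometry, centered on the cluster centroid
  repeat {
    F <- .runif_sphere(n, spec$cluster_extent / 2)
    sv <- svd(sweep(F, 2, colMeans(F)), nu = 0, nv = 0)$d
    if (sv[2] < 0.15 * spec$cluster_extent) next    # avoid near-collinear draws
    # reject label-ambiguous (near-symmetric) arrangements: automated
    # correspondence needs the runner-up pairing to fit clearly worse,
    # mirroring how markers are placed asymmetrically in practice
    if (n <= 6) {
      perms <- .arrangements(n, n)
      fres <- apply(perms[-1, , drop = FALSE], 1, function(p) {
        fit <- .fit_rigid_core(F, F[p, , drop = FALSE])
        sqrt(mean(rowSums(fit$residuals^2)))
      })
      gap_needed <- 3 * (spec$fle_image + spec$fle_emt)
      if (min(fres) < gap_needed) next
    }
    break
  }
  ctr <- colMeans(F)
  target <- ctr + spec$target_offset * .rand_unit()
  ns <- spec$n_screws
  screws <- t(vapply(seq_len(ns), function(i)
    ctr + stats::runif(1, spec$screw_range[1], spec$screw_range[2]) * .rand_unit(),
    numeric(3)))
  # ground-truth patient -> image transform
  T_pi <- rigid_transform(random_rotation(), stats::runif(3, -100, 100))
  T_ip <- invert_transform(T_pi)

  image_fids_true <- labeled_points(paste0("F", 1:n), F, frame = "image")
  patient_true_pos <- apply_transform(T_ip, F)
  shuffle <- sample(n)
  patient_fids_true <- labeled_points(paste0("S", 1:n),
                                      patient_true_pos[shuffle, , drop = FALSE],
                                      frame = "patient")
  true_mapping <- stats::setNames(paste0("F", shuffle), paste0("S", 1:n))

  sd_img <- spec$fle_image / sqrt(3)
  sd_emt <- spec$fle_emt / sqrt(3)
  noisy <- function(ps, sd) {
    if (sd <= 0) return(ps)
    p <- .positions(ps) + matrix(stats::rnorm(3 * nrow(ps), sd = sd), nrow(ps))
    labeled_points(ps$label, p, frame = attr(ps, "frame"))
  }
  image_fids <- noisy(image_fids_true, sd_img)
  patient_fids <- noisy(patient_fids_true, sd_emt)

  image_screws_true <- labeled_points(paste0("T", 1:ns), screws, frame = "image")
  image_screws <- noisy(image_screws_true, sd_img)
  patient_screws_true <- labeled_points(paste0("T", 1:ns),
                                        apply_transform(T_ip, screws),
                                        frame = "patient")
  touches <- do.call(rbind, lapply(seq_len(ns), function(i) {
    p <- matrix(rep(.positions(patient_screws_true)[i, ], spec$n_touches),
                spec$n_touches, 3, byrow = TRUE)
    p <- p + matrix(stats::rnorm(3 * spec$n_touches, sd = sd_emt),
                    spec$n_touches)
    data.frame(label = paste0("T", i), x = p[, 1], y = p[, 2], z = p[, 3])
  }))

  target_patient <- apply_transform(T_ip, target)
  stream <- .simulate_trajectory(spec, target_patient)

  structure(list(
    transform = T_pi,
    image_fids_true = image_fids_true, image_fids = image_fids,
    patient_fids_true = patient_fids_true, patient_fids = patient_fids,
    true_mapping = true_mapping,
    target_image = vec3(target), target_patient = vec3(target_patient),
    image_screws_true = image_screws_true, image_screws = image_screws,
    patient_screws_true = patient_screws_true, touches = touches,
    stream = stream,
    phantom_spec = list(centers = image_fids_true, radius = 2,
                        spacing = c(0.43, 0.43, 0.6), noise_sd = 25,
                        background = 40, foreground = 1000),
    spec = spec, seed = seed
  ), class = "synthetic_session")
}

# Instrument trajectories in patient space, oriented with z_hat toward the
# target (tip-forward) throughout.
.simulate_trajectory <- function(spec, target) {
  dt <- 1 / spec$rate
  approach_dir <- .rand_unit()
  # axes with z_hat = -approach_dir (instrument advances along +z)
  zhat <- -approach_dir
  xr <- .rand_unit()
  xhat <- .unit(xr - sum(xr * zhat) * zhat)
  axes <- cbind(xhat, .cross(zhat, xhat), zhat)   # right-handed triad
  if (spec$trajectory == "straight") {
    dist0 <- 10
    tt <- seq(0, dist0 / spec$speed, by = dt)
    pos <- t(vapply(tt, function(s)
      target + (dist0 - spec$speed * s) * approach_dir, numeric(3)))
  } else if (spec$trajectory == "dwell") {
    tt <- seq(0, 4, by = dt)
    pos <- matrix(rep(target, length(tt)), ncol = 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * length(tt), sd = 0.2), ncol = 3)
  } else {   # excursion: approach with a large initial lateral offset
    lat <- 25 * xhat
    tt <- seq(0, 5, by = dt)
    frac <- tt / max(tt)
    pos <- t(vapply(seq_along(tt), function(i)
      target + (1 - frac[i]) * (10 * approach_dir + lat), numeric(3)))
  }
  list(time = tt, positions = pos,
       rotations = rep(list(axes), length(tt)), axes = axes)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.synthetic_session <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("Synthetic navigation session (seed %d): %d fiducials ",
                     "(%.0f mm cluster), target %.0f mm away, %d screws, ",
                     "FLE %.2f/%.2f mm (image/EMT), '%s' trajectory\n"),
              x$seed, s$n_fiducials, s$cluster_extent, s$target_offset,
              s$n_screws, s$fle_image, s$fle_emt, s$trajectory))
  invisible(x)
}
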