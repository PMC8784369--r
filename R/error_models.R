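# Statistical models of navigation uncertainty: fiducial localization
# error (FLE) composition, FLE recovery from FRE, analytic target
# registration error (TRE) prediction, first-order TRE covariance with
# chi-square confidence ellipses, and a Monte-Carlo oracle.

#' Fiducial localization error model
#'
#' Combines independent localization-error sources (e.g. image-space
#' centroid error and electromagnetic-tracker error) into a single FLE by
#' root-sum-of-squares: `total_rms^2 = sum(rms_i^2)`.  The RMS values are
#' 3D RMS errors in mm.  An optional 3x3 covariance (mm^2) describes
#' anisotropic noise; by default the noise is isotropic with per-axis
#' variance `total_rms^2 / 3`.
#'
#' @param components named numeric vector of per-source RMS errors (mm),
#'   e.g. `c(image = 0.1, emt = 0.7)`.
#' @param covariance optional 3x3 symmetric PSD matrix with
#'   `trace == total_rms^2` (within 1e-9 relative); supplied only for
#'   anisotropic noise.
#' @return an object of class `fle_model` with `components`, `total_rms`,
#'   `covariance` and the flag `isotropic`.
#' @export
#' @examples
#' combine_fle(c(image = 0.1, emt = 0.7))$total_rms  # 0.7071068
combine_fle <- function(components, covariance = NULL) {
  components <- unlist(components)
  if (any(!is.finite(components)) || any(components < 0))
    stop("component RMS values must be finite and >= 0", call. = FALSE)
  total <- sqrt(sum(components^2))
  iso <- is.null(covariance)
  if (iso) {
    covariance <- diag(rep(total^2 / 3, 3))
  } else {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == c(3L, 3L)) ||
        max(abs(covariance - t(covariance))) > 1e-9)
      stop("covariance must be 3x3 symmetric", call. = FALSE)
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9 * max(abs(ev), 1))
      stop("covariance must be positive semidefinite", call. = FALSE)
    if (abs(sum(diag(covariance)) - total^2) > 1e-9 * max(total^2, 1))
      stop("covariance trace must equal total_rms^2", call. = FALSE)
    iso <- max(abs(covariance - diag(rep(total^2 / 3, 3)))) <= 1e-12 * max(total^2, 1)
  }
  structure(list(components = components, total_rms = total,
                 covariance = covariance, isotropic = iso),
            class = "fle_model")
}

#' @export
print.fle_model <- function(x, ...) {
  cat(sprintf("FLE model: total RMS %.4f mm (%s)\n", x$total_rms,
              if (x$isotropic) "isotropic" else "anisotropic"))
  if (length(x$components) > 1) {
    cat("  components (mm):\n")
    print(round(x$components, 4))
  }
  invisible(x)
}

.as_fle <- function(fle) {
  if (inherits(fle, "fle_model")) fle else combine_fle(fle)
}

#' Recover FLE from an observed FRE
#'
#' The expected squared fiducial registration error underestimates the
#' squared fiducial localization error by the factor `(1 - 2/N)` for a
#' rigid fit on `N` fiducials:
#' `<FRE^2> = (1 - 2/N) <FLE^2>`.
#' Inverting this gives an FLE estimate from a measured RMS FRE.
#'
#' @param fre_rms RMS fiducial registration error (mm).
#' @param n_fiducials number of fiducials N (>= 3; at N = 2 the factor
#'   vanishes and the relation is uninformative).
#' @return estimated FLE RMS (mm).
#' @export
#' @examples
#' fle_from_fre(0.5, 4)  # sqrt(0.25 / 0.5) = 0.7071068
fle_from_fre <- function(fre_rms, n_fiducials) {
  if (n_fiducials < 3) stop("n_fiducials must be >= 3", call. = FALSE)
  if (any(fre_rms < 0)) stop("fre_rms must be >= 0", call. = FALSE)
  sqrt(fre_rms^2 / (1 - 2 / n_fiducials))
}

#' Fiducial configuration geometry
#'
#' Derives from a fiducial point set the quantities entering TRE
#' prediction: the centroid, the principal axes of the demeaned
#' configuration, and the RMS distance `f_k` of the fiducials from each
#' principal axis.
#'
#' @param fiducials a [labeled_points()] set (N >= 3) or an N x 3 matrix.
#' @return object of class `fiducial_config`: `positions`, `centroid`,
#'   `axes` (columns = principal axes, descending spread), `f` (per-axis
#'   RMS fiducial distances, mm) and `n`.
#' @export
fiducial_config <- function(fiducials) {
  P <- if (inherits(fiducials, "labeled_points")) .positions(fiducials)
       else as.matrix(fiducials)
  if (nrow(P) < 3L) stop("need >= 3 fiducials", call. = FALSE)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  e <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  # mean squared coordinate along each principal axis
  a2 <- pmax(e$values, 0)
  # f_k = RMS distance from axis k = spread along the other two axes
  f2 <- sum(a2) - a2
  structure(list(positions = P, centroid = ctr, axes = e$vectors,
                 axis_ms = a2, f = sqrt(f2), n = nrow(P)),
            class = "fiducial_config")
}

#' @export
print.fiducial_config <- function(x, ...) {
  cat(sprintf("Fiducial configuration: %d fiducials, centroid (%.2f, %.2f, %.2f) mm\n",
              x$n, x$centroid[1], x$centroid[2], x$centroid[3]))
  cat("  RMS distance from principal axes (mm):",
      paste(sprintf("%.3f", x$f), collapse = " "), "\n")
  invisible(x)
}

#' Predict target registration error
#'
#' Analytic first-order prediction of the RMS target registration error
#' at a point of interest, for a rigid registration on `N` fiducials with
#' isotropic localization noise:
#'
#' `<TRE^2>(r) = <FLE^2>/N * (1 + (1/3) * sum_k d_k^2 / f_k^2)`
#'
#' where `f_k` is the RMS distance of the fiducials from principal axis
#' `k` and `d_k` the distance of the target from that axis.  A full 3x3
#' TRE covariance is additionally computed by first-order propagation of
#' the fiducial noise through the rigid fit (see
#' [predict_tre_covariance()]); its trace equals the squared closed-form
#' RMS for isotropic noise, and the two paths cross-validate each other.
#'
#' @param config a [fiducial_config()] (or a point set coercible to one).
#' @param target length-3 target position (mm).
#' @param fle an [combine_fle()] model (or numeric RMS components).  The
#'   closed form requires isotropic FLE; anisotropic models are served by
#'   the covariance path only.
#' @return object of class `tre_prediction`: `tre_rms` (mm), `covariance`
#'   (3x3 mm^2), `d` (target distances from the principal axes), and the
#'   inputs.
#' @export
predict_tre <- function(config, target, fle) {
  if (!inherits(config, "fiducial_config")) config <- fiducial_config(config)
  target <- vec3(target)
  fle <- .as_fle(fle)
  if (!fle$isotropic)
    stop("closed-form TRE prediction requires isotropic FLE; ",
         "use predict_tre_covariance() for anisotropic noise", call. = FALSE)
  rc <- drop(t(config$axes) %*% (target - config$centroid))
  d2 <- sum(rc^2) - rc^2           # squared distance from each principal axis
  f2 <- config$f^2
  if (any(f2 < 1e-12 & d2 > 1e-12))
    stop("degenerate geometry: fiducials collinear along an axis the ",
         "target is displaced from", call. = FALSE)
  ratio <- ifelse(f2 < 1e-12, 0, d2 / f2)
  tre2 <- fle$total_rms^2 / config$n * (1 + sum(ratio) / 3)
  cov <- predict_tre_covariance(config, target, fle)
  structure(list(target = target, tre_rms = sqrt(tre2), covariance = cov,
                 d = sqrt(d2), f = config$f, n = config$n, fle = fle),
            class = "tre_prediction")
}

#' @export
print.tre_prediction <- function(x, ...) {
  cat(sprintf("Predicted TRE at (%.1f, %.1f, %.1f) mm: %.4f mm RMS\n",
              x$target[1], x$target[2], x$target[3], x$tre_rms))
  cat(sprintf("  N = %d fiducials, FLE %.4f mm; target-axis distances %s mm\n",
              x$n, x$fle$total_rms,
              paste(sprintf("%.1f", x$d), collapse = "/")))
  invisible(x)
}

#' First-order TRE covariance
#'
#' Propagates per-fiducial localization noise (isotropic or anisotropic)
#' through the linearized least-squares rigid fit to a target point.  The
#' displacement at target `r` is, to first order,
#' `d = mean(eps) + domega x (r - centroid)` with the small rotation
#' `domega` solving the demeaned normal equations; `d` is linear in the
#' noise, so its covariance follows directly.  For isotropic FLE the
#' trace equals the squared closed-form RMS of [predict_tre()].
#'
#' @inheritParams predict_tre
#' @return 3x3 covariance matrix (mm^2) of the target displacement.
#' @export
predict_tre_covariance <- function(config, target, fle) {
  if (!inherits(config, "fiducial_config")) config <- fiducial_config(config)
  target <- vec3(target)
  fle <- .as_fle(fle)
  P <- sweep(config$positions, 2, config$centroid)
  n <- nrow(P)
  # normal matrix of the rotational subproblem: sum(|x|^2 I - x x')
  Ginv <- sum(P^2) * diag(3) - crossprod(P)
  sv <- svd(Ginv, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: collinear fiducials", call. = FALSE)
  G <- solve(Ginv)
  Src <- .skew(target - config$centroid)
  Sigma <- fle$covariance
  cov <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    Mi <- diag(3) / n - Src %*% G %*% .skew(P[i, ])
    cov <- cov + Mi %*% Sigma %*% t(Mi)
  }
  (cov + t(cov)) / 2
}

#' Chi-square confidence ellipse of a 2D covariance
#'
#' For a bivariate normal with covariance `cov2d`, the boundary of the
#' `level` confidence region is the ellipse with semi-axes
#' `sqrt(qchisq(level, 2) * lambda_i)` along the covariance eigenvectors.
#' Used to draw lateral-plane uncertainty ellipses around instrument tip
#' and target.
#'
#' @param cov2d 2x2 symmetric PSD covariance (mm^2).
#' @param level confidence level in (0, 1); default 0.95
#'   (`qchisq(0.95, 2) = 5.99146`).
#' @return object of class `confidence_ellipse`: `semi_axes` `(a, b)` with
#'   `a >= b` (mm), `orientation` (radians, direction of the major axis),
#'   `level`.
#' @export
confidence_ellipse <- function(cov2d, level = 0.95) {
  cov2d <- as.matrix(cov2d)
  if (!all(dim(cov2d) == c(2L, 2L)) || max(abs(cov2d - t(cov2d))) > 1e-9)
    stop("cov2d must be 2x2 symmetric", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  e <- eigen(cov2d, symmetric = TRUE)
  if (min(e$values) < -1e-12 * max(abs(e$values), 1))
    stop("cov2d must be positive semidefinite", call. = FALSE)
  lam <- pmax(e$values, 0)
  k <- stats::qchisq(level, df = 2)
  structure(list(semi_axes = sqrt(k * lam),
                 orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level, covariance = cov2d),
            class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% confidence ellipse: semi-axes %.3f / %.3f mm, orientation %.1f deg\n",
              100 * x$level, x$semi_axes[1], x$semi_axes[2],
              x$orientation * 180 / pi))
  invisible(x)
}

#' Is a 2D point inside a confidence ellipse?
#' @param ellipse a [confidence_ellipse()].
#' @param xy 2-vector or M x 2 matrix of points (mm, relative to the
#'   ellipse center).
#' @return logical vector.
#' @export
in_ellipse <- function(ellipse, xy) {
  xy <- if (is.null(dim(xy))) matrix(xy, 1) else as.matrix(xy)
  k <- stats::qchisq(ellipse$level, df = 2)
  q <- rowSums((xy %*% solve(ellipse$covariance)) * xy)
  q <= k
}

#' Monte-Carlo TRE simulation
#'
#' The empirical oracle behind the analytic error models: for each
#' repetition, both sides of the fiducial correspondence are perturbed
#' with independent localization noise, the rigid transform is refit, and
#' the displacement at the target point is recorded.  Noise is split
#' between the two spaces (moving/tracker and fixed/image); by default
#' the full FLE is applied to the fixed side only, matching the classical
#' single-space formulation.
#'
#' @inheritParams predict_tre
#' @param reps number of repetitions.
#' @param seed optional integer; when given, the R session RNG is seeded
#'   so the sample set is exactly reproducible.
#' @param fle_moving optional second [combine_fle()] model for the moving
#'   side; when supplied, `fle` perturbs the fixed side and `fle_moving`
#'   the moving side (their quadrature sum is the effective FLE).
#' @return object of class `mc_tre`: `displacements` (reps x 3, mm),
#'   `tre` (per-rep norms, mm), `tre_rms`, `fre_rms`
#'   (`sqrt(mean(FRE^2))` across reps), `covariance` (empirical 3x3).
#' @export
monte_carlo_tre <- function(config, target, fle, reps = 10000, seed = NULL,
                            fle_moving = NULL) {
  if (!inherits(config, "fiducial_config")) config <- fiducial_config(config)
  target <- vec3(target)
  stopifnot(reps >= 1)
  fle <- .as_fle(fle)
  .check_noncollinear(config$positions)
  zero <- matrix(0, 3, 3)
  chol_f <- if (fle$total_rms > 0) chol(fle$covariance) else zero
  chol_m <- zero
  if (!is.null(fle_moving)) {
    fle_moving <- .as_fle(fle_moving)
    if (fle_moving$total_rms > 0) chol_m <- chol(fle_moving$covariance)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_mc_tre(config$positions, target, chol_m, chol_f, as.integer(reps))
  disp <- out$displacements
  tre <- sqrt(rowSums(disp^2))
  structure(list(displacements = disp, tre = tre,
                 tre_rms = sqrt(mean(tre^2)),
                 fre_rms = sqrt(mean(out$fre2)),
                 fre2 = out$fre2,
                 covariance = crossprod(disp) / reps,
                 reps = reps, seed = seed),
            class = "mc_tre")
}

#' @export
print.mc_tre <- function(x, ...) {
  cat(sprintf("Monte-Carlo TRE: %d reps, RMS %.4f mm (FRE RMS %.4f mm)\n",
              x$reps, x$tre_rms, x$fre_rms))
  invisible(x)
}
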