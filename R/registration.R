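# Paired-point rigid registration (Arun/Umeyama closed form) and automated
# label correspondence by exhaustive permutation search.

# Core least-squares fit mapping rows of X (moving) onto rows of Y (fixed):
# y ~ R x + t.  Centroid demeaning + SVD of the cross-covariance, with the
# reflection corrected by flipping the smallest singular vector so that
# det(R) = +1 always.
.fit_rigid_core <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)               # sum x_c y_c'
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - drop(R %*% cx)
  resid <- Yc - Xc %*% t(R)            # equals Y - (X R' + t)
  list(rotation = R, translation = t, residuals = resid)
}

.check_noncollinear <- function(P, what = "fiducials") {
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: ", what, " are (near-)collinear", call. = FALSE)
  invisible(TRUE)
}

#' Fit a rigid transform between corresponding labeled point sets
#'
#' Least-squares paired-point registration: the proper rigid motion
#' minimizing the sum of squared distances between `transform(moving)`
#' and `fixed` over corresponding labels (closed form via SVD of the
#' demeaned cross-covariance; a reflection optimum is corrected to the
#' best proper rotation).  The fiducial registration error (FRE) is
#' reported as the RMS of the per-fiducial residual norms.
#'
#' @param moving,fixed [labeled_points()] sets sharing >= 3 labels in a
#'   non-collinear configuration (e.g. tracked sensor positions and image
#'   fiducial centroids).
#' @param mapping optional named character vector mapping moving labels to
#'   fixed labels (as returned by [match_correspondence()]); by default
#'   labels are matched by name.
#' @return an object of class `rigid_registration` with elements
#'   `transform` (a [rigid_transform()]), `fre_rms` (mm),
#'   `residuals` (named per-fiducial residual norms, mm) and `n`.
#' @seealso [match_correspondence()] to find the label pairing first.
#' @export
#' @examples
#' set.seed(1)
#' fids <- labeled_points(paste0("F", 1:4), matrix(rnorm(12, sd = 10), 4),
#'                        frame = "image")
#' fit <- fit_rigid(fids, fids)
#' fit$fre_rms   # 0: identical sets
fit_rigid <- function(moving, fixed, mapping = NULL) {
  stopifnot(inherits(moving, "labeled_points"), inherits(fixed, "labeled_points"))
  if (is.null(mapping)) {
    common <- intersect(moving$label, fixed$label)
    mapping <- stats::setNames(common, common)
  } else if (inherits(mapping, "fiducial_correspondence")) {
    mapping <- mapping$mapping
  }
  if (length(mapping) < 3L)
    stop("degenerate geometry: need >= 3 corresponding pairs", call. = FALSE)
  X <- .positions(moving)[names(mapping), , drop = FALSE]
  Y <- .positions(fixed)[mapping, , drop = FALSE]
  if (anyNA(X) || anyNA(Y))
    stop("mapping refers to labels absent from the point sets", call. = FALSE)
  .check_noncollinear(X, "moving points")
  fit <- .fit_rigid_core(X, Y)
  rn <- sqrt(rowSums(fit$residuals^2))
  names(rn) <- names(mapping)
  structure(list(
    transform = rigid_transform(fit$rotation, fit$translation),
    fre_rms = sqrt(mean(rn^2)),
    residuals = rn,
    mapping = mapping,
    n = length(mapping),
    frames = c(moving = attr(moving, "frame"), fixed = attr(fixed, "frame"))
  ), class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("Rigid registration: %d fiducial pairs (%s -> %s)\n", x$n,
              x$frames[["moving"]] %||% "?", x$frames[["fixed"]] %||% "?"))
  cat(sprintf("  FRE (RMS): %.4f mm\n", x$fre_rms))
  invisible(x)
}

#' @export
summary.rigid_registration <- function(object, ...) {
  cat(sprintf("Rigid registration on %d fiducial pairs\n", object$n))
  cat(sprintf("  FRE (RMS over fiducials): %.4f mm\n", object$fre_rms))
  cat("  per-fiducial residuals (mm):\n")
  print(round(object$residuals, 4))
  print(object$transform)
  invisible(object)
}

#' @export
residuals.rigid_registration <- function(object, ...) object$residuals

#' @export
coef.rigid_registration <- function(object, ...) {
  c(object$transform$translation, fre_rms = object$fre_rms)
}

#' Map points through a fitted registration
#' @param object a `rigid_registration`.
#' @param newdata points (vector, matrix or [labeled_points()]).
#' @param ... unused.
#' @export
predict.rigid_registration <- function(object, newdata, ...) {
  apply_transform(object$transform, newdata)
}

#' Automated fiducial label correspondence
#'
#' Finds the pairing of patient-space sensor labels to image-space
#' fiducial labels that minimizes the FRE of the rigid fit, by exhaustive
#' search over all permutations (closed-form fit per candidate; feasible
#' for N <= 8).  A near-tie between the best and second-best permutation
#' signals a (near-)symmetric fiducial configuration in which labeling is
#' ambiguous, and is raised as an error rather than silently resolved.
#'
#' @param image_fids,patient_fids [labeled_points()] with 3..8 points each.
#' @param ambiguity_margin minimum FRE gap (mm) between best and runner-up
#'   permutation; below it an ambiguity error is thrown.  Default 0.1 mm.
#' @return an object of class `fiducial_correspondence`: `mapping` (named
#'   character vector, patient label -> image label) and `residual_rms` (mm).
#' @export
match_correspondence <- function(image_fids, patient_fids,
                                 ambiguity_margin = 0.1) {
  stopifnot(inherits(image_fids, "labeled_points"),
            inherits(patient_fids, "labeled_points"))
  ni <- nrow(image_fids); np <- nrow(patient_fids)
  n <- min(ni, np)
  if (n < 3L || max(ni, np) > 8L)
    stop("correspondence search needs 3..8 fiducials per side", call. = FALSE)
  P <- .positions(patient_fids)
  Im <- .positions(image_fids)
  # pair every point of the smaller set with an ordered arrangement of the
  # larger set; with equal counts this is the full permutation search
  if (np <= ni) {
    small <- P; big <- Im; small_lab <- patient_fids$label
    big_lab <- image_fids$label; patient_small <- TRUE
  } else {
    small <- Im; big <- P; small_lab <- image_fids$label
    big_lab <- patient_fids$label; patient_small <- FALSE
  }
  .check_noncollinear(small, "fiducials")
  arr <- .arrangements(nrow(big), nrow(small))
  fre <- apply(arr, 1, function(idx) {
    f <- if (patient_small)
      .fit_rigid_core(small, big[idx, , drop = FALSE])
    else
      .fit_rigid_core(big[idx, , drop = FALSE], small)
    sqrt(mean(rowSums(f$residuals^2)))
  })
  o <- order(fre)
  if (length(fre) > 1 && fre[o[2]] - fre[o[1]] < ambiguity_margin)
    stop(sprintf(paste0("ambiguous fiducial configuration: best and ",
                        "second-best pairings differ by %.4f mm FRE ",
                        "(< %.4f mm margin)"),
                 fre[o[2]] - fre[o[1]], ambiguity_margin), call. = FALSE)
  best <- arr[o[1], ]
  mapping <- if (patient_small)
    stats::setNames(big_lab[best], small_lab)
  else
    stats::setNames(small_lab, big_lab[best])
  structure(list(mapping = mapping, residual_rms = fre[o[1]]),
            class = "fiducial_correspondence")
}

#' @export
print.fiducial_correspondence <- function(x, ...) {
  cat("Fiducial correspondence (patient -> image):\n")
  cat(paste0("  ", names(x$mapping), " -> ", x$mapping, collapse = "\n"), "\n")
  cat(sprintf("  FRE at optimum: %.4f mm\n", x$residual_rms))
  invisible(x)
}

# All ordered arrangements of k items out of 1..m, as rows
# (m <= 8 => at most 8! = 40320 rows).
.arrangements <- function(m, k) {
  if (k == 0L) return(matrix(integer(0), 1, 0))
  if (k == 1L) return(matrix(seq_len(m), m, 1))
  sub <- .arrangements(m - 1L, k - 1L)
  out <- matrix(0L, m * nrow(sub), k)
  r <- 0L
  for (first in seq_len(m)) {
    rows <- nrow(sub)
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    out[r + seq_len(rows), 1] <- first
    out[r + seq_len(rows), -1] <- rest
    r <- r + rows
  }
  out
}

# Back-compat helper used in tests: full permutations of 1..n.
.permutations <- function(n) .arrangements(n, n)
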