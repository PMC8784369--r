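#' @useDynLib surgnav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Numerical tolerance used for all orthonormality / unit-norm validation.
.GEOM_TOL <- 1e-9

#' Create a 3D point or vector
#'
#' Coordinates are lengths in millimetres throughout the package (the CT
#' world frame, LPS orientation, is the reference frame; see the methods
#' vignette).  This is a thin validator around a plain numeric vector of
#' length 3.
#'
#' @param x,y,z coordinates in mm, or `x` alone a numeric vector of length 3.
#' @return a named numeric vector `c(x=, y=, z=)`.
#' @export
#' @examples
#' vec3(1, 2, 3)
vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  if (length(v) != 3L || !all(is.finite(v)))
    stop("vec3: need 3 finite components", call. = FALSE)
  names(v) <- c("x", "y", "z")
  v
}

.unit <- function(v, what = "direction") {
  n <- sqrt(sum(v^2))
  if (n < .GEOM_TOL) stop(what, ": zero-norm vector", call. = FALSE)
  v / n
}

.assert_unit <- function(v, what = "normal") {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-9)
    stop(what, " must have unit norm (within 1e-9)", call. = FALSE)
  invisible(v)
}

.is_rotation <- function(R, tol = .GEOM_TOL) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && det(R) > 0
}

#' Rigid transform (proper rotation + translation)
#'
#' Maps a point `p` to `R %*% p + t`.  Used for frame changes such as
#' patient (tracker) space to image space.  The rotation must be
#' orthonormal with determinant +1 within 1e-9: reflections are rejected,
#' since anatomy is never mirrored by a registration.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- vec3(translation)
  if (!.is_rotation(rotation))
    stop("rotation must be proper orthonormal (R'R = I, det = +1, within 1e-9)",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.4f", x$translation), collapse = " "),
      "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or N x 3 matrix / data frame of points (mm).
#' @return object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) {
    p <- vec3(points)
    return(vec3(drop(transform$rotation %*% p) + transform$translation))
  }
  m <- as.matrix(points[, intersect(c("x", "y", "z"), colnames(points)),
                        drop = FALSE])
  if (ncol(m) != 3L) m <- as.matrix(points)
  out <- sweep(m %*% t(transform$rotation), 2, transform$translation, "+")
  if (is.data.frame(points)) {
    points[, c("x", "y", "z")] <- out
    points
  } else out
}

#' Compose two rigid transforms
#'
#' `compose(T1, T2)` is the transform applying `T2` first, then `T1`
#' (matrix convention: `T1 %.% T2`).
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @export
compose_transforms <- function(t1, t2) {
  stopifnot(inherits(t1, "rigid_transform"), inherits(t2, "rigid_transform"))
  rigid_transform(t1$rotation %*% t2$rotation,
                  drop(t1$rotation %*% t2$translation) + t1$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Tracking streams conventionally ship orientations as quaternions
#' `(qw, qx, qy, qz)`; they are normalized before conversion, so mild
#' drift in recorded streams is tolerated.
#'
#' @param q numeric length 4, `(qw, qx, qy, qz)`.
#' @return 3x3 proper rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  stopifnot(length(q) == 4L, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero-norm quaternion", call. = FALSE)
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

.skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' Random proper rotation (uniform over SO(3))
#'
#' Draws a unit quaternion uniformly on S3 and converts it.  Uses the
#' R session RNG, so results are reproducible under `set.seed()`.
#'
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rotation(q / sqrt(sum(q^2)))
}

# ---- labeled point sets -----------------------------------------------------

#' Labeled point set
#'
#' An ordered set of labeled 3D positions in one coordinate frame:
#' fiducial centroids in image space, tracked sensor positions in patient
#' space, screw check-points, and so on.  Stored as a data frame with
#' columns `label, x, y, z` (mm) and a `frame` attribute naming the space.
#'
#' @param labels character vector of unique labels.
#' @param positions N x 3 matrix of positions (mm).
#' @param frame name of the coordinate space (e.g. `"image"`, `"patient"`).
#' @return a data frame of class `labeled_points`.
#' @export
labeled_points <- function(labels, positions, frame = "world") {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L)
  labels <- as.character(labels)
  if (length(labels) != nrow(positions))
    stop("labels and positions disagree in length", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (nrow(positions) < 1L) stop("need at least one point", call. = FALSE)
  if (!all(is.finite(positions))) stop("positions must be finite", call. = FALSE)
  out <- data.frame(label = labels, x = positions[, 1], y = positions[, 2],
                    z = positions[, 3], stringsAsFactors = FALSE)
  attr(out, "frame") <- frame
  class(out) <- c("labeled_points", "data.frame")
  out
}

#' @export
print.labeled_points <- function(x, ...) {
  cat(sprintf("Labeled point set: %d point(s), frame '%s' (mm)\n",
              nrow(x), attr(x, "frame") %||% "?"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.positions <- function(ps) {
  m <- as.matrix(ps[, c("x", "y", "z")])
  rownames(m) <- ps$label
  m
}

#' Read / write labeled point sets as CSV
#'
#' Plain CSV with header `label,x,y,z`, coordinates in mm.
#'
#' @param path file path.
#' @param frame coordinate-frame tag attached on read.
#' @export
read_points_csv <- function(path, frame = "world") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("point CSV must have header label,x,y,z", call. = FALSE)
  labeled_points(d$label, as.matrix(d[, c("x", "y", "z")]), frame = frame)
}

#' @rdname read_points_csv
#' @param points a [labeled_points()] set.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("label", "x", "y", "z")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a rigid transform as JSON
#'
#' Stored as a 4x4 row-major homogeneous matrix under the key `"matrix"`.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @export
write_transform_json <- function(transform, path) {
  H <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = H), path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  H <- jsonlite::fromJSON(path)$matrix
  H <- matrix(as.numeric(H), 4, 4, byrow = FALSE)
  # jsonlite round-trips a rowmajor-written matrix back to the same layout
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}
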