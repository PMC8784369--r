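# Pivot calibration: estimate the fixed tip offset of a tracked instrument
# from poses recorded while pivoting the instrument about a stationary
# physical point.

#' Pivot calibration of a tracked instrument
#'
#' While the tip rests on a fixed point and the instrument is pivoted,
#' every pose satisfies `R_i %*% t_tip + p_i = p_pivot`, with `t_tip` the
#' tip offset in the sensor frame and `p_pivot` the stationary point in
#' the tracker frame.  Stacking all poses gives an overdetermined linear
#' system in the 6 unknowns `(t_tip, p_pivot)`, solved in one shot by
#' least squares.  Rotation diversity is required: if the instrument is
#' only rotated about (nearly) a single axis the system is rank-deficient
#' and the unconstrained tip direction is reported in the error.
#'
#' @param rotations list of 3x3 proper rotation matrices (or a 3x3xK
#'   array), sensor orientation per sample.
#' @param positions K x 3 matrix of sensor positions (mm).
#' @param max_condition condition-number threshold of the stacked design
#'   matrix above which the pose set is declared degenerate (default 1e6).
#' @return object of class `pivot_calibration`: `tip_offset` (mm, sensor
#'   frame), `pivot_point` (mm, tracker frame), `residual_rms` (mm), `n`.
#' @export
#' @examples
#' set.seed(7)
#' tip <- c(0, 0, 150)
#' Rs <- replicate(50, random_rotation(), simplify = FALSE)
#' pivot <- c(10, -5, 30)
#' pos <- t(vapply(Rs, function(R) pivot - drop(R %*% tip), numeric(3)))
#' pivot_calibrate(Rs, pos)
pivot_calibrate <- function(rotations, positions, max_condition = 1e6) {
  if (is.array(rotations) && length(dim(rotations)) == 3L)
    rotations <- lapply(seq_len(dim(rotations)[3]),
                        function(k) rotations[, , k])
  positions <- as.matrix(positions)
  k <- length(rotations)
  if (k < 3L || nrow(positions) != k)
    stop("need >= 3 pose samples with matching rotations and positions",
         call. = FALSE)
  for (R in rotations)
    if (!.is_rotation(R, tol = 1e-6))
      stop("all rotations must be proper orthonormal", call. = FALSE)
  A <- matrix(0, 3 * k, 6)
  b <- numeric(3 * k)
  for (i in seq_len(k)) {
    r <- 3 * (i - 1) + 1:3
    A[r, 1:3] <- rotations[[i]]
    A[r, 4:6] <- -diag(3)
    b[r] <- -positions[i, ]
  }
  s <- svd(A)
  if (s$d[1] / s$d[6] > max_condition) {
    # the null direction of the tip-offset block names what is unconstrained
    dir <- s$v[1:3, 6]
    dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
    stop(sprintf(paste0("degenerate pose set: rotations do not constrain the ",
                        "tip offset along direction (%.2f, %.2f, %.2f); ",
                        "pivot about more than one axis"),
                 dir[1], dir[2], dir[3]), call. = FALSE)
  }
  x <- drop(s$v %*% (crossprod(s$u, b) / s$d))
  res <- matrix(A %*% x - b, ncol = 3, byrow = TRUE)
  structure(list(tip_offset = vec3(x[1:3]), pivot_point = vec3(x[4:6]),
                 residual_rms = sqrt(mean(rowSums(res^2))), n = k),
            class = "pivot_calibration")
}

#' @export
print.pivot_calibration <- function(x, ...) {
  cat(sprintf("Pivot calibration from %d poses\n", x$n))
  cat(sprintf("  tip offset (sensor frame): (%.3f, %.3f, %.3f) mm, |t| = %.3f mm\n",
              x$tip_offset[1], x$tip_offset[2], x$tip_offset[3],
              sqrt(sum(x$tip_offset^2))))
  cat(sprintf("  pivot point (tracker frame): (%.3f, %.3f, %.3f) mm\n",
              x$pivot_point[1], x$pivot_point[2], x$pivot_point[3]))
  cat(sprintf("  residual RMS: %.4f mm\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.pivot_calibration <- function(object, ...) {
  c(tip = object$tip_offset, pivot = object$pivot_point)
}

#' Read a tracked pose stream from CSV
#'
#' Format: header `t,qw,qx,qy,qz,x,y,z`; time in seconds, unit quaternion
#' `(qw,qx,qy,qz)` (normalized on read), position in mm.
#'
#' @param path CSV file path.
#' @return list with `time` (s), `rotations` (list of 3x3 matrices),
#'   `positions` (K x 3, mm).
#' @export
read_pose_stream <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "qw", "qx", "qy", "qz", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("pose CSV must have header t,qw,qx,qy,qz,x,y,z", call. = FALSE)
  rots <- lapply(seq_len(nrow(d)), function(i)
    quat_to_rotation(as.numeric(d[i, c("qw", "qx", "qy", "qz")])))
  list(time = d$t, rotations = rots,
       positions = as.matrix(d[, c("x", "y", "z")]))
}
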