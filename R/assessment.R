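# Postoperative placement-error decomposition and the summary statistics
# used to report navigation accuracy.

#' Placement error of an achieved vs planned position
#'
#' Decomposes the 3D displacement between achieved and planned positions
#' (CT frame, mm) into the Euclidean distance, a 2D "lateral" error in
#' the plane lying on the electrode surface, and a 1D "depth" error
#' orthogonal to that plane: with `c = achieved - planned` and unit plane
#' normal `n`, `depth = |c . n|` and `lateral = |c - (c . n) n|`, so
#' `lateral^2 + depth^2 = euclidean^2`.
#'
#' @param planned,achieved positions (mm).
#' @param plane_normal unit normal (within 1e-9) of the electrode plane.
#' @return object of class `placement_error`: `components` (mm),
#'   `euclidean`, `lateral`, `depth`.
#' @export
#' @examples
#' placement_error(c(0, 0, 0), c(1.0, 1.2, 0.2), c(0, 0, 1))
placement_error <- function(planned, achieved, plane_normal) {
  planned <- vec3(planned); achieved <- vec3(achieved)
  plane_normal <- vec3(plane_normal)
  .assert_unit(plane_normal, "plane_normal")
  comp <- achieved - planned
  depth_signed <- sum(comp * plane_normal)
  lat_vec <- comp - depth_signed * plane_normal
  structure(list(components = comp, euclidean = sqrt(sum(comp^2)),
                 lateral = sqrt(sum(lat_vec^2)), depth = abs(depth_signed),
                 plane_normal = plane_normal),
            class = "placement_error")
}

#' @export
print.placement_error <- function(x, ...) {
  cat(sprintf("Placement error: [%s] mm; Euclidean %.2f, lateral %.2f, depth %.2f mm\n",
              paste(sprintf("%.1f", x$components), collapse = ", "),
              x$euclidean, x$lateral, x$depth))
  invisible(x)
}

#' Mean and sample standard deviation summary
#'
#' The mean +/- sigma summary used throughout accuracy reporting: the
#' arithmetic mean and the sample standard deviation (n - 1 denominator).
#' `NA` entries (e.g. lost screws) are excluded.
#'
#' @param values numeric vector (mm).
#' @return object of class `summary_stat`: `mean`, `sd` (NA when n < 2),
#'   `n` (non-NA count).
#' @export
#' @examples
#' summary_stat(c(NA, 4.0, 2.1, 1.6))  # 2.56 +/- 1.27 mm
summary_stat <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("no non-missing values to summarize", call. = FALSE)
  structure(list(mean = mean(values),
                 sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
                 n = length(values)),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.2f +/- %s mm (n = %d)\n", x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd), x$n))
  invisible(x)
}

#' Measured TRE on implanted check screws
#'
#' Each skull-implanted screw is touched one or more times with a
#' calibrated tracked pointer; every touch is mapped into image space
#' through the registration and compared with the screw position detected
#' in the image.  The per-screw TRE is the mean distance over its
#' touches; the summary is mean +/- sample sd over screws.
#'
#' @param touches data frame with columns `label, x, y, z`: patient-space
#'   pointer positions, one row per touch (labels repeat across touches
#'   of the same screw).
#' @param image_screws [labeled_points()] of screw positions in image
#'   space.
#' @param transform [rigid_transform()] (or `rigid_registration`) mapping
#'   patient to image space.
#' @return object of class `screw_tre`: `per_screw` (named mm vector),
#'   `summary` (a [summary_stat()]), `n_touches`.
#' @export
screw_tre <- function(touches, image_screws, transform) {
  if (inherits(transform, "rigid_registration")) transform <- transform$transform
  stopifnot(inherits(transform, "rigid_transform"),
            inherits(image_screws, "labeled_points"))
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(touches)))
    stop("touches must have columns label,x,y,z", call. = FALSE)
  if (!all(touches$label %in% image_screws$label))
    stop("touch labels missing from image screw set: ",
         paste(setdiff(touches$label, image_screws$label), collapse = ", "),
         call. = FALSE)
  S <- .positions(image_screws)
  mapped <- apply_transform(transform,
                            as.matrix(touches[, c("x", "y", "z")]))
  dists <- sqrt(rowSums((mapped - S[touches$label, , drop = FALSE])^2))
  per_screw <- tapply(dists, touches$label, mean)
  per_screw <- per_screw[unique(touches$label)]   # keep touch order
  structure(list(per_screw = per_screw,
                 summary = summary_stat(as.numeric(per_screw)),
                 n_touches = table(touches$label)),
            class = "screw_tre")
}

#' @export
print.screw_tre <- function(x, ...) {
  cat("Measured TRE on screws (mm):\n")
  print(round(x$per_screw, 3))
  cat("  summary: "); print(x$summary)
  invisible(x)
}

#' Round half away from zero
#'
#' Reporting convention for printed tables (R's `round()` rounds half to
#' even); raw doubles are always retained alongside.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
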