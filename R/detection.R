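# Sub-voxel localization of spherical titanium fiducials in CT-like
# volumes, a synthetic phantom generator, and pre/post fiducial stability
# assessment.

#' CT-like volume container
#'
#' A voxel intensity array with an index-to-world affine.  World
#' coordinates are mm in an LPS frame; array element `[i, j, k]` has its
#' center at `affine %*% c(i - 1, j - 1, k - 1, 1)` (0-based indices,
#' voxel centers at integer indices).
#'
#' @param data 3D numeric array of intensities (CT-like arbitrary units).
#' @param affine 4x4 index-to-world matrix (mm); its 3x3 block must be
#'   nonsingular.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(data, affine) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine 3x3 block must be nonsingular", call. = FALSE)
  structure(list(data = data, affine = affine, dim = dim(data)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  sp <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("CT-like volume: %s voxels, spacing %.3f x %.3f x %.3f mm\n",
              paste(x$dim, collapse = " x "), sp[1], sp[2], sp[3]))
  invisible(x)
}

# 0-based voxel indices (rows) -> world mm
.index_to_world <- function(vol, idx0) {
  idx0 <- if (is.null(dim(idx0))) matrix(idx0, 1) else as.matrix(idx0)
  sweep(idx0 %*% t(vol$affine[1:3, 1:3]), 2, vol$affine[1:3, 4], "+")
}

.world_to_index <- function(vol, world) {
  world <- if (is.null(dim(world))) matrix(world, 1) else as.matrix(world)
  inv <- solve(vol$affine[1:3, 1:3])
  sweep(world, 2, vol$affine[1:3, 4]) %*% t(inv)
}

#' Write / read a volume as NIfTI
#'
#' The package world frame is LPS; NIfTI stores RAS xforms, so the first
#' two affine rows are sign-flipped on write and restored on read.
#'
#' @param vol a [ct_volume()].
#' @param path `.nii` or `.nii.gz` path.
#' @export
write_volume_nifti <- function(vol, path) {
  flip <- diag(c(-1, -1, 1, 1))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(flip %*% vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  flip <- diag(c(-1, -1, 1, 1))
  aff <- flip %*% structure(RNifti::xform(img), dim = c(4, 4))
  ct_volume(array(as.numeric(img), dim = dim(img)), aff)
}

#' Generate a synthetic fiducial phantom volume
#'
#' Rasterizes spheres of constant intensity into a CT-like volume with
#' partial-volume edge weighting (per-voxel sphere overlap fraction
#' approximated by supersampling), then adds white Gaussian noise.
#' Deterministic for a given seed.  Emulates titanium spherical fiducials
#' on a soft-tissue background.
#'
#' @param centers N x 3 matrix or [labeled_points()] of sphere centers
#'   (world mm).
#' @param radius sphere radius (mm); default 2 (a 4 mm sphere).
#' @param spacing voxel spacing (mm); default `c(0.43, 0.43, 0.6)`, a
#'   typical temporal-bone CT protocol.
#' @param margin padding around the centers' bounding box (mm).
#' @param background,foreground intensities (arbitrary CT-like units).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed optional RNG seed for the noise.
#' @param supersample sub-divisions per voxel edge for the partial-volume
#'   fractions (default 3, i.e. 27 samples per voxel).
#' @return list with `volume` (a [ct_volume()]) and `truth`
#'   (a [labeled_points()] of the sphere centers, frame `"image"`).
#' @export
generate_phantom <- function(centers, radius = 2,
                             spacing = c(0.43, 0.43, 0.6),
                             margin = 6, background = 40, foreground = 1000,
                             noise_sd = 0, seed = NULL, supersample = 3L) {
  C <- if (inherits(centers, "labeled_points")) .positions(centers)
       else as.matrix(centers)
  labels <- if (inherits(centers, "labeled_points")) centers$label
            else paste0("F", seq_len(nrow(C)))
  if (nrow(C) > 1) {
    dd <- as.matrix(stats::dist(C))
    diag(dd) <- Inf
    if (min(dd) < 2 * radius)
      stop("spheres overlap: minimum center distance ", round(min(dd), 2),
           " mm < diameter ", 2 * radius, " mm", call. = FALSE)
  }
  if (margin < radius + 2 * max(spacing))
    stop("margin must leave >= radius + 2 voxels around every center",
         call. = FALSE)
  origin <- apply(C, 2, min) - margin
  extent <- apply(C, 2, max) + margin - origin
  dims <- pmax(ceiling(extent / spacing) + 1L, 8L)
  affine <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  arr <- array(background, dim = dims)

  s <- as.integer(supersample)
  off <- ((seq_len(s) - 0.5) / s - 0.5)        # sub-voxel offsets in [-0.5, 0.5)
  sub <- as.matrix(expand.grid(dx = off * spacing[1], dy = off * spacing[2],
                               dz = off * spacing[3]))
  for (f in seq_len(nrow(C))) {
    ctr <- C[f, ]
    idx_c <- (ctr - origin) / spacing          # 0-based index of the center
    half <- ceiling(radius / spacing) + 1L
    rng <- lapply(1:3, function(a)
      max(0L, floor(idx_c[a]) - half[a]):min(dims[a] - 1L, ceiling(idx_c[a]) + half[a]))
    g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    vox_w <- sweep(sweep(g, 2, spacing, "*"), 2, origin, "+")
    d2c <- sweep(vox_w, 2, ctr)
    # fraction of supersample points inside the sphere, per voxel
    frac <- numeric(nrow(g))
    r2 <- radius^2
    dist2 <- rowSums(d2c^2)
    vox_diag <- sqrt(sum((spacing / 2)^2))
    inner <- dist2 <= (radius - vox_diag)^2
    outer <- dist2 >= (radius + vox_diag)^2
    frac[inner] <- 1
    edge <- which(!inner & !outer)
    if (length(edge)) {
      for (e in edge) {
        pts <- sweep(sub, 2, d2c[e, ], "+")
        frac[e] <- mean(rowSums(pts^2) <= r2)
      }
    }
    lin <- 1L + g[, 1] + g[, 2] * dims[1] + g[, 3] * dims[1] * dims[2]
    arr[lin] <- pmax(arr[lin], background + (foreground - background) * frac)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    arr <- arr + array(stats::rnorm(prod(dims), sd = noise_sd), dim = dims)
  }
  list(volume = ct_volume(arr, affine),
       truth = labeled_points(labels, C, frame = "image"))
}

# Otsu threshold on a 256-bin intensity histogram (maximizes between-class
# variance).  Applied to the whole 3D volume at once.
.otsu_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  sb2 <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

#' Detect spherical fiducials in a CT-like volume
#'
#' Pipeline: global intensity threshold (Otsu by default; titanium is far
#' brighter than tissue) -> 26-connected components -> filter by voxel
#' count and equivalent-diameter band -> intensity-weighted sub-voxel
#' centroid mapped to world mm.  Components touching the volume border
#' are excluded.  Results are sorted by descending peak intensity.
#'
#' @param vol a [ct_volume()].
#' @param threshold intensity threshold; `NULL` (default) uses Otsu's
#'   method on the volume histogram.
#' @param min_voxels minimum component size (voxels); rejects noise
#'   specks.  Default 5.
#' @param diameter_range accepted equivalent-diameter band (mm); default
#'   `c(2, 8)` around a 4 mm sphere.
#' @return a [labeled_points()] (frame `"image"`, labels `"F1"...` in
#'   detection order) with extra columns `voxel_count`,
#'   `equivalent_diameter` and `peak_intensity`.  Zero rows (with a
#'   warning) when nothing passes the filters.
#' @export
detect_fiducials <- function(vol, threshold = NULL, min_voxels = 5L,
                             diameter_range = c(2, 8)) {
  stopifnot(inherits(vol, "ct_volume"))
  v <- vol$data
  thr <- if (is.null(threshold)) .otsu_threshold(as.numeric(v)) else threshold
  fg <- which(v > thr)
  dims <- dim(v)
  voxvol <- abs(det(vol$affine[1:3, 1:3]))
  empty <- labeled_points("none", matrix(0, 1, 3))[0, ]
  attr(empty, "frame") <- "image"
  empty$voxel_count <- integer(0)
  empty$equivalent_diameter <- numeric(0)
  empty$peak_intensity <- numeric(0)
  if (!length(fg)) {
    warning("no voxels above threshold ", signif(thr, 4))
    return(empty)
  }
  comp <- .connected_components_26(fg, dims)
  rows <- list()
  for (cid in seq_along(comp)) {
    lin <- comp[[cid]]
    if (length(lin) < min_voxels) next
    idx <- arrayInd(lin, dims)                # 1-based
    if (any(idx == 1L) ||
        any(sweep(idx, 2, dims, "==")))  {    # touches the border
      next
    }
    eq_d <- 2 * (3 * length(lin) * voxvol / (4 * pi))^(1 / 3)
    if (eq_d < diameter_range[1] || eq_d > diameter_range[2]) next
    w <- v[lin] - thr
    ctr0 <- colSums((idx - 1L) * w) / sum(w)  # 0-based sub-voxel centroid
    world <- drop(.index_to_world(vol, ctr0))
    rows[[length(rows) + 1L]] <- data.frame(
      x = world[1], y = world[2], z = world[3],
      voxel_count = length(lin), equivalent_diameter = eq_d,
      peak_intensity = max(v[lin]))
  }
  if (!length(rows)) {
    warning("no fiducial candidates passed size/diameter filters")
    return(empty)
  }
  d <- do.call(rbind, rows)
  d <- d[order(-d$peak_intensity), , drop = FALSE]
  out <- labeled_points(paste0("F", seq_len(nrow(d))),
                        as.matrix(d[, c("x", "y", "z")]), frame = "image")
  out$voxel_count <- d$voxel_count
  out$equivalent_diameter <- d$equivalent_diameter
  out$peak_intensity <- d$peak_intensity
  out
}

# 26-connected components over foreground linear indices (1-based) of a
# 3D array; returns a list of linear-index vectors.  Union-find on the
# foreground voxels only, so cost scales with the foreground size.
.connected_components_26 <- function(fg, dims) {
  nxy <- dims[1] * dims[2]
  pos <- seq_along(fg)
  lookup <- structure(pos, names = fg)        # linear index -> node id
  parent <- pos
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- arrayInd(fg, dims)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[1:13, , drop = FALSE]          # forward half of the 26-neighborhood
  for (o in seq_len(nrow(offs))) {
    ni <- idx[, 1] + offs[o, 1]
    nj <- idx[, 2] + offs[o, 2]
    nk <- idx[, 3] + offs[o, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
          nk >= 1L & nk <= dims[3]
    nlin <- ni[ok] + (nj[ok] - 1L) * dims[1] + (nk[ok] - 1L) * nxy
    hit <- lookup[as.character(nlin)]
    src <- pos[ok][!is.na(hit)]
    dst <- hit[!is.na(hit)]
    for (m in seq_along(src)) {
      a <- find(src[m]); b <- find(dst[m])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(pos, find, integer(1))
  split(fg, root)
}

#' Pre/post fiducial stability assessment
#'
#' Quantifies fiducial (e.g. nasopharyngeal marker) migration between two
#' scans: the post set is best-fit rigidly aligned onto the pre set
#' (removing head repositioning, which would otherwise be conflated with
#' marker slippage), then per-fiducial residual norms are reported with
#' their mean and sample standard deviation.
#'
#' @param pre,post [labeled_points()] sets sharing the same labels
#'   (N >= 3).
#' @return object of class `fiducial_stability`: `deviations` (named, mm),
#'   `mean`, `sd` (sample, n-1), `fit` (the `rigid_registration`).
#' @export
assess_stability <- function(pre, post) {
  stopifnot(inherits(pre, "labeled_points"), inherits(post, "labeled_points"))
  if (!setequal(pre$label, post$label))
    stop("pre and post sets must carry the same labels", call. = FALSE)
  fit <- fit_rigid(post, pre)
  dev <- fit$residuals
  structure(list(deviations = dev, mean = mean(dev),
                 sd = stats::sd(dev), fit = fit),
            class = "fiducial_stability")
}

#' @export
print.fiducial_stability <- function(x, ...) {
  cat(sprintf("Fiducial stability over %d markers: %.3f +/- %.3f mm (mean +/- sd)\n",
              length(x$deviations), x$mean, x$sd))
  print(round(x$deviations, 4))
  invisible(x)
}
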