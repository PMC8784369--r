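# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no binary fixtures.

# a generic (distinct pairwise distances, non-collinear) fiducial cluster
make_cluster <- function(n = 4, extent = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    P <- matrix(stats::runif(3 * n, -extent / 2, extent / 2), n)
    sv <- svd(sweep(P, 2, colMeans(P)), nu = 0, nv = 0)$d
    dd <- as.matrix(stats::dist(P)); diag(dd) <- Inf
    # non-collinear and well separated; generic draws have distinct
    # pairwise distances, so labeling is unambiguous
    if (sv[2] > 0.2 * extent && min(dd) > 0.15 * extent) break
  }
  labeled_points(paste0("F", seq_len(n)), P, frame = "image")
}

random_rigid <- function(trans_scale = 50) {
  rigid_transform(random_rotation(), stats::runif(3, -trans_scale, trans_scale))
}

# axis-aligned instrument pose helper
pose_at <- function(tip = c(0, 0, 0), axes = diag(3)) instrument_pose(tip, axes)

# pivot-calibration pose generator: rotations within a cone about z plus a
# random roll, tip resting on a fixed pivot point
make_pivot_poses <- function(tip, pivot, k = 200, cone_deg = 60,
                             noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rots <- replicate(k, {
    ax <- c(rnorm(2, sd = sin(cone_deg * pi / 360)), 1)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    K <- surgnav:::.skew(ax)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K   # Rodrigues
  }, simplify = FALSE)
  pos <- t(vapply(rots, function(R) pivot - drop(R %*% tip), numeric(3)))
  if (noise_sd > 0) pos <- pos + matrix(rnorm(3 * k, sd = noise_sd), k)
  list(rotations = rots, positions = pos)
}

expect_near <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max|%s - expected| = %g <= %g",
                              deparse(substitute(object)),
                              max(abs(object - expected)), tol))
}
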