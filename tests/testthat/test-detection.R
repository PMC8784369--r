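phantom_centers <- rbind(c(0, 0, 0), c(12, 3, -2), c(5, 11, 4), c(-4, 8, 9))

test_that("phantoms rasterize 4 spheres with ground truth and are seed-deterministic", {
  ph <- generate_phantom(phantom_centers, noise_sd = 25, seed = 71)
  expect_equal(nrow(ph$truth), 4)
  ph2 <- generate_phantom(phantom_centers, noise_sd = 25, seed = 71)
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_error(generate_phantom(rbind(c(0, 0, 0), c(1, 0, 0))), "overlap")
})

test_that("a noiseless on-grid sphere has an unbiased intensity centroid", {
  # center exactly on a voxel grid point: spacing * integer + origin
  sp <- c(0.43, 0.43, 0.6)
  ph <- generate_phantom(matrix(c(0, 0, 0), 1), spacing = sp, noise_sd = 0)
  det <- detect_fiducials(ph$volume)
  expect_equal(nrow(det), 1)
  err_vox <- abs(as.numeric(det[1, c("x", "y", "z")])) / sp
  expect_lt(max(err_vox), 0.05)
})

test_that("detection finds exactly the true fiducials under noise", {
  # noise sd = 5% of the titanium/tissue contrast
  ph <- generate_phantom(phantom_centers, noise_sd = 0.05 * 960, seed = 72)
  det <- detect_fiducials(ph$volume)
  expect_equal(nrow(det), 4)
  D <- as.matrix(det[, c("x", "y", "z")])
  err <- vapply(seq_len(4), function(i)
    min(sqrt(colSums((t(D) - phantom_centers[i, ])^2))), numeric(1))
  expect_lt(max(err) / 0.43, 0.2)                 # sub-voxel accuracy
  expect_true(all(det$equivalent_diameter > 2 & det$equivalent_diameter < 8))
  # sorted by descending peak intensity
  expect_true(all(diff(det$peak_intensity) <= 0))
})

test_that("empty volumes and small specks yield no detections", {
  flat <- ct_volume(array(40, c(12, 12, 12)), diag(4))
  expect_warning(d0 <- detect_fiducials(flat, threshold = 500), "no voxels")
  expect_equal(nrow(d0), 0)

  ph <- generate_phantom(matrix(c(0, 0, 0), 1), noise_sd = 0)
  arr <- ph$volume$data
  # a 2-voxel speck well above threshold, away from the sphere and border
  arr[3, 3, 3] <- 1000; arr[4, 3, 3] <- 1000
  det <- detect_fiducials(ct_volume(arr, ph$volume$affine))
  expect_equal(nrow(det), 1)                      # the speck is filtered
})

test_that("stability assessment removes rigid motion and isolates displaced markers", {
  pre <- make_cluster(4, seed = 73)
  # pure rigid motion: zero deviations
  set.seed(74)
  post <- apply_transform(random_rigid(), pre)
  s <- assess_stability(pre, post)
  expect_lt(max(s$deviations), 1e-9)
  expect_equal(s$mean, 0, tolerance = 1e-9)

  # identical sets: mean 0, sd 0
  s0 <- assess_stability(pre, pre)
  expect_equal(s0$mean, 0, tolerance = 1e-12)
  expect_equal(s0$sd, 0, tolerance = 1e-12)

  # a marker displaced out of the others' plane dominates the residuals
  planar <- labeled_points(paste0("F", 1:4),
                           rbind(c(0, 0, 0), c(20, 0, 0), c(10, 17, 0),
                                 c(10, 6, 0)))
  moved <- surgnav:::.positions(planar)
  moved[4, 3] <- moved[4, 3] + 2
  s1 <- assess_stability(planar, labeled_points(planar$label, moved))
  expect_equal(names(which.max(s1$deviations)), "F4")
  # brute-force check: residuals match direct optimization over the motion
  obj <- function(par) {
    ax <- par[1:3]; K <- surgnav:::.skew(ax)
    th <- sqrt(sum(ax^2))
    R <- if (th < 1e-12) diag(3) else
      diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
    sum((sweep(moved %*% t(R), 2, -par[4:6]) -
           surgnav:::.positions(planar))^2)
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(sum(s1$deviations^2), opt$value, tolerance = 1e-6)

  expect_error(assess_stability(pre, labeled_points(letters[1:4],
                                                    surgnav:::.positions(pre))),
               "labels")
})

test_that("stability is invariant to a global rigid motion of either set", {
  pre <- make_cluster(5, seed = 75)
  set.seed(76)
  pos <- surgnav:::.positions(pre) + matrix(rnorm(15, sd = 0.3), 5)
  post <- labeled_points(pre$label, pos)
  base <- assess_stability(pre, post)
  for (i in 1:3) {
    T1 <- random_rigid()
    expect_near(assess_stability(pre, apply_transform(T1, post))$deviations,
                base$deviations, 1e-8)
    expect_near(assess_stability(apply_transform(T1, pre), post)$deviations,
                base$deviations, 1e-8)
  }
})

test_that("volumes round-trip through NIfTI with their world affine", {
  ph <- generate_phantom(phantom_centers[1:2, ], noise_sd = 10, seed = 77)
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$volume, f)
  back <- read_volume_nifti(f)
  expect_equal(back$dim, ph$volume$dim)
  expect_near(back$affine, ph$volume$affine, 1e-4)
  expect_near(back$data, ph$volume$data, 1e-3)
  det <- detect_fiducials(back)
  expect_equal(nrow(det), 2)
})
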