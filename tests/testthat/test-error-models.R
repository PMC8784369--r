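test_that("FLE components combine by root-sum-of-squares", {
  expect_equal(combine_fle(c(image = 0.1, emt = 0.7))$total_rms,
               sqrt(0.1^2 + 0.7^2), tolerance = 1e-12)  # 0.70710678 mm
  expect_equal(combine_fle(0.5)$total_rms, 0.5)
  expect_equal(combine_fle(c(3, 4))$total_rms, 5)
  expect_error(combine_fle(c(0.1, -0.2)), ">= 0")
  # covariance contract
  m <- combine_fle(c(0.3, 0.4))
  expect_equal(sum(diag(m$covariance)), m$total_rms^2, tolerance = 1e-12)
  expect_error(combine_fle(0.5, covariance = diag(c(1, 1, 1))), "trace")
})

test_that("FLE recovery from FRE inverts the (1 - 2/N) law", {
  expect_equal(fle_from_fre(0.5, 4), sqrt(0.5), tolerance = 1e-8)  # 0.70710678
  expect_equal(fle_from_fre(0, 7), 0)
  expect_error(fle_from_fre(0.5, 2), ">= 3")
  # Monte-Carlo round trip: simulate with a known FLE, recover it from FRE
  cfg <- fiducial_config(make_cluster(6, seed = 41))
  mc <- monte_carlo_tre(cfg, cfg$centroid, combine_fle(1.0), reps = 60000,
                        seed = 42)
  expect_equal(fle_from_fre(sqrt(mean(mc$fre2)), 6), 1.0, tolerance = 0.02)
})

test_that("closed-form TRE prediction has its exact limits", {
  cfg <- fiducial_config(make_cluster(4, seed = 43))
  fle <- combine_fle(0.7071068)
  at_centroid <- predict_tre(cfg, cfg$centroid, fle)
  expect_equal(at_centroid$tre_rms, fle$total_rms / sqrt(4), tolerance = 1e-9)
  expect_equal(predict_tre(cfg, cfg$centroid + c(50, 0, 0),
                           combine_fle(0))$tre_rms, 0)
  expect_error(predict_tre(labeled_points(letters[1:4],
                                          cbind(1:4, 1:4, 1:4)),
                           c(50, 0, 0), fle))
})

test_that("analytic TRE matches the Monte-Carlo oracle on a distant target", {
  # geometry of the intended use: compact 4-fiducial cluster, target 70 mm out
  cfg <- fiducial_config(make_cluster(4, extent = 25, seed = 44))
  fle <- combine_fle(c(image = 0.1, emt = 0.7))
  set.seed(45)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  target <- cfg$centroid + 70 * dir
  pred <- predict_tre(cfg, target, fle)
  mc <- monte_carlo_tre(cfg, target, fle, reps = 1e5, seed = 46)
  expect_equal(mc$tre_rms / pred$tre_rms, 1, tolerance = 0.03)
})

test_that("TRE covariance: exact at the centroid, PSD, trace-consistent, MC-consistent", {
  fle <- combine_fle(0.6)
  set.seed(47)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    cfg <- fiducial_config(make_cluster(n))
    target <- cfg$centroid + runif(1, 20, 80) * {
      d <- rnorm(3); d / sqrt(sum(d^2))
    }
    cov <- predict_tre_covariance(cfg, target, fle)
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 0)
    # trace equals the squared closed-form RMS (isotropic FLE)
    pred <- predict_tre(cfg, target, fle)
    expect_equal(sum(diag(cov)), pred$tre_rms^2, tolerance = 1e-6 * pred$tre_rms^2)
  }
  # centroid: pure translation noise, cov = FLE^2/(3N) I
  cfg <- fiducial_config(make_cluster(5, seed = 48))
  cov0 <- predict_tre_covariance(cfg, cfg$centroid, fle)
  expect_near(cov0, diag(rep(fle$total_rms^2 / (3 * 5), 3)), 1e-9)
  # empirical covariance agreement (Frobenius, relative)
  target <- cfg$centroid + c(60, -20, 30)
  covp <- predict_tre_covariance(cfg, target, fle)
  mc <- monte_carlo_tre(cfg, target, fle, reps = 1e5, seed = 49)
  expect_lt(norm(mc$covariance - covp, "F") / norm(covp, "F"), 0.05)
})

test_that("anisotropic FLE is served by the covariance path only", {
  cfg <- fiducial_config(make_cluster(4, seed = 50))
  aniso <- combine_fle(0.7, covariance = diag(c(0.3, 0.1, 0.09)))
  expect_false(aniso$isotropic)
  expect_error(predict_tre(cfg, cfg$centroid + c(50, 0, 0), aniso),
               "anisotropic|isotropic")
  cov <- predict_tre_covariance(cfg, cfg$centroid, aniso)
  expect_near(cov, aniso$covariance / 4, 1e-9)   # translation-only at centroid
})

test_that("TRE prediction is invariant under a global rigid motion", {
  cfg_pts <- make_cluster(5, seed = 51)
  target <- fiducial_config(cfg_pts)$centroid + c(40, 30, -20)
  fle <- combine_fle(0.5)
  base <- predict_tre(fiducial_config(cfg_pts), target, fle)
  set.seed(52)
  for (i in 1:5) {
    T1 <- random_rigid()
    moved <- predict_tre(fiducial_config(apply_transform(T1, cfg_pts)),
                         apply_transform(T1, target), fle)
    expect_equal(moved$tre_rms, base$tre_rms, tolerance = 1e-9)
  }
})

test_that("confidence ellipses have the stated geometry and coverage", {
  circ <- confidence_ellipse(diag(c(4, 4)), 0.95)
  expect_equal(unname(circ$semi_axes),
               rep(2 * sqrt(qchisq(0.95, 2)), 2), tolerance = 1e-9)
  ell <- confidence_ellipse(diag(c(4, 1)), 0.95)
  expect_equal(unname(ell$semi_axes),
               c(2, 1) * sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_equal(abs(cos(ell$orientation)), 1, tolerance = 1e-9)
  expect_error(confidence_ellipse(matrix(c(1, 2, 2, 1), 2), 0.95),
               "semidefinite")
  expect_error(confidence_ellipse(diag(2), 1.2), "level")

  # empirical coverage at the nominal level
  set.seed(53)
  S <- matrix(c(4, 1.2, 1.2, 2), 2)
  z <- matrix(rnorm(2e5), ncol = 2) %*% chol(S)
  cover <- mean(in_ellipse(confidence_ellipse(S, 0.95), z))
  expect_equal(cover, 0.95, tolerance = 0.005)
})

test_that("the Monte-Carlo oracle is deterministic and distance-monotone", {
  cfg <- fiducial_config(make_cluster(4, seed = 54))
  fle <- combine_fle(0.5)
  a <- monte_carlo_tre(cfg, cfg$centroid + c(30, 0, 0), fle, reps = 500,
                       seed = 99)
  b <- monte_carlo_tre(cfg, cfg$centroid + c(30, 0, 0), fle, reps = 500,
                       seed = 99)
  expect_identical(a$displacements, b$displacements)

  z <- monte_carlo_tre(cfg, cfg$centroid, combine_fle(0), reps = 50, seed = 1)
  expect_equal(max(z$tre), 0)

  set.seed(55)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rms <- sapply(c(0, 20, 40, 80, 160), function(dist)
    monte_carlo_tre(cfg, cfg$centroid + dist * dir, fle, reps = 20000,
                    seed = 7)$tre_rms)
  expect_true(all(diff(rms) > 0))
})
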