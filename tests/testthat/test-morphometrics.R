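# Procrustes superimposition, thin-plate-spline scores, shape
# regression and the univariate ratios.

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

test_that("Procrustes distance is zero under similarity transforms", {
  tri <- matrix(c(0, 1, 0.3, 0, 0, 1), 3, 2)
  expect_lt(procrustes_distance(tri, tri), 1e-12)
  moved <- sweep(tri %*% rot2(1.1) * 3.7, 2, c(-5, 2))
  expect_lt(procrustes_distance(tri, moved), 1e-8)
  fish <- template_landmarks()
  moved_fish <- sweep(fish %*% rot2(-2.3) * 0.4, 2, c(10, 10))
  expect_lt(procrustes_distance(fish, moved_fish), 1e-8)
})

test_that("pairwise distances match a brute-force rotation search", {
  set.seed(21)
  for (i in 1:8) {
    a <- matrix(rnorm(6), 3, 2)
    b <- matrix(rnorm(6), 3, 2)
    expect_equal(procrustes_distance(a, b),
                 oracle_procrustes_distance(a, b), tolerance = 1e-5)
  }
})

test_that("GPA is invariant to input similarity transforms and order", {
  lms <- gen_landmarks(8, 17, deformation_magnitude = 0.05,
                       noise_sd = 0.01, seed = 31)
  g1 <- gpa_align(lms)
  # transform every input differently; consensus shape must not move
  lms2 <- lms
  for (i in 1:8) {
    lms2[, , i] <- sweep(lms[, , i] %*% rot2(i) * (0.5 + i / 4), 2,
                         c(i, -i))
  }
  g2 <- gpa_align(lms2)
  expect_lt(procrustes_distance(g1$consensus, g2$consensus), 1e-6)
  g3 <- gpa_align(lms[, , 8:1])
  expect_lt(procrustes_distance(g1$consensus, g3$consensus), 1e-6)
  expect_error(gpa_align(lms[, , 1, drop = FALSE]), "at least 2")
})

test_that("partial warp scores have the right dimension and vanish at the
          consensus", {
  lms <- gen_landmarks(10, 17, deformation_magnitude = 0.04,
                       noise_sd = 0.01, seed = 32)
  gpa <- gpa_align(lms)
  sc <- tps_partial_warps(gpa)
  expect_equal(ncol(sc$partial_warp_scores), 2 * (17 - 3))
  expect_equal(ncol(sc$uniform), 2L)
  # a specimen placed exactly at the consensus scores zero everywhere
  gpa2 <- gpa
  gpa2$aligned[, , 1] <- gpa$consensus
  sc2 <- tps_partial_warps(gpa2)
  expect_lt(max(abs(sc2$scores[1, ])), 1e-12)
})

test_that("squared scores decompose the tangent residual (Pythagoras)", {
  lms <- gen_landmarks(12, 17, deformation_magnitude = 0.06,
                       noise_sd = 0.02, seed = 33)
  sc <- tps_partial_warps(gpa_align(lms))
  expect_lt(max(abs(rowSums(sc$scores^2) - sc$tangent_resid_norm2)), 1e-8)
})

test_that("a pure affine shear loads only on the uniform component", {
  lms <- gen_landmarks(6, 17, deformation_magnitude = 0, noise_sd = 0,
                       seed = 34)
  gpa <- gpa_align(lms)
  shear <- matrix(c(1, 0, 0.15, 1), 2, 2)
  sheared <- gpa$consensus %*% t(shear)
  sheared <- sheared / sqrt(sum(sweep(sheared, 2, colMeans(sheared))^2))
  R <- swimphys:::optimal_rotation(sheared, gpa$consensus)
  gpa$aligned[, , 1] <- sheared %*% R
  sc <- tps_partial_warps(gpa)
  expect_lt(max(abs(sc$partial_warp_scores[1, ])), 1e-10)
  expect_gt(sqrt(sum(sc$uniform[1, ]^2)), 1e-3)
})

test_that("shape regression rejects real signal and respects permutation
          invariance", {
  lms <- gen_landmarks(25, 17, deformation_magnitude = 0.08,
                       noise_sd = 0.005, seed = 35)
  sc <- tps_partial_warps(gpa_align(lms))
  cov <- attr(lms, "covariate")
  reg <- shape_regression(sc, cov, n_perm = 199, seed = 1)
  expect_lte(reg$p, 0.01)
  # reordering specimens together with the covariate leaves F unchanged
  perm <- sample(25)
  reg2 <- shape_regression(sc$scores[perm, ], cov[perm], n_perm = 99,
                           seed = 1)
  expect_equal(reg2$F, reg$F, tolerance = 1e-10)
  expect_error(shape_regression(sc, rep(1, 25)), "non-constant")
})

test_that("morphological ratios follow their defining formulas", {
  r <- morpho_ratios(8, 1.6, 2, 1, 0.6)
  expect_equal(r$FR, 5)
  expect_equal(r$AR, 4)
  expect_equal(r$CPH, 7.5)
  expect_equal(r$CPD_BD, 0.375)
  # a caudal peduncle depth factor in the plausible biological range
  r2 <- morpho_ratios(8, 1.5, 2, 1, 0.6)
  expect_gt(100 * r2$CPD_BD, 38); expect_lt(100 * r2$CPD_BD, 44)
  expect_error(morpho_ratios(8, -1, 2, 1, 0.6), "positive")
})

test_that("the packaged template has 17 named landmarks", {
  tpl <- template_landmarks()
  expect_equal(dim(tpl), c(17L, 2L))
  expect_true("caudal_fork" %in% rownames(tpl))
})
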