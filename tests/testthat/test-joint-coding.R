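test_that("sign contingency reproduces hand-computed chi-squared values", {
  svp <- rep(c(TRUE, FALSE), c(50, 50)); svn <- !svp
  idp <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40)); idn <- !idp
  ct <- sign_contingency(svp, svn, idp, idn)
  # counts [[40,10],[10,40]]: E = 25 per cell, chi2 = 4 * 225/25 = 36
  expect_equal(unname(ct$observed), matrix(c(40, 10, 10, 40), 2))
  expect_true(all(ct$expected == 25))
  expect_equal(ct$chi2, 36)
  expect_equal(ct$df, 1)
  # expected cells are products of marginals
  marg <- outer(rowSums(ct$observed), colSums(ct$observed)) / ct$n_joint
  expect_equal(unname(ct$expected), unname(marg))
  expect_equal(sum(ct$observed_pct), 100, tolerance = 0.2)
  # balanced table: chi2 = 0
  idp2 <- rep(c(TRUE, FALSE), 50); idn2 <- !idp2
  expect_equal(sign_contingency(svp, svn, idp2, idn2)$chi2, 0)
  # transpose invariance
  ct2 <- sign_contingency(idp, idn, svp, svn)
  expect_equal(ct$chi2, ct2$chi2)
  # errors
  expect_error(sign_contingency(svp, svp, idp, idn), "disjoint")
  expect_error(sign_contingency(svp, svn, idp, idn,
                                mask = rep(FALSE, 100)), "no overlapping")
})

test_that("chi-squared contingency test is calibrated under independent sign maps", {
  set.seed(61)
  n_draws <- 1000; rej <- 0; used <- 0
  for (i in seq_len(n_draws)) {
    a <- rnorm(800); b <- rnorm(800)
    r <- tryCatch(sign_contingency(a > 1, a < -1, b > 1, b < -1),
                  error = function(e) NULL)
    if (is.null(r)) next
    used <- used + 1
    if (r$p < 0.05) rej <- rej + 1
  }
  expect_gt(used, 950)
  expect_lt(abs(rej / used - 0.05), 0.02)
})

test_that("ROI overlap percentages follow the matching-sign count", {
  svp <- rep(TRUE, 50); svn <- !svp
  idp <- rep(c(TRUE, FALSE), c(49, 1)); idn <- !idp
  ov <- roi_overlap(svp, svn, idp, idn, rep(TRUE, 50))
  expect_equal(ov$percent, 98)
  expect_equal(ov$n_joint, 50)
  # all-matching ROI: 100 %
  ov2 <- roi_overlap(svp, svn, rep(TRUE, 50), rep(FALSE, 50), rep(TRUE, 50))
  expect_equal(ov2$percent, 100)
  # empty ROI: undefined, no crash
  ov3 <- roi_overlap(svp, svn, idp, idn, rep(FALSE, 50))
  expect_false(ov3$defined)
  expect_true(is.na(ov3$percent))
})

test_that("map correlations behave like Pearson r with affine invariance", {
  set.seed(67)
  a <- rnorm(200); b <- 0.6 * a + rnorm(200, 0, 0.5)
  expect_equal(map_correlation(a, a)$r, 1)
  expect_equal(map_correlation(a, -a)$r, -1)
  r1 <- map_correlation(a, b)
  r2 <- map_correlation(3 * a - 7, 0.5 * b + 2)
  expect_equal(r1$r, r2$r)
  expect_equal(r1$r, cor.test(a, b)$estimate, ignore_attr = TRUE)
  # masking restricts the voxel set
  m <- c(rep(TRUE, 100), rep(FALSE, 100))
  expect_equal(map_correlation(a, b, mask = m)$n_voxels, 100)
  # degenerate input flagged, not crashed
  expect_false(map_correlation(rep(1, 50), rnorm(50))$defined)
  expect_error(map_correlation(a[1:2], b[1:2]), "at least 3")
})

test_that("gradient summation map z-scores each input and flags cancellation", {
  set.seed(71)
  A <- array(rnorm(4^3), c(4, 4, 4))
  g_same <- gradient_map(A, A)
  zs <- attr(g_same, "zscored_sv")
  expect_equal(as.vector(g_same), 2 * zs)
  expect_lt(abs(mean(zs)), 1e-10)
  expect_equal(sd(zs), 1)
  # opposed maps cancel after z-scoring
  g_opp <- gradient_map(A, -3 * A + 5)
  expect_lt(max(abs(g_opp)), 1e-10)
  expect_error(gradient_map(array(1, c(4, 4, 4)), A), "zero-variance")
})

test_that("loss-aversion voxel ratio tracks generating loss aversion across a cohort", {
  set.seed(73)
  n_sub <- 16; V <- 1000
  la <- exp(rnorm(n_sub, log(2), 0.4))
  # subject maps whose negative voxel share grows with loss aversion
  stack <- t(sapply(la, function(l) {
    neg_frac <- l / (1 + l)
    sgn <- ifelse(runif(V) < neg_frac, -1, 1)
    sgn * (3 + rnorm(V))
  }))
  res <- loss_aversion_voxel_ratio(stack, la, z_thresh = 2.3)
  expect_gt(res$rho, 0.5)
  expect_equal(res$n_used, n_sub)
  # equal counts -> ratio 1
  half <- matrix(rep(c(3, -3), each = 10), 1)
  r1 <- loss_aversion_voxel_ratio(half, 2)
  expect_equal(unname(r1$ratio), 1)
  # no supra-threshold positives -> participant skipped with warning
  none <- matrix(-3, 2, 10)
  expect_warning(r2 <- loss_aversion_voxel_ratio(none, c(1, 2)),
                 "skipped")
  expect_true(all(is.na(r2$ratio)))
})

test_that("probabilistic masks binarise at 50% after nearest-neighbour resampling", {
  m <- volume(0, c(4, 4, 4))
  m[1:2, , ] <- 80; m[3, , ] <- 40
  b <- binarise_mask(m)
  expect_true(all(b[1:2, , ]))
  expect_false(any(b[3:4, , ]))
  # resample to a finer grid preserves the region boundary
  b2 <- binarise_mask(m, dim3 = c(8, 8, 8))
  expect_equal(dim(b2), c(8, 8, 8))
  expect_true(all(b2[1:4, , ]))
  expect_false(any(b2[5:8, , ]))
  # fractional (0-1) masks work unchanged
  b3 <- binarise_mask(m / 100)
  expect_equal(as.vector(b3), as.vector(b))
})
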