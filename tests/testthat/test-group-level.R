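test_that("group one-sample statistics match hand computation and deweight outliers", {
  # all-zero maps -> Z = 0 everywhere
  g0 <- group_onesample(matrix(0, 5, 10), deweight = FALSE)
  expect_true(all(g0$z == 0))
  # {2,4,4,6}: mean 4, sd sqrt(8/3), t = 4 / (1.633/2) = 4.899
  g <- group_onesample(matrix(c(2, 4, 4, 6), 4, 1), deweight = FALSE)
  expect_equal(g$effect / g$se, 4.898979, tolerance = 1e-6)
  expect_equal(g$z, qnorm(pt(4.898979, df = 3)), tolerance = 1e-6)
  # Huber deweighting pulls a wild outlier toward the clean mean
  set.seed(31)
  y <- c(rnorm(19, 1, 0.2), 25)
  gd <- group_onesample(matrix(y, 20, 1), deweight = TRUE)
  gu <- group_onesample(matrix(y, 20, 1), deweight = FALSE)
  clean_mean <- mean(y[1:19])
  expect_lt(abs(gd$effect - clean_mean), abs(gu$effect - clean_mean))
  expect_lt(min(gd$weights), 1)          # the outlier was downweighted
  expect_error(group_onesample(matrix(0, 2, 4)), "at least 3")
})

test_that("cluster inference finds a planted blob and respects tail symmetry", {
  set.seed(41)
  dim3 <- c(12, 12, 12); V <- prod(dim3); n <- 16
  stack <- matrix(rnorm(n * V), n, V)
  blob <- array(FALSE, dim3); blob[5:7, 5:7, 5:6] <- TRUE
  stack[, as.vector(blob)] <- stack[, as.vector(blob)] + 2
  g <- group_onesample(stack, dim3 = dim3, pixdim = rep(3, 3))
  tab <- cluster_inference(g, n_perm = 500, seed = 2)
  expect_gte(nrow(tab), 1)
  expect_lt(tab$p_corrected[1], 0.05)
  expect_gte(tab$n_voxels[1], 10)
  # the reported cluster covers the planted blob
  sig <- significant_voxels(tab)
  expect_gt(mean(sig[as.vector(blob)]), 0.8)
  # peak lies inside the cluster
  lab <- attr(tab, "labels")
  expect_true(all(tab$n_voxels >= 1))
  # negative-tail inference on -M equals positive-tail on M
  gneg <- group_onesample(-stack, dim3 = dim3, pixdim = rep(3, 3))
  tneg <- cluster_inference(gneg, n_perm = 500, tail = "negative", seed = 2)
  expect_equal(tab$n_voxels, tneg$n_voxels)
  expect_equal(tab$p_corrected, tneg$p_corrected)
  # all-zero map -> empty table
  gz <- group_onesample(matrix(0, 5, V), dim3 = dim3)
  expect_equal(nrow(cluster_inference(gz, n_perm = 50, seed = 1)), 0)
})

test_that("conjunction takes the voxelwise minimum and is monotone", {
  set.seed(43)
  dim3 <- c(10, 10, 10); V <- prod(dim3); n <- 14
  base <- numeric(V); base[1:200] <- 1.2
  A <- matrix(rnorm(n * V, 0, 0.6), n, V) + rep(base, each = n)
  B <- matrix(rnorm(n * V, 0, 0.6), n, V) + rep(base, each = n)
  ga <- group_onesample(A, dim3 = dim3); gb <- group_onesample(B, dim3 = dim3)
  cj <- conjunction(ga, gb)
  expect_equal(cj$z, pmin(ga$z, gb$z))
  tab <- cluster_inference(cj, n_perm = 200, seed = 5)
  sig <- significant_voxels(tab)
  # conjunction voxels are supra-threshold in both parents
  expect_true(all(ga$z[sig] >= 2.3))
  expect_true(all(gb$z[sig] >= 2.3))
  expect_error(conjunction(ga, group_onesample(B[, 1:500], dim3 = c(5, 10, 10))),
               "mismatch|subject")
})

test_that("permutation cluster p-values are valid (never anti-conservative) under the null", {
  set.seed(47)
  dim3 <- c(8, 8, 8); V <- prod(dim3); n <- 12
  n_rep <- 100; n_perm <- 99
  minp <- rep(1, n_rep)
  for (r in seq_len(n_rep)) {
    stack <- matrix(rnorm(n * V), n, V)
    g <- group_onesample(stack, dim3 = dim3, deweight = FALSE)
    tab <- cluster_inference(g, n_perm = n_perm, alpha = 1, seed = r)
    if (nrow(tab)) minp[r] <- min(tab$p_corrected)
  }
  # family-wise P(p <= alpha) <= alpha + Monte-Carlo slack; unsmoothed
  # white-noise extents are discrete, so conservatism is expected
  expect_lte(mean(minp <= 0.05), 0.05 + 0.045)
  expect_lte(mean(minp <= 0.01), 0.01 + 0.03)
})

test_that("SV-vs-iDE contrast detects stronger iDE coding and is exactly symmetric", {
  set.seed(53)
  dim3 <- c(10, 10, 10); V <- prod(dim3); n <- 16
  blob <- array(FALSE, dim3); blob[3:8, 3:8, 3:6] <- TRUE
  base <- numeric(V); base[as.vector(blob)] <- 1.5
  svs <- matrix(rnorm(n * V, 0, 0.5), n, V) + rep(base, each = n)
  ids <- matrix(rnorm(n * V, 0, 0.5), n, V) + rep(2 * base, each = n)
  ct <- contrast_sv_vs_ide(svs, ids, n_perm = 1000, alpha = 0.05,
                           dim3 = dim3, seed = 4)
  expect_gte(nrow(ct$ide_gt_sv), 1)
  expect_equal(nrow(ct$sv_gt_ide), 0)
  # iDE>SV clusters cover most of the active region
  lab <- attr(ct$ide_gt_sv, "labels")
  covered <- mean((lab > 0)[as.vector(blob)])
  expect_gt(covered, 0.8)
  # permutation Z saturates at the resolution limit of n_perm
  expect_equal(ct$max_z, qnorm(1 - 1 / 1001))
  expect_lte(max(ct$z_ide_gt_sv), ct$max_z + 1e-12)
  # swapping the stacks swaps the tables exactly
  ct_sw <- contrast_sv_vs_ide(ids, svs, n_perm = 1000, alpha = 0.05,
                              dim3 = dim3, seed = 4)
  a <- ct$ide_gt_sv; b <- ct_sw$sv_gt_ide
  expect_equal(a$n_voxels, b$n_voxels)
  expect_equal(a$p_corrected, b$p_corrected)
  # identical stacks: no significant contrast anywhere
  ct0 <- contrast_sv_vs_ide(svs, svs, n_perm = 200, dim3 = dim3, seed = 9)
  expect_equal(nrow(ct0$ide_gt_sv), 0)
  expect_equal(nrow(ct0$sv_gt_ide), 0)
  expect_error(contrast_sv_vs_ide(svs, ids[1:4, ]), "paired")
})

test_that("paper's contrast peak Z of 3.54 is the 5000-permutation saturation bound", {
  expect_equal(round(qnorm(1 - 1 / 5001), 2), 3.54)
})

test_that("task-active mask is binary, two-sided, and nested in the analysis mask", {
  set.seed(59)
  dim3 <- c(8, 8, 8); V <- prod(dim3)
  base <- numeric(V); base[1:64] <- 2; base[65:128] <- -2
  stack <- matrix(rnorm(12 * V, 0, 0.4), 12, V) + rep(base, each = 12)
  g <- group_onesample(stack, dim3 = dim3)
  m <- task_active_mask(g, 2.3)
  expect_type(as.vector(m), "logical")
  expect_gt(mean(m[1:128]), 0.9)       # both signs captured
  expect_lt(mean(m[129:V]), 0.2)
  g0 <- group_onesample(matrix(0, 5, V), dim3 = dim3)
  expect_equal(sum(task_active_mask(g0, 2.3)), 0)
})
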