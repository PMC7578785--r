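test_that("double-gamma HRF has the canonical shape", {
  tg <- seq(0, 32, by = 0.1)
  h <- hrf_double_gamma(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-3)      # unit-peak normalisation
  peak_t <- tg[which.max(h)]
  expect_gte(peak_t, 4.5); expect_lte(peak_t, 6.5)
  # exactly one sign change: positive lobe then undershoot
  s <- sign(h[abs(h) > 1e-8])
  expect_equal(sum(diff(s) != 0), 1)
  # undershoot minimum in the 14-18 s window
  expect_true(tg[which.min(h)] > 14 && tg[which.min(h)] < 18)
})

test_that("design matrix columns follow the modulated-boxcar contract", {
  tr <- data.frame(onset = c(10, 30, 50), duration = 4,
                   sv = c(1, 2, 3), ide = c(-0.2, -0.9, -0.5))
  X <- build_design(tr, motion = NULL, TR = 1, n_volumes = 80)
  expect_equal(colnames(X), c("trials", "sv", "ide", "trials_deriv",
                              "sv_deriv", "ide_deriv", "constant"))
  # constant modulator vanishes after centring
  tr2 <- tr; tr2$sv <- 5
  X2 <- build_design(tr2, NULL, TR = 1, n_volumes = 80)
  expect_equal(max(abs(X2[, "sv"])), 0)
  # single event peaks where the oracle convolution peaks
  tr3 <- data.frame(onset = 0, duration = 4, sv = 1, ide = -1)
  X3 <- build_design(tr3, NULL, TR = 1, n_volumes = 40)
  oracle <- oracle_convolve_event(0, 4, TR = 1, n_volumes = 40)
  expect_equal(which.max(X3[, "trials"]), which.max(oracle))
  expect_true(which.max(oracle) %in% 6:9)       # peak at 6-8 s post onset
  # 0.1 s microtime vs 0.01 s oracle: small discretisation slack on a
  # regressor whose peak is ~2
  expect_lt(max(abs(X3[, "trials"] - oracle)), 0.05)
  expect_gt(cor(X3[, "trials"], oracle), 0.999)
  # identical events -> identical designs
  expect_equal(unclass(build_design(tr, NULL, 1, 80)),
               unclass(build_design(tr, NULL, 1, 80)))
  expect_error(build_design(tr[0, ], NULL, 1, 80), "empty")
  expect_error(build_design(tr, NULL, 1, 20), "outside")
})

test_that("high-pass projection removes drift, passes task frequencies, and is idempotent", {
  n <- 400; TR <- 1
  trend <- 3 + 0.05 * seq_len(n)
  expect_lt(sqrt(sum(highpass(trend, TR, 100)^2)) / sqrt(sum(trend^2)), 1e-8)
  s10 <- sin(2 * pi * seq_len(n) / 10)
  expect_gt(sd(highpass(s10, TR, 100)) / sd(s10), 0.99)
  once <- highpass(s10, TR, 100)
  expect_equal(highpass(once, TR, 100), once)
  expect_error(highpass(s10, TR, cutoff = 1.5))
  # design matrix: constant column protected
  tr <- data.frame(onset = c(10, 30), duration = 4, sv = 1:2, ide = c(-1, 0))
  X <- build_design(tr, NULL, TR = 1, n_volumes = 60)
  Xf <- highpass(X, TR = 1, 100)
  expect_equal(Xf[, "constant"], X[, "constant"])
  expect_false(isTRUE(all.equal(Xf[, "trials"], X[, "trials"])))
})

test_that("Gaussian smoothing preserves constants and mass, with ~5 mm FWHM", {
  v <- volume(2.5, c(10, 10, 10), 3)
  expect_equal(smooth_volumes(v, 5), v, ignore_attr = TRUE)
  # impulse on a fine 1 mm grid: measure the half-maximum width
  imp <- volume(0, c(31, 31, 31), 1)
  imp[16, 16, 16] <- 1
  sm <- smooth_volumes(imp, 5)
  prof <- sm[, 16, 16]
  hm <- max(prof) / 2
  above <- which(prof >= hm)
  lo <- min(above); hi <- max(above)
  left <- (lo - 1) + (hm - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  right <- hi + (hm - prof[hi]) / (prof[hi + 1] - prof[hi])
  expect_equal(right - left, 5, tolerance = 0.15)
  expect_equal(sum(sm), 1, tolerance = 1e-6)    # interior impulse mass
  expect_error(smooth_volumes(imp, -1))
  expect_identical(smooth_volumes(imp, 0), imp)
})

test_that("run GLM recovers exact weights without noise and handles degenerate designs", {
  nr <- noiseless_run()
  X <- build_design(nr$trials, nr$bold$motion, TR = 1,
                    n_volumes = nr$n_volumes)
  fit <- fit_run_glm(nr$bold, X, whiten = FALSE)
  expect_lt(max(abs(fit$beta["sv", ] - as.vector(nr$maps$sv_weight))) /
              max(abs(nr$maps$sv_weight)), 1e-6)
  expect_lt(max(abs(fit$beta["ide", ] - as.vector(nr$maps$ide_weight))) /
              max(abs(nr$maps$ide_weight)), 1e-6)
  expect_lt(max(abs(fit$beta["trials", ] - as.vector(nr$maps$intercept))) /
              max(abs(nr$maps$intercept)), 1e-6)
  # data equal to one design column -> unit beta there, zero elsewhere
  y <- X[, "sv", drop = FALSE]
  f2 <- fit_run_glm(y, X, whiten = FALSE)
  expect_equal(f2$beta["sv", 1], 1, tolerance = 1e-8)
  expect_lt(max(abs(f2$beta[setdiff(rownames(f2$beta), "sv"), 1])), 1e-8)
  # rank-deficient design names the collinear column
  Xbad <- cbind(X, dup_sv = X[, "sv"])
  expect_error(fit_run_glm(nr$bold$data, Xbad, whiten = FALSE), "dup_sv|sv")
})

test_that("prewhitened GLM Z statistics are calibrated on AR(1) noise", {
  set.seed(14)
  tr <- data.frame(onset = seq(10, 290, by = 14), duration = 4,
                   sv = rnorm(21), ide = rnorm(21))
  X <- build_design(tr, NULL, TR = 1, n_volumes = 320)
  nsim <- 800
  rho <- 0.4
  E <- matrix(rnorm(320 * nsim, 0, sqrt(1 - rho^2)), 320, nsim)
  E <- apply(E, 2, function(e) as.numeric(stats::filter(e, rho,
                                                        "recursive")))
  fit <- fit_run_glm(E, X, whiten = TRUE)
  z <- fit$beta["sv", ] / sqrt(fit$var["sv", ])
  rate <- mean(abs(z) > 1.96)
  expect_lt(abs(rate - 0.05), 0.025)
  expect_gt(mean(fit$rho), 0.2)     # AR(1) actually detected
})

test_that("centring invariance: shifting all SV values leaves the SV beta unchanged", {
  nr <- noiseless_run()
  X1 <- build_design(nr$trials, NULL, TR = 1, n_volumes = nr$n_volumes)
  tr2 <- nr$trials; tr2$sv <- tr2$sv + 7.3
  X2 <- build_design(tr2, NULL, TR = 1, n_volumes = nr$n_volumes)
  f1 <- fit_run_glm(nr$bold$data, X1, whiten = FALSE)
  f2 <- fit_run_glm(nr$bold$data, X2, whiten = FALSE)
  expect_lt(max(abs(f1$beta["sv", ] - f2$beta["sv", ])), 1e-8)
})

test_that("correlated (non-orthogonalised) modulators are still identifiable", {
  nr <- noiseless_run()
  tr <- nr$trials
  # make iDE strongly correlated with SV, as in real data
  tr$ide <- 0.8 * scale(tr$sv)[, 1] + 0.2 * tr$ide
  b <- generate_bold(tr, nr$maps, noise_model(sigma = 0, ar1_rho = 0,
                                              drift_amplitude = 0),
                     TR = 1, n_volumes = nr$n_volumes, seed = 4)
  X <- build_design(tr, NULL, TR = 1, n_volumes = nr$n_volumes)
  fit <- fit_run_glm(b$data, X, whiten = FALSE)
  expect_lt(max(abs(fit$beta["sv", ] - as.vector(nr$maps$sv_weight))) /
              max(abs(nr$maps$sv_weight)), 1e-6)
  expect_lt(max(abs(fit$beta["ide", ] - as.vector(nr$maps$ide_weight))) /
              max(abs(nr$maps$ide_weight)), 1e-6)
})

test_that("fixed-effects pooling follows the inverse-variance formulas", {
  mk <- function(b, v) list(beta = matrix(b, 1, 2,
                                          dimnames = list("sv", NULL)),
                            var = matrix(v, 1, 2,
                                         dimnames = list("sv", NULL)),
                            regressors = "sv")
  p <- pool_fixed_effects(list(mk(1, 1), mk(3, 1)))
  expect_equal(unname(p$beta[1, ]), c(2, 2))
  expect_equal(unname(p$var[1, ]), c(0.5, 0.5))
  expect_equal(unname(p$z[1, ]), c(2, 2) / sqrt(0.5))
  # single run is the identity
  one <- pool_fixed_effects(list(mk(1.5, 2)))
  expect_equal(unname(one$beta[1, ]), c(1.5, 1.5))
  expect_equal(unname(one$var[1, ]), c(2, 2))
  # four identical runs quarter the variance
  four <- pool_fixed_effects(list(mk(1, 2), mk(1, 2), mk(1, 2), mk(1, 2)))
  expect_equal(unname(four$var[1, ]), c(0.5, 0.5))
  # pooled variance never exceeds the smallest run variance
  mixed <- pool_fixed_effects(list(mk(1, 0.5), mk(2, 4)))
  expect_true(all(mixed$var <= 0.5))
  expect_error(pool_fixed_effects(list(mk(1, 0))), "degenerate")
})
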