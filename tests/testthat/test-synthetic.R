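test_that("task config enforces the range conditions", {
  eq <- task_config("equal_range")
  expect_equal(range(eq$loss_levels), range(eq$gain_levels))
  ei <- task_config("equal_indifference")
  expect_equal(diff(range(ei$loss_levels)), diff(range(ei$gain_levels)) / 2)
  # explicit span 30 -> loss span 15
  ei2 <- task_config("equal_indifference", gain_levels = seq(10, 40, 10))
  expect_equal(diff(range(ei2$loss_levels)), 15)
})

test_that("gamble schedules are orthogonal, reproducible, and bounded by the crossing", {
  cfg <- task_config()
  g1 <- generate_gambles(cfg, seed = 5)
  g2 <- generate_gambles(cfg, seed = 5)
  expect_identical(g1, g2)
  g3 <- generate_gambles(cfg, seed = 6)
  expect_false(identical(g1$gain, g3$gain))
  # full crossing per run: gain/loss exactly orthogonal
  for (r in 1:4) {
    gr <- g1[g1$run == r, ]
    expect_equal(cor(gr$gain, gr$loss), 0)
    expect_equal(sort(unique(paste(gr$gain, gr$loss))),
                 sort(paste(expand.grid(gain = cfg$gain_levels,
                                        loss = cfg$loss_levels)$gain,
                            expand.grid(gain = cfg$gain_levels,
                                        loss = cfg$loss_levels)$loss)))
  }
  # onsets strictly increasing with ITI in range
  gaps <- diff(g1$onset[g1$run == 1]) - cfg$trial_duration
  expect_true(all(gaps >= cfg$iti_range[1] & gaps <= cfg$iti_range[2]))
  # too many trials without replacement errors
  expect_error(generate_gambles(task_config(n_trials_per_run = 65)),
               "replace")
  expect_silent(generate_gambles(task_config(n_trials_per_run = 65),
                                 replace = TRUE))
})

test_that("simulated choices saturate and split weak/strong at the threshold", {
  cfg <- task_config(n_trials_per_run = 16, n_runs = 1)
  sat <- true_choice_model(0.1, -0.2, 50)
  tr <- simulate_participant(cfg, sat, seed = 2)
  expect_true(all(tr$accept == 1))
  # p = 0.5 exactly -> always a weak response
  half <- true_choice_model(0, 0, 0)
  tr2 <- simulate_participant(cfg, half, seed = 3)
  expect_true(all(tr2$response4 %in% c("weakly_accept", "weakly_reject")))
})

test_that("gradient map modes produce the expected sign structure", {
  al <- make_gradient_maps(c(16, 16, 16), mode = "aligned", seed = 2)
  agree <- mean(sign(al$sv_weight) == sign(al$ide_weight))
  expect_gte(agree, 0.95)
  ind <- make_gradient_maps(c(24, 24, 24), mode = "independent", seed = 3)
  agree_i <- mean(sign(ind$sv_weight) == sign(ind$ide_weight))
  expect_lt(abs(agree_i - 0.5), 0.05)
  op <- make_gradient_maps(c(16, 16, 16), mode = "opposed", seed = 2)
  expect_lt(cor(as.vector(op$sv_weight), as.vector(op$ide_weight)), 0)
  # neg_fraction shifts the negative share of the SV field
  lo <- make_gradient_maps(c(16, 16, 16), neg_fraction = 0.25, seed = 4)
  hi <- make_gradient_maps(c(16, 16, 16), neg_fraction = 0.75, seed = 4)
  expect_lt(mean(lo$sv_weight < 0), mean(hi$sv_weight < 0))
})

test_that("BOLD generation is deterministic and degenerates correctly", {
  nr <- noiseless_run()
  # all-zero weights, zero noise -> constant time courses
  maps0 <- nr$maps
  maps0$sv_weight[] <- 0; maps0$ide_weight[] <- 0; maps0$intercept[] <- 0
  b0 <- generate_bold(nr$trials, maps0,
                      noise_model(sigma = 0, ar1_rho = 0,
                                  drift_amplitude = 0),
                      TR = 1, n_volumes = nr$n_volumes, seed = 1)
  expect_equal(max(abs(b0$data)), 0)
  # determinism
  nm <- noise_model(sigma = 1, ar1_rho = 0.3, drift_amplitude = 0.5)
  b1 <- generate_bold(nr$trials, nr$maps, nm, TR = 1,
                      n_volumes = nr$n_volumes, seed = 7)
  b2 <- generate_bold(nr$trials, nr$maps, nm, TR = 1,
                      n_volumes = nr$n_volumes, seed = 7)
  expect_identical(b1$data, b2$data)
  expect_identical(b1$motion, b2$motion)
  # grid mismatch errors
  bad <- nr$maps
  bad$ide_weight <- volume(0, c(4, 4, 4))
  expect_error(generate_bold(nr$trials, bad, nm, TR = 1,
                             n_volumes = nr$n_volumes), "grid")
  # motion table carries the seven confounds
  expect_named(b1$motion, c("fd", "rot_x", "rot_y", "rot_z",
                            "trans_x", "trans_y", "trans_z"))
})

test_that("dataset writer produces the BIDS-like tree with a manifest", {
  dir <- file.path(tempdir(), "svide_ds")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- default_config(seed = 2, n_subjects = 2, dim3 = c(6, 6, 6),
                        task = task_config(n_trials_per_run = 8, n_runs = 2))
  ds <- simulate_dataset(cfg, dir = dir)
  expect_length(list.files(dir, pattern = "_bold\\.nii\\.gz$",
                           recursive = TRUE), 4)
  expect_length(list.files(dir, pattern = "_events\\.tsv$",
                           recursive = TRUE), 4)
  expect_length(list.files(dir, pattern = "_confounds\\.tsv$",
                           recursive = TRUE), 4)
  expect_true(file.exists(file.path(dir, "ground_truth", "sv_weight.nii.gz")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 2)
  expect_length(man$true_parameters, 2)
  # events round-trip through the behaviour reader
  ev <- read_events(list.files(dir, pattern = "_events\\.tsv$",
                               recursive = TRUE, full.names = TRUE)[1])
  expect_true(all(c("gain", "loss", "accept") %in% names(ev)))
  # ground-truth volume round-trips through NIfTI
  v <- read_volume(file.path(dir, "ground_truth", "sv_weight.nii.gz"))
  expect_equal(as.vector(v), as.vector(ds$maps$sv_weight), tolerance = 1e-6)
})
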