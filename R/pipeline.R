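#' Default pipeline configuration
#'
#' Desk-scale study conditions: 24 synthetic participants, a 20x20x20 voxel
#' grid (3 mm), four 64-trial runs at TR = 1 s, loss-averse cohort
#' behaviour, aligned ground-truth gradients, and analysis thresholds of
#' z = 2.3 / alpha = 0.05 (cluster), 5000 permutations at alpha = 0.01 for
#' the paired SV-vs-iDE contrast, and 2.3 SD exclusion rules.
#'
#' @param seed master seed; every stage seed is derived from it.
#' @param n_subjects cohort size.
#' @param dim3,pixdim grid geometry.
#' @param mode ground-truth map mode (`"aligned"`, `"independent"`,
#'   `"opposed"`).
#' @param subject_maps `"shared"` (one set of ground-truth maps for the
#'   cohort) or `"loss_aversion_scaled"` (each subject's SV gradient
#'   zero-crossing shifts with their generating loss aversion).
#' @param ... overrides for nested entries (`task`, `noise`, `glm`,
#'   `group`, `behaviour`).
#' @return nested configuration list of class `"run_config"`.
#' @export
default_config <- function(seed = 1, n_subjects = 24,
                           dim3 = c(20, 20, 20), pixdim = 3,
                           mode = "aligned", subject_maps = "shared", ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = n_subjects,
    dim3 = dim3, pixdim = pixdim,
    mode = mode, subject_maps = subject_maps,
    task = task_config(),
    noise = noise_model(),
    maps = list(axis = 3, amplitude = 1, smoothness = 2, noise_sd = 0.08,
                neg_fraction = 0.5, intercept_amplitude = 1),
    behaviour = list(theta = 0.75, exclusion_sd = 2.3,
                     mean_beta_gain = 0.1, mean_loss_aversion = 2,
                     intercept_sd = 0.2),
    glm = list(fwhm = 5, hp_cutoff = 100, whiten = TRUE),
    group = list(z_thresh = 2.3, alpha = 0.05, n_perm = 500,
                 contrast_n_perm = 5000, contrast_alpha = 0.01,
                 deweight = TRUE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !inherits(cfg[[nm]], "task_config"))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML pipeline configuration
#'
#' Reads a YAML file of overrides and merges it onto [default_config()].
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return a `run_config`.
#' @export
read_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  do.call(default_config, y)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass_deep(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

# deterministic per-stage/subject seeds below 2^31
derive_seed <- function(master, stage, i = 0L) {
  (as.integer(master) * 1009L + stage * 101L + i) %% 2147483629L
}

#' Simulate the full synthetic dataset
#'
#' Generates ground-truth maps, cohort choice models, per-subject gamble
#' schedules, choices, motion, and BOLD runs. With `dir` set, writes a
#' BIDS-like tree (`sub-XX/func/*_events.tsv`, `*_bold.nii.gz`,
#' `*_confounds.tsv`), `ground_truth/` NIfTI maps, and a JSON manifest of
#' seeds and true parameters; otherwise returns everything in memory.
#'
#' @param config a [default_config()].
#' @param dir optional output directory.
#' @param keep_bold keep BOLD matrices in the returned object (default
#'   `TRUE`; `run_pipeline` streams subjects instead).
#' @return list of class `"synthetic_dataset"`: `maps`, `subjects` (each
#'   with `model`, `trials`, `bold` list), `config`, `manifest`.
#' @export
simulate_dataset <- function(config = default_config(), dir = NULL,
                             keep_bold = TRUE) {
  maps <- dataset_maps(config)
  models <- cohort_models(config$n_subjects,
                          mean_beta_gain = config$behaviour$mean_beta_gain,
                          mean_loss_aversion = config$behaviour$mean_loss_aversion,
                          intercept_sd = config$behaviour$intercept_sd,
                          seed = derive_seed(config$seed, 1L))
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subjects[[i]] <- simulate_subject(config, models[[i]], maps, i,
                                      keep_bold = keep_bold)
  }
  names(subjects) <- sprintf("sub-%02d", seq_len(config$n_subjects))
  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    config_hash = config_hash(config),
    true_parameters = lapply(models, function(m)
      as.list(stats::coef(m))),
    map_mode = config$mode)
  ds <- structure(list(maps = maps, subjects = subjects, config = config,
                       manifest = manifest), class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

dataset_maps <- function(config, neg_fraction = NULL) {
  mp <- config$maps
  make_gradient_maps(config$dim3, config$pixdim, axis = mp$axis,
                     amplitude = mp$amplitude, smoothness = mp$smoothness,
                     mode = config$mode,
                     neg_fraction = if (is.null(neg_fraction))
                       mp$neg_fraction else neg_fraction,
                     noise_sd = mp$noise_sd,
                     intercept_amplitude = mp$intercept_amplitude,
                     seed = derive_seed(config$seed, 2L))
}

simulate_subject <- function(config, model, maps, i, keep_bold = TRUE) {
  trials <- simulate_participant(config$task, model,
                                 seed = derive_seed(config$seed, 3L, i),
                                 theta = config$behaviour$theta)
  trials$ide_true <- inverse_decision_entropy(trials$p_accept_true)
  if (identical(config$subject_maps, "loss_aversion_scaled")) {
    la <- model$loss_aversion
    maps <- dataset_maps_subject(config, la, i)
  }
  n_vol <- attr(trials, "n_volumes")
  bold <- vector("list", config$task$n_runs)
  for (r in seq_len(config$task$n_runs)) {
    tr <- trials[trials$run == r, , drop = FALSE]
    tr$sv <- tr$sv_true
    tr$ide <- tr$ide_true
    bold[[r]] <- generate_bold(tr, maps, config$noise, TR = config$task$TR,
                               n_volumes = n_vol[[r]],
                               seed = derive_seed(config$seed, 4L,
                                                  i * 100L + r))
  }
  list(model = model, trials = trials, maps = maps,
       motion = lapply(bold, `[[`, "motion"),
       n_volumes = n_vol,
       bold = if (keep_bold) bold else NULL)
}

# per-subject maps whose negative fraction tracks loss aversion la:
# neg_fraction = la / (1 + la), so la = 2 puts two thirds of the gradient
# on the negative side
dataset_maps_subject <- function(config, la, i) {
  nf <- min(0.9, max(0.1, la / (1 + la)))
  dataset_maps(config, neg_fraction = nf)
}

write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- file.path(dir, "ground_truth")
  dir.create(gt, showWarnings = FALSE)
  write_volume(ds$maps$intercept, file.path(gt, "intercept.nii.gz"))
  write_volume(ds$maps$sv_weight, file.path(gt, "sv_weight.nii.gz"))
  write_volume(ds$maps$ide_weight, file.path(gt, "ide_weight.nii.gz"))
  for (i in seq_along(ds$subjects)) {
    sid <- names(ds$subjects)[i]
    sub <- ds$subjects[[i]]
    fdir <- file.path(dir, sid, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(ds$config$task$n_runs)) {
      tr <- sub$trials[sub$trials$run == r, , drop = FALSE]
      ev <- data.frame(onset = tr$onset, duration = tr$duration,
                       gain = tr$gain, loss = tr$loss,
                       participant_response = ifelse(is.na(tr$response4),
                                                     "NoResp",
                                                     as.character(tr$response4)))
      base <- sprintf("%s_task-gambles_run-%02d", sid, r)
      utils::write.table(ev, file.path(fdir, paste0(base, "_events.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sub$motion[[r]],
                         file.path(fdir, paste0(base, "_confounds.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      b <- sub$bold[[r]]
      arr <- array(t(b$data), dim = c(b$dim3, nrow(b$data)))
      attr(arr, "pixdim") <- b$pixdim
      write_volume(arr, file.path(fdir, paste0(base, "_bold.nii.gz")))
    }
  }
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' behaviour -> first level -> group level -> joint coding, on a synthetic
#' dataset generated from the configuration (subjects are simulated,
#' analysed, and discarded one at a time). Identical configuration and seed
#' give identical numerical outputs.
#'
#' @param config a [default_config()].
#' @param verbose print stage progress.
#' @return list of class `"run_report"`; see Details.
#' @details The report contains `behaviour` (fits, exclusions, iDE
#'   validation), `group` (group maps, cluster tables, conjunctions,
#'   contrast, task-active mask), `joint` (contingency, correlations,
#'   gradient map, loss-aversion voxel ratio), `config`, `config_hash`,
#'   `deviations` (named methodological stand-ins), and per-stage wall
#'   times.
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)
  timings <- c()
  maps <- dataset_maps(config)
  models <- cohort_models(config$n_subjects,
                          mean_beta_gain = config$behaviour$mean_beta_gain,
                          mean_loss_aversion = config$behaviour$mean_loss_aversion,
                          intercept_sd = config$behaviour$intercept_sd,
                          seed = derive_seed(config$seed, 1L))
  n <- config$n_subjects
  fits <- vector("list", n)
  value_tables <- vector("list", n)
  mean_fd <- numeric(n)
  sv_beta <- ide_beta <- int_beta <- NULL
  sv_z <- ide_z <- int_z <- NULL
  say("behaviour + first level (", n, " subjects)")
  for (i in seq_len(n)) {
    sub <- simulate_subject(config, models[[i]], maps, i)
    pf <- fit_participant(sub$trials)
    fits[[i]] <- pf$fit
    value_tables[[i]] <- pf$trials
    mean_fd[i] <- mean(vapply(sub$motion, function(m) mean(m$fd), numeric(1)))
    trial_list <- split(pf$trials, pf$trials$run)
    est <- first_level_subject(sub$bold, trial_list,
                               TR = config$task$TR,
                               fwhm = config$glm$fwhm,
                               hp_cutoff = config$glm$hp_cutoff,
                               whiten = config$glm$whiten)
    if (is.null(sv_beta)) {
      V <- ncol(est$beta)
      sv_beta <- ide_beta <- int_beta <- matrix(NA_real_, n, V)
      sv_z <- ide_z <- int_z <- matrix(NA_real_, n, V)
    }
    sv_beta[i, ] <- est$beta["sv", ]; sv_z[i, ] <- est$z["sv", ]
    ide_beta[i, ] <- est$beta["ide", ]; ide_z[i, ] <- est$z["ide", ]
    int_beta[i, ] <- est$beta["trials", ]; int_z[i, ] <- est$z["trials", ]
  }
  timings["first_level"] <- proc.time()[["elapsed"]] - t0
  names(fits) <- names(value_tables) <- sprintf("sub-%02d", seq_len(n))
  excl <- exclude_participants(fits, motion = mean_fd,
                               sd_limit = config$behaviour$exclusion_sd)
  keep <- !excl$excluded
  if (!any(keep))
    stop("all subjects excluded at the behaviour stage: ",
         paste(excl$reasons, collapse = "; "))
  validation <- validate_ide(value_tables[keep])
  la <- vapply(fits, function(f) f$loss_aversion, numeric(1))

  say("group level")
  t1 <- proc.time()[["elapsed"]]
  gcfg <- config$group
  dim3 <- config$dim3; pixdim <- rep(config$pixdim, length.out = 3)
  gmap <- function(M) group_onesample(M[keep, , drop = FALSE],
                                      deweight = gcfg$deweight,
                                      dim3 = dim3, pixdim = pixdim)
  g_sv <- gmap(sv_beta); g_ide <- gmap(ide_beta); g_int <- gmap(int_beta)
  ci <- function(g, tail, stage)
    cluster_inference(g, z_thresh = gcfg$z_thresh, alpha = gcfg$alpha,
                      n_perm = gcfg$n_perm, tail = tail,
                      seed = derive_seed(config$seed, 5L, stage))
  clusters <- list(sv_pos = ci(g_sv, "positive", 1L),
                   sv_neg = ci(g_sv, "negative", 2L),
                   ide_pos = ci(g_ide, "positive", 3L),
                   ide_neg = ci(g_ide, "negative", 4L))
  conj <- list(pos = ci(conjunction(g_sv, g_ide), "positive", 5L),
               neg = ci(conjunction(g_sv, g_ide), "negative", 6L))
  contrast <- contrast_sv_vs_ide(
    sv_z[keep, , drop = FALSE], ide_z[keep, , drop = FALSE],
    sv_group = g_sv, ide_group = g_ide,
    n_perm = gcfg$contrast_n_perm, alpha = gcfg$contrast_alpha,
    dim3 = dim3, pixdim = pixdim,
    seed = derive_seed(config$seed, 6L))
  active <- task_active_mask(g_int, gcfg$z_thresh)
  group <- list(sv = g_sv, ide = g_ide, intercept = g_int,
                clusters = clusters, conjunction = conj,
                contrast = contrast, task_active = active,
                dim3 = dim3, pixdim = pixdim)
  timings["group_level"] <- proc.time()[["elapsed"]] - t1

  say("joint coding")
  t2 <- proc.time()[["elapsed"]]
  joint <- joint_coding_stage(group, maps = maps,
                              subject_sv_z = sv_z[keep, , drop = FALSE],
                              loss_aversion = la[keep])
  timings["joint_coding"] <- proc.time()[["elapsed"]] - t2

  structure(list(
    behaviour = list(fits = fits, exclusions = excl, validation = validation,
                     loss_aversion = la, mean_fd = mean_fd),
    group = group, joint = joint, maps = maps,
    subject_maps = list(sv_beta = sv_beta, ide_beta = ide_beta,
                        sv_z = sv_z, ide_z = ide_z, int_z = int_z),
    config = config, config_hash = config_hash(config),
    deviations = pipeline_deviations(), timings = timings,
    n_kept = sum(keep)), class = "run_report")
}

#' Joint-coding stage on cached group results
#'
#' Runs the joint-coding analyses from a finished group stage; re-running
#' this on cached group maps reproduces the full-run results exactly.
#'
#' @param group the `group` element of a [run_pipeline()] report (group
#'   maps, cluster tables, task-active mask, geometry).
#' @param maps optional ground-truth maps (adds truth-based ROI summaries).
#' @param subject_sv_z optional subjects x voxels SV Z stack for the
#'   loss-aversion voxel ratio.
#' @param loss_aversion behavioural loss-aversion vector matching
#'   `subject_sv_z` rows.
#' @return list with `contingency`, `correlations`, `gradient`,
#'   `la_ratio`, and the significant sign maps used.
#' @export
joint_coding_stage <- function(group, maps = NULL, subject_sv_z = NULL,
                               loss_aversion = NULL) {
  sig <- lapply(group$clusters, significant_voxels)
  active <- as.vector(group$task_active) > 0
  contingency <- tryCatch(
    sign_contingency(sig$sv_pos, sig$sv_neg, sig$ide_pos, sig$ide_neg,
                     mask = active),
    error = function(e) e)
  corr <- list(whole = map_correlation(group$sv$effect, group$ide$effect,
                                       mask = active, name = "task_active"))
  overlap <- list()
  if (!is.null(maps)) {
    for (nm in names(maps$roi_masks)) {
      corr[[nm]] <- map_correlation(group$sv$effect, group$ide$effect,
                                    mask = maps$roi_masks[[nm]], name = nm)
      overlap[[nm]] <- roi_overlap(sig$sv_pos, sig$sv_neg, sig$ide_pos,
                                   sig$ide_neg, maps$roi_masks[[nm]])
    }
  }
  grad <- gradient_map(array(group$sv$effect, group$dim3),
                       array(group$ide$effect, group$dim3),
                       mask = active)
  la_ratio <- NULL
  if (!is.null(subject_sv_z) && !is.null(loss_aversion))
    la_ratio <- loss_aversion_voxel_ratio(subject_sv_z, loss_aversion,
                                          z_thresh = 2.3)
  list(contingency = contingency, correlations = corr, overlap = overlap,
       gradient = grad, la_ratio = la_ratio, sig_maps = sig)
}

#' Voxels inside the significant clusters of a cluster table
#'
#' @param tab a `cluster_table` from [cluster_inference()].
#' @return logical vector over the grid (TRUE inside surviving clusters).
#' @export
significant_voxels <- function(tab) {
  labels <- attr(tab, "labels")
  as.vector(labels %in% tab$index & labels > 0)
}

pipeline_deviations <- function() {
  list(
    autocorrelation = "per-voxel AR(1) Cochrane-Orcutt prewhitening in place of a locally regularised autocorrelation model",
    highpass = "discrete cosine + linear drift-basis projection (100 s cutoff) in place of a running-line detrend",
    group_model = "method-of-moments random effects with one-round Huber deweighting in place of two-stage Bayesian mixed effects",
    cluster_p = "sign-flip permutation of maximum cluster extent in place of Gaussian-random-field cluster p-values")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$n_kept, "of", x$config$n_subjects,
      "subjects kept; mode =", x$config$mode, "\n")
  cat("Config hash:", x$config_hash, "\n")
  if (!inherits(x$joint$contingency, "error")) {
    cc <- x$joint$contingency
    if (is.nan(cc$chi2))
      cat(sprintf("Sign contingency: diagonal %.1f%% (chi2 undefined: a sign class is empty, i.e. perfect alignment)\n",
                  cc$observed_pct[1, 1] + cc$observed_pct[2, 2]))
    else
      cat(sprintf("Sign contingency: chi2 = %.2f (p = %.3g), diagonal %.1f%%\n",
                  cc$chi2, cc$p,
                  cc$observed_pct[1, 1] + cc$observed_pct[2, 2]))
  }
  cat(sprintf("Whole-mask SV~iDE beta correlation: r = %.3f\n",
              x$joint$correlations$whole$r))
  cat("Stage timings (s):",
      paste(names(x$timings), round(x$timings, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cluster table as TSV
#'
#' @param tab `cluster_table`.
#' @param path output TSV path.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
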