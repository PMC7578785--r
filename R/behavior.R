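#' Read a BIDS-style events table
#'
#' Expects tab-separated columns `onset`, `duration`, `gain`, `loss`,
#' `participant_response` (one of `strongly_reject`, `weakly_reject`,
#' `weakly_accept`, `strongly_accept`, or `NoResp`; label case and
#' spaces/underscores are normalised). Adds the derived binary `accept`
#' column (`NA` for missing responses).
#'
#' @param path path to a `*_events.tsv` file.
#' @return data frame of trials ordered by onset.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("onset", "duration", "gain", "loss", "participant_response")
  miss <- setdiff(req, names(ev))
  if (length(miss)) stop("events file missing columns: ", paste(miss, collapse = ", "))
  normalise_events(ev)
}

normalise_events <- function(ev) {
  lab <- tolower(gsub("[ _-]+", "_", trimws(ev$participant_response)))
  lab[lab %in% c("noresp", "no_resp", "n/a", "na", "")] <- NA
  bad <- !is.na(lab) & !lab %in% response_levels()
  if (any(bad)) stop("unrecognised response labels: ",
                     paste(unique(ev$participant_response[bad]), collapse = ", "))
  ev$response4 <- factor(lab, levels = response_levels())
  ev$accept <- ifelse(is.na(lab), NA_real_,
                      as.numeric(lab %in% c("weakly_accept", "strongly_accept")))
  if (any(ev$duration <= 0)) stop("trial durations must be positive")
  ord <- order(ev$onset)
  ev <- ev[ord, , drop = FALSE]
  if (is.unsorted(ev$onset, strictly = TRUE))
    stop("onsets must be strictly increasing within a run")
  rownames(ev) <- NULL
  ev
}

#' Fit the choice model for one participant across runs
#'
#' Pools all runs' trials (the model has no run term) and fits
#' [choice_model()], then attaches trial-wise SV, acceptance probability,
#' decision entropy, iDE and probability-correct to the trial table using the
#' fitted coefficients. Trials without a response are dropped from fitting
#' but retained (with values) only if `keep_missing`.
#'
#' @param trials data frame of trials (from [read_events()] or
#'   [simulate_participant()]), with `gain`, `loss`, `accept` columns and
#'   optionally `run`, `onset`, `duration`, `response4`.
#' @param keep_missing keep missing-response rows in the returned trial
#'   table (they are never used for fitting). Default `FALSE`, matching the
#'   treatment of missing responses in the event regressors.
#' @param ... passed to [choice_model()].
#' @return list with elements `fit` (the `choice_model`) and `trials` (the
#'   trial table augmented with `sv`, `p_accept`, `p_reject`, `de`, `ide`,
#'   `p_correct`).
#' @export
fit_participant <- function(trials, keep_missing = FALSE, ...) {
  fit <- choice_model(accept ~ gain + loss, trials, ...)
  keep <- if (keep_missing) rep(TRUE, nrow(trials)) else !is.na(trials$accept)
  out <- trials[keep, , drop = FALSE]
  vals <- trial_values(fit, newdata = out)
  list(fit = fit, trials = cbind(out, vals))
}

#' Apply the cohort exclusion rules
#'
#' A participant is excluded when either gain or loss coefficient lies more
#' than `sd_limit` group standard deviations from the group mean, or when
#' the motion summary (mean framewise displacement) exceeds the group mean
#' by more than `sd_limit` standard deviations. Group statistics include the
#' candidate participant (ddof = 1). A zero group SD yields no exclusions on
#' that measure.
#'
#' @param fits named list of `choice_model` fits (or a data frame with
#'   columns `beta_gains`, `beta_losses`).
#' @param motion optional named numeric vector of per-participant mean
#'   framewise displacement (mm).
#' @param sd_limit exclusion threshold in group SD units (default 2.3).
#' @return data frame with `participant`, `excluded`, `reasons`.
#' @export
exclude_participants <- function(fits, motion = NULL, sd_limit = 2.3) {
  if (is.data.frame(fits)) {
    bg <- fits$beta_gains; bl <- fits$beta_losses
    ids <- if (!is.null(fits$participant)) as.character(fits$participant)
           else rownames(fits)
  } else {
    bg <- vapply(fits, function(f) stats::coef(f)[["gain"]], numeric(1))
    bl <- vapply(fits, function(f) stats::coef(f)[["loss"]], numeric(1))
    ids <- names(fits)
  }
  n <- length(bg)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < 3) stop("need at least 3 participants for group exclusion statistics")
  reasons <- rep("", n)
  flag <- function(x, two_sided) {
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) return(rep(FALSE, length(x)))
    if (two_sided) abs(x - m) > sd_limit * s else x - m > sd_limit * s
  }
  g_out <- flag(bg, TRUE)
  l_out <- flag(bl, TRUE)
  reasons[g_out] <- paste0(reasons[g_out], "gain_coefficient_outlier;")
  reasons[l_out] <- paste0(reasons[l_out], "loss_coefficient_outlier;")
  if (!is.null(motion)) {
    if (length(motion) != n) stop("motion summary length must match fits")
    m_out <- flag(as.numeric(motion), FALSE)
    reasons[m_out] <- paste0(reasons[m_out], "high_motion;")
  }
  data.frame(participant = ids, excluded = reasons != "",
             reasons = sub(";$", "", reasons), stringsAsFactors = FALSE)
}

#' Behavioural validation of the iDE measure
#'
#' Computes, per participant: the Spearman correlation between trial-wise SV
#' and acceptance probability (expected 1 whenever SV values are tie-free,
#' since the inverse logit is strictly monotone), and between iDE and the
#' probability of being correct (both strictly increasing in
#' `|p_accept - 0.5|`). Summarises each with the group mean, SD, and a
#' one-sample t test against zero. If 4-level responses are present, also
#' compares per-participant mean iDE for weak vs strong responses with a
#' Welch two-sample t test (strong minus weak; the model predicts weak
#' responses carry lower iDE).
#'
#' @param value_tables named list of per-participant trial tables carrying
#'   `sv`, `p_accept`, `ide`, `p_correct` and optionally `response4` (as
#'   returned by [fit_participant()]).
#' @return list of class `"ide_validation"` with `per_participant`,
#'   `sv_p_accept` and `ide_p_correct` summaries, and `weak_strong` (Welch
#'   test, or `NULL` with a warning when either response class is absent).
#' @export
validate_ide <- function(value_tables) {
  stopifnot(length(value_tables) >= 1)
  ids <- names(value_tables)
  if (is.null(ids)) ids <- as.character(seq_along(value_tables))
  rho_sv <- vapply(value_tables, function(d)
    stats::cor(d$sv, d$p_accept, method = "spearman"), numeric(1))
  rho_ide <- vapply(value_tables, function(d)
    stats::cor(d$ide, d$p_correct, method = "spearman"), numeric(1))
  weak_mean <- strong_mean <- rep(NA_real_, length(value_tables))
  for (i in seq_along(value_tables)) {
    d <- value_tables[[i]]
    if (is.null(d$response4)) next
    w <- d$response4 %in% c("weakly_reject", "weakly_accept")
    s <- d$response4 %in% c("strongly_reject", "strongly_accept")
    if (any(w)) weak_mean[i] <- mean(d$ide[w])
    if (any(s)) strong_mean[i] <- mean(d$ide[s])
  }
  one_sample <- function(x) {
    x <- x[!is.na(x)]
    tt <- if (length(x) >= 2 && stats::sd(x) > 0)
      tryCatch(stats::t.test(x, mu = 0), error = function(e) NULL) else NULL
    list(mean = mean(x), sd = stats::sd(x),
         t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
         p = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  weak_strong <- NULL
  wv <- weak_mean[!is.na(weak_mean)]
  sv_ <- strong_mean[!is.na(strong_mean)]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  if (length(wv) == 0 || length(sv_) == 0) {
    warning("no weak or no strong responses present; Welch test skipped")
  } else if (sd0(wv) == 0 && sd0(sv_) == 0) {
    d <- mean(sv_) - mean(wv)
    weak_strong <- list(mean_weak = mean(wv), mean_strong = mean(sv_),
                        t = if (d == 0) 0 else sign(d) * Inf,
                        df = NA_real_, p = if (d == 0) 1 else 0)
  } else {
    tt <- tryCatch(stats::t.test(sv_, wv, var.equal = FALSE),
                   error = function(e) NULL)
    weak_strong <- list(mean_weak = mean(wv), mean_strong = mean(sv_),
                        sd_weak = sd0(wv), sd_strong = sd0(sv_),
                        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                        df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                        p = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  structure(list(
    per_participant = data.frame(participant = ids, rho_sv_p_accept = rho_sv,
                                 rho_ide_p_correct = rho_ide,
                                 mean_weak_ide = weak_mean,
                                 mean_strong_ide = strong_mean),
    sv_p_accept = one_sample(rho_sv),
    ide_p_correct = one_sample(rho_ide),
    weak_strong = weak_strong), class = "ide_validation")
}

#' @export
print.ide_validation <- function(x, ...) {
  cat("Behavioural validation of iDE (", nrow(x$per_participant),
      " participants)\n", sep = "")
  cat(sprintf("  Spearman SV ~ p_accept : mean %.4f (sd %.4f)\n",
              x$sv_p_accept$mean, x$sv_p_accept$sd))
  cat(sprintf("  Spearman iDE ~ p_correct: mean %.4f (sd %.4f)\n",
              x$ide_p_correct$mean, x$ide_p_correct$sd))
  if (!is.null(x$weak_strong))
    cat(sprintf("  Weak vs strong iDE: %.3f vs %.3f, Welch t(%.2f) = %.2f\n",
                x$weak_strong$mean_weak, x$weak_strong$mean_strong,
                x$weak_strong$df, x$weak_strong$t))
  invisible(x)
}

#' Write per-participant fit results
#'
#' Writes a JSON file with coefficients and diagnostic flags, and a TSV of
#' trial-wise derived values.
#'
#' @param pfit result of [fit_participant()].
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the list written to JSON.
#' @export
write_participant_fit <- function(pfit, json_path = NULL, tsv_path = NULL) {
  b <- stats::coef(pfit$fit)
  info <- list(beta_gains = unname(b[["gain"]]),
               beta_losses = unname(b[["loss"]]),
               intercept = unname(b[["(Intercept)"]]),
               loss_aversion = pfit$fit$loss_aversion,
               converged = pfit$fit$converged,
               separable = pfit$fit$separable,
               n_trials = pfit$fit$n,
               n_dropped = pfit$fit$n_dropped)
  if (!is.null(json_path))
    jsonlite::write_json(info, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(pfit$trials, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(info)
}
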