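#' Sign contingency of SV and iDE effects
#'
#' Among mask voxels significant for both variables, cross-classifies the
#' effect signs into a 2x2 table (SV +/- by iDE +/-), computes expected
#' cells from the marginals, and tests independence with a chi-squared test
#' (df = 1, no continuity correction). Joint positive-positive and
#' negative-negative dominance is the signature of aligned coding.
#'
#' @param sv_pos,sv_neg,ide_pos,ide_neg logical volumes (or vectors) of
#'   significant voxels per variable and sign; within a variable the two
#'   sets must be disjoint.
#' @param mask logical task-active mask (default: all voxels).
#' @return list of class `"contingency_result"`: `observed`, `expected`
#'   (counts), `observed_pct`, `expected_pct` (to one decimal), `chi2`,
#'   `df`, `p`, `n_joint`.
#' @export
sign_contingency <- function(sv_pos, sv_neg, ide_pos, ide_neg, mask = NULL) {
  svp <- as.vector(sv_pos) > 0; svn <- as.vector(sv_neg) > 0
  idp <- as.vector(ide_pos) > 0; idn <- as.vector(ide_neg) > 0
  lens <- lengths(list(svp, svn, idp, idn))
  if (length(unique(lens)) != 1) stop("sign maps must share one grid")
  if (any(svp & svn) || any(idp & idn))
    stop("positive and negative sets must be disjoint within a variable")
  m <- if (is.null(mask)) rep(TRUE, length(svp)) else as.vector(mask) > 0
  joint <- m & (svp | svn) & (idp | idn)
  if (!any(joint)) stop("no overlapping effects: no voxel significant for both variables")
  svs <- ifelse(svp[joint], "sv_pos", "sv_neg")
  ids <- ifelse(idp[joint], "ide_pos", "ide_neg")
  tab <- table(factor(svs, c("sv_pos", "sv_neg")),
               factor(ids, c("ide_pos", "ide_neg")))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  structure(list(observed = unclass(tab), expected = unclass(ht$expected),
                 observed_pct = round(100 * unclass(tab) / n, 1),
                 expected_pct = round(100 * unclass(ht$expected) / n, 1),
                 chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, n_joint = n),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("SV x iDE sign contingency over", x$n_joint, "jointly significant voxels\n")
  cat("Observed % (expected % under independence):\n")
  for (i in 1:2) for (j in 1:2)
    cat(sprintf("  %s / %s: %.1f (%.1f)\n",
                rownames(x$observed)[i], colnames(x$observed)[j],
                x$observed_pct[i, j], x$expected_pct[i, j]))
  cat(sprintf("chi-squared = %.2f, df = %d, p = %.3g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Sign-agreement percentage within an ROI
#'
#' Among ROI voxels significant for both variables, the percentage whose SV
#' and iDE effect signs match.
#'
#' @inheritParams sign_contingency
#' @param roi_mask logical ROI volume (binarise probabilistic masks with
#'   [binarise_mask()] first).
#' @return list with `percent` (NA with `defined = FALSE` when no joint
#'   voxels), `n_joint`, `n_match`.
#' @export
roi_overlap <- function(sv_pos, sv_neg, ide_pos, ide_neg, roi_mask) {
  roi <- as.vector(roi_mask) > 0
  svp <- as.vector(sv_pos) > 0; svn <- as.vector(sv_neg) > 0
  idp <- as.vector(ide_pos) > 0; idn <- as.vector(ide_neg) > 0
  joint <- roi & (svp | svn) & (idp | idn)
  if (!any(joint))
    return(list(percent = NA_real_, n_joint = 0L, n_match = 0L,
                defined = FALSE))
  match_sign <- (svp & idp) | (svn & idn)
  n_match <- sum(match_sign[joint])
  list(percent = 100 * n_match / sum(joint), n_joint = sum(joint),
       n_match = n_match, defined = TRUE)
}

#' Voxelwise correlation between two statistic maps
#'
#' Pearson correlation across masked voxels between two group-level maps
#' (e.g. the SV and iDE beta maps), as used for the ROI and whole-brain
#' map-correlation analyses.
#'
#' @param a,b volumes or numeric vectors on one grid.
#' @param mask logical mask or ROI (default: all voxels).
#' @param name region label carried into the result.
#' @return list of class `"map_correlation"`: `region`, `n_voxels`, `r`,
#'   `p` (`r = NA` with `defined = FALSE` on zero-variance input).
#' @export
map_correlation <- function(a, b, mask = NULL, name = "mask") {
  av <- as.vector(a); bv <- as.vector(b)
  if (length(av) != length(bv)) stop("maps must share one grid")
  m <- if (is.null(mask)) rep(TRUE, length(av)) else as.vector(mask) > 0
  av <- av[m]; bv <- bv[m]
  if (length(av) < 3) stop("need at least 3 masked voxels for a correlation")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    return(structure(list(region = name, n_voxels = length(av), r = NA_real_,
                          p = NA_real_, defined = FALSE),
                     class = "map_correlation"))
  ct <- stats::cor.test(av, bv, method = "pearson")
  structure(list(region = name, n_voxels = length(av),
                 r = unname(ct$estimate), p = ct$p.value, defined = TRUE),
            class = "map_correlation")
}

#' @export
print.map_correlation <- function(x, ...) {
  if (!x$defined) cat("Map correlation (", x$region, "): undefined (zero variance)\n", sep = "")
  else cat(sprintf("Map correlation (%s): r = %.3f over %d voxels, p = %.3g\n",
                   x$region, x$r, x$n_voxels, x$p))
  invisible(x)
}

#' Gradient summation map
#'
#' Z-scores each input map across masked voxels (independently) and sums
#' them. Large positive values mark jointly positive coding, large negative
#' values jointly negative coding, and near-zero values cancellation —
#' the summary used to visualise aligned dorsoventral gradients.
#'
#' @param sv_map,ide_map statistic volumes on one grid.
#' @param mask logical mask (default: all voxels).
#' @return volume with the summed z-scores inside the mask and 0 outside;
#'   attributes `zscored_sv` and `zscored_ide` hold the standardised inputs.
#' @export
gradient_map <- function(sv_map, ide_map, mask = NULL) {
  av <- as.vector(sv_map); bv <- as.vector(ide_map)
  if (length(av) != length(bv)) stop("maps must share one grid")
  m <- if (is.null(mask)) rep(TRUE, length(av)) else as.vector(mask) > 0
  zsc <- function(x) {
    s <- stats::sd(x[m])
    if (s == 0) stop("zero-variance map inside mask; cannot z-score")
    out <- numeric(length(x))
    out[m] <- (x[m] - mean(x[m])) / s
    out
  }
  za <- zsc(av); zb <- zsc(bv)
  out <- za + zb
  if (!is.null(dim(sv_map))) out <- array(out, dim(sv_map))
  attr(out, "pixdim") <- voxdim(sv_map)
  attr(out, "zscored_sv") <- za
  attr(out, "zscored_ide") <- zb
  out
}

#' Loss-aversion voxel ratio
#'
#' Per participant, the ratio of negative to positive SV voxels in the
#' subject-level Z map (counts beyond -z_thresh and +z_thresh), and its
#' Spearman correlation across participants with behavioural loss aversion
#' (`-beta_losses / beta_gains`).
#'
#' @param subject_z subjects x voxels matrix of subject-level SV Z maps.
#' @param loss_aversion numeric vector of behavioural loss-aversion ratios
#'   (one per subject).
#' @param z_thresh voxel threshold (default 2.3).
#' @param mask optional logical mask.
#' @return list of class `"la_voxel_ratio"`: per-subject `ratio` (NA where
#'   undefined), `n_pos`, `n_neg`, `rho` and `p` for the rank correlation
#'   over subjects with a defined ratio, `n_used`.
#' @export
loss_aversion_voxel_ratio <- function(subject_z, loss_aversion,
                                      z_thresh = 2.3, mask = NULL) {
  n <- nrow(subject_z)
  if (length(loss_aversion) != n)
    stop("one loss-aversion value per subject required")
  m <- if (is.null(mask)) rep(TRUE, ncol(subject_z)) else as.vector(mask) > 0
  n_pos <- rowSums(subject_z[, m, drop = FALSE] > z_thresh)
  n_neg <- rowSums(subject_z[, m, drop = FALSE] < -z_thresh)
  ratio <- ifelse(n_pos > 0, n_neg / n_pos, NA_real_)
  if (any(is.na(ratio)))
    warning(sum(is.na(ratio)),
            " participant(s) had no positive supra-threshold voxels; skipped")
  ok <- !is.na(ratio) & !is.na(loss_aversion)
  rho <- p <- NA_real_
  if (sum(ok) >= 3 && stats::sd(ratio[ok]) > 0 &&
      stats::sd(loss_aversion[ok]) > 0) {
    ct <- suppressWarnings(stats::cor.test(ratio[ok], loss_aversion[ok],
                                           method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(ratio = ratio, n_pos = n_pos, n_neg = n_neg,
                 rho = rho, p = p, n_used = sum(ok)),
            class = "la_voxel_ratio")
}

#' Binarise a probabilistic mask
#'
#' Nearest-neighbour resamples a mask to a target grid if needed, then
#' binarises at the given threshold (default 50%).
#'
#' @param mask numeric volume (probabilities in 0-1 or 0-100).
#' @param dim3 target grid (default: the mask's own).
#' @param threshold binarisation threshold as a fraction (default 0.5).
#' @return logical volume.
#' @export
binarise_mask <- function(mask, dim3 = NULL, threshold = 0.5) {
  v <- mask
  if (max(v, na.rm = TRUE) > 1) v <- v / 100
  if (!is.null(dim3) && !all(dim(mask) == dim3)) {
    src <- dim(mask)
    idx <- lapply(1:3, function(ax)
      pmin(src[ax], pmax(1L, round((seq_len(dim3[ax]) - 0.5) *
                                     src[ax] / dim3[ax] + 0.5))))
    v <- v[idx[[1]], idx[[2]], idx[[3]]]
  }
  out <- v >= threshold
  attr(out, "pixdim") <- voxdim(mask)
  out
}
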