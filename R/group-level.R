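#' Group-level one-sample random-effects map
#'
#' Per voxel, a one-sample test across subjects with method-of-moments
#' between-subject variance (the sample variance of the subject values).
#' With `deweight = TRUE`, one round of Huber reweighting (c = 1.345 on
#' standardised residuals) downweights outlying subjects before the final
#' estimate — a lightweight analogue of outlier-deweighted mixed-effects
#' estimation. The t statistic (n - 1 df) is mapped to a standard-normal Z.
#'
#' @param maps subjects x voxels matrix of subject-level statistics (betas
#'   or Z maps), or a list of volumes / vectors.
#' @param deweight apply Huber deweighting (default `TRUE`).
#' @param dim3,pixdim spatial geometry (taken from volume inputs when
#'   available).
#' @param mask optional logical vector/volume restricting analysis.
#' @return list of class `"group_map"`: `effect`, `se`, `z` (vectors of
#'   length V), `stack` (the subject matrix), `weights` (subject weight
#'   summary), `n_subjects`, `mask`, `dim3`, `pixdim`.
#' @export
group_onesample <- function(maps, deweight = TRUE, dim3 = NULL,
                            pixdim = NULL, mask = NULL) {
  if (is.list(maps)) {
    if (is.null(dim3) && !is.null(dim(maps[[1]]))) dim3 <- dim(maps[[1]])
    if (is.null(pixdim)) pixdim <- voxdim(maps[[1]])
    maps <- do.call(rbind, lapply(maps, as.vector))
  }
  n <- nrow(maps)
  if (n < 3) stop("need at least 3 subjects for group inference")
  V <- ncol(maps)
  if (is.null(dim3)) dim3 <- c(V, 1, 1)
  if (is.null(pixdim)) pixdim <- rep(3, 3)
  mask <- if (is.null(mask)) rep(TRUE, V) else as.vector(mask) > 0
  st <- group_stats(maps, deweight)
  z <- t_to_z(st$t, n - 1)
  z[!mask] <- 0
  structure(list(effect = st$effect, se = st$se, z = z, stack = maps,
                 weights = st$weights, deweight = deweight,
                 n_subjects = n, mask = mask, dim3 = dim3, pixdim = pixdim),
            class = "group_map")
}

# vectorised one-sample statistics with optional single-round Huber
# deweighting; works on a subjects x voxels matrix
group_stats <- function(Y, deweight, huber_c = 1.345) {
  n <- nrow(Y)
  mu <- colMeans(Y)
  s <- sqrt(colSums(sweep(Y, 2, mu)^2) / (n - 1))
  w_summary <- rep(1, n)
  if (deweight) {
    s_safe <- pmax(s, .Machine$double.eps)
    R <- sweep(sweep(Y, 2, mu), 2, s_safe, "/")
    W <- huber_c / pmax(abs(R), .Machine$double.eps)
    W[W > 1] <- 1
    sw <- colSums(W)
    mu <- colSums(W * Y) / sw
    dev <- Y - rep(mu, each = n)
    s <- sqrt(colSums(W * dev^2) / pmax(sw - 1, 1))
    neff <- sw^2 / colSums(W^2)
    se <- s / sqrt(neff)
    w_summary <- rowMeans(W)
  } else {
    se <- s / sqrt(n)
  }
  se <- pmax(se, .Machine$double.eps)
  list(effect = mu, se = se, t = mu / se, weights = w_summary)
}

#' @export
print.group_map <- function(x, ...) {
  cat("Group one-sample map:", x$n_subjects, "subjects,",
      sum(x$mask), "in-mask voxels\n")
  cat("  Z range:", paste(signif(range(x$z[x$mask]), 4), collapse = " .. "),
      if (x$deweight) " (Huber-deweighted)" else "", "\n")
  invisible(x)
}

#' Cluster-level inference by sign-flip permutation
#'
#' Thresholds the group Z map at `z_thresh`, forms 26-connected clusters,
#' and assigns each a family-wise corrected p value from the permutation
#' null of the maximum cluster extent: subject maps are sign-flipped at
#' random, the group Z map recomputed, and the maximum supra-threshold
#' cluster size recorded. Negative-tail inference negates the maps first.
#'
#' @param group a `group_map` (or conjunction object from [conjunction()]).
#' @param z_thresh cluster-forming threshold (default 2.3).
#' @param alpha cluster-wise significance level (default 0.05).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param tail `"positive"` or `"negative"`.
#' @param seed permutation seed.
#' @return data frame of class `"cluster_table"` with columns `index`,
#'   `n_voxels`, `peak_z`, `x_mm`, `y_mm`, `z_mm`, `p_corrected`, `sign`;
#'   attribute `null_max_extent` carries the permutation distribution.
#' @export
cluster_inference <- function(group, z_thresh = 2.3, alpha = 0.05,
                              n_perm = 1000, tail = c("positive", "negative"),
                              seed = 1) {
  tail <- match.arg(tail)
  flip <- if (tail == "negative") -1 else 1
  zfun <- group_zfun(group)
  mask <- group$mask
  if (!any(mask)) stop("empty analysis mask")
  dim3 <- group$dim3; pixdim <- group$pixdim
  z_obs <- flip * zfun(rep(1, group$n_subjects))
  obs <- cluster_sizes(z_obs, mask, dim3, z_thresh)
  set.seed(seed)
  null_max <- numeric(n_perm)
  n <- group$n_subjects
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    zb <- flip * zfun(s)
    null_max[b] <- max(cluster_sizes(zb, mask, dim3, z_thresh)$sizes, 0)
  }
  tab <- cluster_table(obs, z_obs, null_max, n_perm, dim3, pixdim,
                       sign = if (tail == "positive") "positive" else "negative")
  tab <- tab[tab$p_corrected <= alpha, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "null_max_extent") <- null_max
  attr(tab, "z_thresh") <- z_thresh
  attr(tab, "labels") <- obs$labels
  attr(tab, "kept") <- obs$ids[match(tab$index, obs$ids)]
  class(tab) <- c("cluster_table", class(tab))
  tab
}

# closure recomputing the group Z map under a sign-flip vector; for
# conjunction objects, the minimum of the parents' flipped Z maps
group_zfun <- function(group) {
  if (inherits(group, "conjunction_map")) {
    fa <- group_zfun(group$a); fb <- group_zfun(group$b)
    function(s) pmin(fa(s), fb(s))
  } else {
    stack <- group$stack; n <- group$n_subjects; dw <- group$deweight
    function(s) {
      st <- group_stats(s * stack, dw)
      t_to_z(st$t, n - 1)
    }
  }
}

cluster_sizes <- function(z, mask, dim3, z_thresh) {
  supra <- array(z >= z_thresh & mask, dim3)
  labels <- label_components(supra)
  if (!any(supra)) return(list(sizes = integer(0), ids = integer(0),
                               labels = labels))
  tb <- tabulate(labels[labels > 0])
  list(sizes = tb, ids = seq_along(tb), labels = labels)
}

cluster_table <- function(obs, z, null_max, n_perm, dim3, pixdim, sign) {
  if (length(obs$sizes) == 0)
    return(data.frame(index = integer(0), n_voxels = integer(0),
                      peak_z = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      p_corrected = numeric(0), sign = character(0)))
  zv <- array(z, dim3)
  rows <- lapply(obs$ids, function(k) {
    vox <- which(obs$labels == k)
    pk <- vox[which.max(zv[vox])]
    mmc <- voxel_to_mm(arrayInd(pk, dim3), dim3, pixdim)
    data.frame(index = k, n_voxels = obs$sizes[k], peak_z = max(zv[vox]),
               x_mm = mmc[1], y_mm = mmc[2], z_mm = mmc[3],
               p_corrected = (1 + sum(null_max >= obs$sizes[k])) / (n_perm + 1),
               sign = sign)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_voxels), , drop = FALSE]
}

#' Minimum-statistic conjunction of two group maps
#'
#' Voxelwise `Z_conj = min(Z_A, Z_B)`; a voxel can only survive the cluster
#' threshold if both parent effects individually exceed it. Returns an
#' object that [cluster_inference()] accepts: permutations flip the two
#' parents' subject maps jointly.
#'
#' @param a,b `group_map` objects on a common grid.
#' @return list of class `"conjunction_map"` with the combined `z` and the
#'   parents.
#' @export
conjunction <- function(a, b) {
  if (!all(a$dim3 == b$dim3)) stop("grid mismatch between conjunction inputs")
  if (a$n_subjects != b$n_subjects)
    stop("conjunction parents must share the subject set")
  structure(list(a = a, b = b, z = pmin(a$z, b$z),
                 mask = a$mask & b$mask, dim3 = a$dim3, pixdim = a$pixdim,
                 n_subjects = a$n_subjects), class = "conjunction_map")
}

#' Task-active voxel mask
#'
#' Voxels whose group intercept (unmodulated trial response) |Z| reaches
#' `z_thresh`; used to restrict joint-coding analyses to voxels that
#' respond to trials at all.
#'
#' @param group_intercept `group_map` for the trial-intercept regressor.
#' @param z_thresh threshold on |Z| (default 2.3).
#' @return logical volume of the group's grid.
#' @export
task_active_mask <- function(group_intercept, z_thresh = 2.3) {
  m <- abs(group_intercept$z) >= z_thresh & group_intercept$mask
  out <- array(m, group_intercept$dim3)
  attr(out, "pixdim") <- group_intercept$pixdim
  out
}

#' Paired permutation contrast of SV vs iDE
#'
#' Tests the paired difference of subject-level Z maps with a voxelwise
#' sign-flip permutation one-sample test (both directions: iDE - SV and
#' SV - iDE). Permutation p values (one-tailed, with the customary
#' `(1 + k) / (n_perm + 1)` estimator, so the attainable Z saturates at
#' `qnorm(1 - 1/(n_perm + 1))`) are converted to Z, conjoined with the
#' matching main-effect Z map (minimum statistic), and masked by the sign
#' of `|Z_iDE| - |Z_SV|`. Voxelwise family-wise correction uses the
#' max-statistic distribution from the same permutations.
#'
#' @param sv_maps,ide_maps subjects x voxels matrices of subject-level Z
#'   statistics (paired by row).
#' @param sv_group,ide_group main-effect `group_map`s (for the conjunction);
#'   computed from the stacks when omitted.
#' @param n_perm permutations (default 5000).
#' @param alpha significance level on the corrected p (default 0.01).
#' @param dim3,pixdim geometry.
#' @param mask optional logical mask.
#' @param seed permutation seed.
#' @return list of class `"sv_ide_contrast"` with elements `ide_gt_sv` and
#'   `sv_gt_ide`, each a `cluster_table`, plus the permutation Z maps.
#' @export
contrast_sv_vs_ide <- function(sv_maps, ide_maps, sv_group = NULL,
                               ide_group = NULL, n_perm = 5000, alpha = 0.01,
                               dim3 = NULL, pixdim = NULL, mask = NULL,
                               seed = 1) {
  if (!all(dim(sv_maps) == dim(ide_maps)))
    stop("SV and iDE subject map stacks must be paired (same dimensions)")
  n <- nrow(sv_maps); V <- ncol(sv_maps)
  if (is.null(dim3)) dim3 <- c(V, 1, 1)
  if (is.null(pixdim)) pixdim <- rep(3, 3)
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.vector(mask) > 0
  if (is.null(sv_group))
    sv_group <- group_onesample(sv_maps, dim3 = dim3, pixdim = pixdim,
                                mask = mask)
  if (is.null(ide_group))
    ide_group <- group_onesample(ide_maps, dim3 = dim3, pixdim = pixdim,
                                 mask = mask)
  D <- ide_maps - sv_maps
  obs <- colMeans(D)
  set.seed(seed)
  exc_pos <- rep(0L, V); exc_neg <- rep(0L, V)
  max_pos <- numeric(n_perm); max_neg <- numeric(n_perm)
  block <- 500L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    Mb <- (S %*% D) / n
    exc_pos <- exc_pos + colSums(sweep(Mb, 2, obs, ">="))
    exc_neg <- exc_neg + colSums(sweep(Mb, 2, obs, "<="))
    mx <- apply(Mb, 1, max); mn <- apply(Mb, 1, min)
    max_pos[done + seq_len(nb)] <- mx
    max_neg[done + seq_len(nb)] <- mn
    done <- done + nb
  }
  p_pos <- (1 + exc_pos) / (n_perm + 1)
  p_neg <- (1 + exc_neg) / (n_perm + 1)
  pfwe_pos <- (1 + vapply(obs, function(o) sum(max_pos >= o), numeric(1))) /
    (n_perm + 1)
  pfwe_neg <- (1 + vapply(obs, function(o) sum(max_neg <= o), numeric(1))) /
    (n_perm + 1)
  z_pos <- p_to_z(p_pos)
  z_neg <- p_to_z(p_neg)
  abs_mask_ide <- abs(ide_group$z) > abs(sv_group$z)
  abs_mask_sv <- abs(sv_group$z) > abs(ide_group$z)
  one_side <- function(z_perm, pfwe, main_z, abs_mask, label) {
    zc <- pmin(z_perm, main_z)
    sig <- mask & abs_mask & pfwe <= alpha & main_z > 0
    labels <- label_components(array(sig, dim3))
    ids <- if (any(sig)) seq_len(max(labels)) else integer(0)
    rows <- lapply(ids, function(k) {
      vox <- which(labels == k)
      pk <- vox[which.max(zc[vox])]
      mmc <- voxel_to_mm(arrayInd(pk, dim3), dim3, pixdim)
      data.frame(index = k, n_voxels = length(vox), peak_z = max(zc[vox]),
                 x_mm = mmc[1], y_mm = mmc[2], z_mm = mmc[3],
                 p_corrected = min(pfwe[vox]), sign = label)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(index = integer(0), n_voxels = integer(0),
                 peak_z = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
                 z_mm = numeric(0), p_corrected = numeric(0),
                 sign = character(0))
    tab <- tab[order(-tab$n_voxels), , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("cluster_table", class(tab))
    attr(tab, "labels") <- labels
    tab
  }
  structure(list(
    ide_gt_sv = one_side(z_pos, pfwe_pos, ide_group$z, abs_mask_ide,
                         "ide_gt_sv"),
    sv_gt_ide = one_side(z_neg, pfwe_neg, sv_group$z, abs_mask_sv,
                         "sv_gt_ide"),
    z_ide_gt_sv = z_pos, z_sv_gt_ide = z_neg,
    max_z = p_to_z(1 / (n_perm + 1)), n_perm = n_perm),
    class = "sv_ide_contrast")
}
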