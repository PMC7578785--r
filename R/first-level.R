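#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak ~5 s, undershoot
#' ~15 s, undershoot ratio 1/6), normalised to unit peak. Shape parameters
#' are the conventional defaults: delays 6 s and 16 s, dispersions 1.
#'
#' @param t time grid in seconds (non-negative).
#' @param peak_delay,undershoot_delay gamma means (seconds).
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio undershoot amplitude relative to the peak lobe.
#' @return kernel values at `t`, max exactly 1 on a sufficiently fine grid.
#' @export
#' @examples
#' h <- hrf_double_gamma(seq(0, 32, by = 0.1))
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  ref <- seq(0, 32, by = 0.01)
  hm <- max(stats::dgamma(ref, shape = peak_delay / peak_disp,
                          scale = peak_disp) -
            ratio * stats::dgamma(ref, shape = undershoot_delay / undershoot_disp,
                                  scale = undershoot_disp))
  h / hm
}

#' Build the first-level design matrix
#'
#' Task regressors are 4 s (or per-event duration) boxcars convolved with
#' the double-gamma HRF at 0.1 s microtime and sampled at the TR: a trial
#' (unmodulated) regressor plus SV and iDE parametric modulators whose
#' amplitudes are mean-centred across the run's trials before convolution.
#' Temporal derivatives (central differences of each convolved task column),
#' the seven motion confounds (unconvolved), and a constant complete the
#' matrix. No orthogonalisation is applied between regressors.
#'
#' @param trials one run's trial table with `onset`, `duration`, `sv`, `ide`.
#' @param motion data frame of 7 motion confounds (or `NULL` to omit).
#' @param TR repetition time (seconds).
#' @param n_volumes number of volumes in the run.
#' @return matrix of class `"design_matrix"` (rows = volumes) with named
#'   columns `trials`, `sv`, `ide`, `trials_deriv`, `sv_deriv`, `ide_deriv`,
#'   motion columns, `constant`; attribute `centring` records the removed
#'   modulator means and `task_cols` the HRF-convolved columns.
#' @export
build_design <- function(trials, motion = NULL, TR, n_volumes) {
  if (is.null(trials) || nrow(trials) == 0) stop("empty event list")
  if (max(trials$onset) >= n_volumes * TR)
    stop("events fall outside the run duration")
  C <- convolved_task_regressors(trials, TR, n_volumes)
  cd <- function(x) {
    n <- length(x)
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  }
  D <- cbind(C,
             trials_deriv = cd(C[, "trials"]),
             sv_deriv = cd(C[, "sv"]),
             ide_deriv = cd(C[, "ide"]))
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    if (nrow(m) != n_volumes) stop("motion table length must equal n_volumes")
    colnames(m) <- colnames(motion)
    D <- cbind(D, m)
  }
  D <- cbind(D, constant = 1)
  if (anyDuplicated(colnames(D))) stop("duplicate design column names")
  attr(D, "centring") <- c(sv = mean(trials$sv), ide = mean(trials$ide))
  attr(D, "task_cols") <- c("trials", "sv", "ide")
  attr(D, "TR") <- TR
  class(D) <- c("design_matrix", class(D))
  D
}

#' High-pass filter by drift-basis projection
#'
#' Removes slow drift by projecting out a basis of discrete cosines with
#' periods longer than `cutoff` seconds, augmented with an exact linear
#' term so pure trends are removed completely. Apply the same filter to the
#' data and to the design (constant column excluded) so the model stays
#' consistent; the projection is idempotent.
#'
#' @param x numeric vector, T x V matrix, or design matrix.
#' @param TR sampling interval (seconds).
#' @param cutoff high-pass cutoff in seconds (default 100); must exceed
#'   `2 * TR`.
#' @param protect column names never filtered (default `"constant"`).
#' @return filtered object of the same shape.
#' @export
highpass <- function(x, TR, cutoff = 100, protect = "constant") {
  stopifnot(cutoff > 2 * TR)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  B <- drift_basis(n, TR, cutoff)
  Q <- qr.Q(qr(B))
  keep_cols <- seq_len(ncol(X))
  prot <- if (!is.null(colnames(X))) which(colnames(X) %in% protect) else integer(0)
  filt <- setdiff(keep_cols, prot)
  Xf <- X
  Xf[, filt] <- X[, filt, drop = FALSE] -
    Q %*% crossprod(Q, X[, filt, drop = FALSE])
  if (vec) as.vector(Xf) else {
    attributes(Xf) <- attributes(x)
    Xf[] <- Xf
    Xf
  }
}

drift_basis <- function(n, TR, cutoff) {
  K <- floor(2 * n * TR / cutoff)
  t0 <- seq_len(n)
  B <- cbind(1, t0 - mean(t0))
  if (K >= 1) {
    ks <- seq_len(K)
    B <- cbind(B, sapply(ks, function(k) cos(pi * k * (2 * t0 - 1) / (2 * n))))
  }
  B
}

#' Fit the run-level GLM with AR(1) prewhitening
#'
#' Ordinary least squares per voxel, followed by estimation of the lag-1
#' residual autocorrelation and one Cochrane-Orcutt refit on the
#' AR(1)-whitened data and design (voxels are grouped by rho rounded to
#' 0.01 so the whitened normal equations are solved once per group).
#'
#' @param Y T x V data matrix (or a `bold_run`).
#' @param design a [build_design()] matrix.
#' @param whiten logical; `FALSE` skips prewhitening (plain OLS).
#' @return list of class `"run_glm"`: `beta` (p x V), `var` (p x V),
#'   `rho` (length V), `df`, `regressors`.
#' @export
fit_run_glm <- function(Y, design, whiten = TRUE) {
  if (inherits(Y, "bold_run")) Y <- Y$data
  X <- unclass(design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rho <- colSums(res[-1, , drop = FALSE] * res[-n, , drop = FALSE]) /
    pmax(colSums(res^2), .Machine$double.eps)
  rho[!is.finite(rho)] <- 0
  rho <- pmin(pmax(rho, -0.95), 0.95)
  if (!whiten) rho[] <- 0
  dfres <- n - p
  var_b <- matrix(0, p, V <- ncol(Y))
  if (all(rho == 0)) {
    XtXi <- chol2inv(qr.R(qrX))
    sigma2 <- colSums(res^2) / dfres
    var_b <- diag(XtXi) %o% sigma2
  } else {
    grp <- split(seq_len(V), round(rho, 2))
    dfres <- (n - 1) - p
    for (g in grp) {
      r <- round(rho[g[1]], 2)
      Xw <- X[-1, , drop = FALSE] - r * X[-n, , drop = FALSE]
      Yw <- Y[-1, g, drop = FALSE] - r * Y[-n, g, drop = FALSE]
      qw <- qr(Xw)
      bw <- qr.coef(qw, Yw)
      rw <- Yw - Xw %*% bw
      s2 <- colSums(rw^2) / dfres
      beta[, g] <- bw
      var_b[, g] <- diag(chol2inv(qr.R(qw))) %o% s2
    }
  }
  rownames(var_b) <- colnames(X)
  structure(list(beta = beta, var = var_b, rho = rho, df = dfres,
                 regressors = colnames(X)), class = "run_glm")
}

#' Pool runs with fixed effects
#'
#' Inverse-variance weighted combination per voxel and regressor:
#' pooled beta `= sum(b_i / v_i) / sum(1 / v_i)`, pooled variance
#' `= 1 / sum(1 / v_i)`, and `Z = beta / sqrt(variance)`.
#'
#' @param runs list of [fit_run_glm()] results on a common grid.
#' @param regressors which regressors to pool (default: all shared).
#' @return list of class `"subject_estimates"`: `beta`, `var`, `z`
#'   (each p x V), `regressors`, `n_runs`.
#' @export
pool_fixed_effects <- function(runs, regressors = NULL) {
  stopifnot(length(runs) >= 1)
  regs <- if (is.null(regressors)) runs[[1]]$regressors else regressors
  V <- ncol(runs[[1]]$beta)
  if (!all(vapply(runs, function(r) ncol(r$beta) == V, logical(1))))
    stop("runs must share a common voxel grid")
  p <- length(regs)
  num <- matrix(0, p, V); den <- matrix(0, p, V)
  for (r in runs) {
    b <- r$beta[regs, , drop = FALSE]
    v <- r$var[regs, , drop = FALSE]
    if (any(v <= 0)) stop("zero or negative run variance at some voxel (degenerate)")
    num <- num + b / v
    den <- den + 1 / v
  }
  beta <- num / den
  varp <- 1 / den
  z <- beta / sqrt(varp)
  rownames(beta) <- rownames(varp) <- rownames(z) <- regs
  structure(list(beta = beta, var = varp, z = z, regressors = regs,
                 n_runs = length(runs)), class = "subject_estimates")
}

#' First-level analysis of one subject
#'
#' Smooths each run, builds the design, high-pass filters data and design,
#' fits the prewhitened GLM, and pools runs with fixed effects.
#'
#' @param runs list of `bold_run` objects (or T x V matrices).
#' @param trial_list list (per run) of trial tables with `onset`,
#'   `duration`, `sv`, `ide`.
#' @param motion_list list of motion confound tables (or `NULL`).
#' @param TR repetition time.
#' @param fwhm smoothing FWHM in mm (0 to skip).
#' @param hp_cutoff high-pass cutoff in seconds (`Inf` or `NULL` to skip).
#' @param whiten AR(1) prewhitening flag.
#' @param dim3,pixdim spatial geometry when runs are plain matrices.
#' @return a `subject_estimates` object (see [pool_fixed_effects()]).
#' @export
first_level_subject <- function(runs, trial_list, motion_list = NULL,
                                TR = 1, fwhm = 5, hp_cutoff = 100,
                                whiten = TRUE, dim3 = NULL, pixdim = NULL) {
  fits <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    Y <- if (inherits(r, "bold_run")) r$data else r
    d3 <- if (inherits(r, "bold_run")) r$dim3 else dim3
    pd <- if (inherits(r, "bold_run")) r$pixdim else pixdim
    nv <- nrow(Y)
    if (fwhm > 0) Y <- smooth_volumes(Y, fwhm, dim3 = d3, pixdim = pd)
    motion <- if (!is.null(motion_list)) motion_list[[i]]
      else if (inherits(r, "bold_run")) r$motion else NULL
    X <- build_design(trial_list[[i]], motion, TR, nv)
    if (!is.null(hp_cutoff) && is.finite(hp_cutoff)) {
      Y <- highpass(Y, TR, hp_cutoff)
      X <- highpass(X, TR, hp_cutoff)
    }
    fits[[i]] <- fit_run_glm(Y, X, whiten = whiten)
  }
  pool_fixed_effects(fits)
}
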