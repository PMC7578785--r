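#' Noise model for synthetic BOLD
#'
#' @param sigma marginal SD of the AR(1) noise in signal units. `NULL`
#'   (default) matches the SD of the noiseless task signal across in-mask
#'   voxels and time — the reference SNR condition used throughout the
#'   package's recovery checks. `0` disables noise.
#' @param ar1_rho lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param drift_amplitude SD of slow (cosine) scanner drift per voxel.
#' @param motion_coupling coupling of motion parameters into the signal
#'   (signal units per mm; 0 = off, the default).
#' @return list of class `"noise_model"`.
#' @export
noise_model <- function(sigma = NULL, ar1_rho = 0.3, drift_amplitude = 1,
                        motion_coupling = 0) {
  stopifnot(is.null(sigma) || sigma >= 0, ar1_rho >= 0, ar1_rho < 1,
            drift_amplitude >= 0)
  structure(list(sigma = sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 motion_coupling = motion_coupling), class = "noise_model")
}

#' Ground-truth encoding maps with spatial gradients
#'
#' Builds the voxelwise weight maps that the BOLD generator uses: an
#' intercept (task-response) map and SV / iDE weight maps. Three modes:
#' `aligned` produces two smooth fields sharing a dorsal-to-ventral style
#' gradient along `axis`, jointly positive at one end and jointly negative
#' at the other; `independent` draws two unrelated smooth fields;
#' `opposed` sign-flips the aligned pairing.
#'
#' @param dim3 grid dimensions (default `c(20, 20, 20)`).
#' @param pixdim voxel size in mm.
#' @param axis gradient axis (1-3).
#' @param amplitude weight scale (signal units per unit of the centred
#'   modulator).
#' @param smoothness Gaussian sigma (voxels) of the random fields.
#' @param mode `"aligned"`, `"independent"` or `"opposed"`.
#' @param neg_fraction fraction of the gradient axis on the negative side
#'   (aligned/opposed modes); lets per-participant loss aversion shift the
#'   balance of negative vs positive SV voxels.
#' @param noise_sd relative SD of the smooth perturbation added to the
#'   gradient (aligned/opposed modes).
#' @param intercept_amplitude task-response amplitude (constant map).
#' @param seed integer seed.
#' @return list of class `"ground_truth_maps"` with `intercept`, `sv_weight`,
#'   `ide_weight` volumes, `mask`, and `roi_masks` (`jointly_positive`,
#'   `jointly_negative`).
#' @export
make_gradient_maps <- function(dim3 = c(20, 20, 20), pixdim = 3, axis = 3,
                               amplitude = 1, smoothness = 2,
                               mode = c("aligned", "independent", "opposed"),
                               neg_fraction = 0.5, noise_sd = 0.08,
                               intercept_amplitude = 1, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(dim3) == 3, axis %in% 1:3,
            neg_fraction > 0, neg_fraction < 1)
  set.seed(seed)
  smooth_field <- function() {
    f <- volume(stats::rnorm(prod(dim3)), dim3, pixdim)
    f <- smooth_volumes(f, fwhm = smoothness * 2.3548 * mean(rep(pixdim, 3)),
                        pixdim = pixdim)
    (f - mean(f)) / stats::sd(f)
  }
  if (mode == "independent") {
    sv_w <- amplitude * smooth_field()
    ide_w <- amplitude * smooth_field()
  } else {
    t_ax <- (seq_len(dim3[axis]) - 0.5) / dim3[axis]
    ramp <- 2 * (t_ax - neg_fraction)
    grad <- volume(0, dim3, pixdim)
    idx <- slice.index(grad, axis)
    grad[] <- ramp[idx]
    sv_w <- amplitude * (grad + noise_sd * smooth_field())
    ide_w <- amplitude * (grad + noise_sd * smooth_field())
    if (mode == "opposed") ide_w <- -ide_w
  }
  attr(sv_w, "pixdim") <- attr(ide_w, "pixdim") <- rep(pixdim, length.out = 3)
  intercept <- volume(intercept_amplitude, dim3, pixdim)
  mask <- volume(TRUE, dim3, pixdim)
  structure(list(
    intercept = intercept, sv_weight = sv_w, ide_weight = ide_w,
    mask = mask,
    roi_masks = list(jointly_positive = (sv_w > 0) & (ide_w > 0),
                     jointly_negative = (sv_w < 0) & (ide_w < 0)),
    mode = mode, axis = axis, neg_fraction = neg_fraction,
    amplitude = amplitude, seed = seed), class = "ground_truth_maps")
}

#' Simulate scanner motion parameters
#'
#' Smooth random walks for three rotations (radians) and three translations
#' (mm), plus framewise displacement (FD) computed with the usual 50 mm
#' head-radius convention. These are the seven motion nuisance regressors.
#'
#' @param n_volumes number of time points.
#' @param step SD of the random-walk increments (mm or rad).
#' @param seed integer seed.
#' @return data frame with columns `fd`, `rot_x/y/z`, `trans_x/y/z`.
#' @export
simulate_motion <- function(n_volumes, step = 0.02, seed = 1) {
  set.seed(seed)
  rw <- function() {
    x <- cumsum(stats::rnorm(n_volumes, 0, step))
    stats::filter(x, rep(1 / 5, 5), sides = 2) -> sm
    as.numeric(ifelse(is.na(sm), x, sm))
  }
  m <- data.frame(rot_x = rw() / 50, rot_y = rw() / 50, rot_z = rw() / 50,
                  trans_x = rw(), trans_y = rw(), trans_z = rw())
  d <- rbind(0, abs(apply(m, 2, diff)))
  fd <- 50 * (d[, 1] + d[, 2] + d[, 3]) + d[, 4] + d[, 5] + d[, 6]
  cbind(fd = fd, m)
}

#' Generate a synthetic BOLD run
#'
#' Inverts the first-level model: each voxel's time series is
#' `intercept * conv(box) + w_sv * conv(box * sv_centred) +
#'  w_ide * conv(box * ide_centred)` plus slow drift, optional
#' motion-coupled signal, and stationary AR(1) noise. The convolution uses
#' the same double-gamma HRF and microtime sampling as the first-level
#' design builder, so with zero noise the GLM recovers the weight maps
#' exactly.
#'
#' @param trials one run's trial table with `onset`, `duration`, `sv`,
#'   `ide` columns (the modulators are mean-centred internally, matching
#'   the analysis design).
#' @param maps a [make_gradient_maps()] object.
#' @param noise a [noise_model()].
#' @param TR repetition time (seconds).
#' @param n_volumes run length in volumes.
#' @param seed integer seed.
#' @return list of class `"bold_run"`: `data` (T x V matrix), `dim3`,
#'   `pixdim`, `TR`, `motion` (confound table), `sigma` (the noise SD
#'   actually used).
#' @export
generate_bold <- function(trials, maps, noise = noise_model(), TR = 1,
                          n_volumes, seed = 1) {
  stopifnot(inherits(maps, "ground_truth_maps"), TR > 0)
  dim3 <- dim(maps$sv_weight)
  if (!all(dim(maps$intercept) == dim3) || !all(dim(maps$ide_weight) == dim3))
    stop("ground-truth maps must share one grid")
  V <- prod(dim3)
  set.seed(seed)
  C <- convolved_task_regressors(trials, TR, n_volumes)  # T x 3
  W <- cbind(as.vector(maps$intercept), as.vector(maps$sv_weight),
             as.vector(maps$ide_weight))                 # V x 3
  signal <- C %*% t(W)
  sigma <- noise$sigma
  if (is.null(sigma)) {
    sc <- sweep(signal, 2, colMeans(signal))
    sigma <- stats::sd(as.vector(sc))
  }
  motion <- simulate_motion(n_volumes, seed = seed + 11L)
  Y <- signal
  if (noise$drift_amplitude > 0) {
    tt <- seq_len(n_volumes)
    B <- cbind(cos(pi * tt / n_volumes), cos(2 * pi * tt / n_volumes))
    A <- matrix(stats::rnorm(2 * V, 0, noise$drift_amplitude), 2, V)
    Y <- Y + B %*% A
  }
  if (noise$motion_coupling != 0) {
    Mp <- as.matrix(motion[, c("trans_x", "trans_y", "trans_z")])
    L <- matrix(stats::rnorm(3 * V, 0, noise$motion_coupling), 3, V)
    Y <- Y + Mp %*% L
  }
  if (sigma > 0) {
    innov_sd <- sigma * sqrt(1 - noise$ar1_rho^2)
    E <- matrix(stats::rnorm(n_volumes * V, 0, innov_sd), n_volumes, V)
    if (noise$ar1_rho > 0)
      E <- apply(E, 2, function(e)
        as.numeric(stats::filter(e, noise$ar1_rho, method = "recursive")))
    Y <- Y + E
  }
  structure(list(data = Y, dim3 = dim3, pixdim = voxdim(maps$sv_weight),
                 TR = TR, motion = motion, sigma = sigma,
                 n_volumes = n_volumes), class = "bold_run")
}

# HRF-convolved trial / SV / iDE regressors sampled at TR (shared between
# the generator and the first-level design builder so the round trip is
# exact)
convolved_task_regressors <- function(trials, TR, n_volumes, dt = 0.1) {
  if (nrow(trials) == 0) stop("empty event list")
  sv_c <- trials$sv - mean(trials$sv)
  ide_c <- trials$ide - mean(trials$ide)
  n_fine <- ceiling(n_volumes * TR / dt) + 1L
  box <- numeric(n_fine); svr <- numeric(n_fine); ider <- numeric(n_fine)
  for (i in seq_len(nrow(trials))) {
    a <- floor(trials$onset[i] / dt) + 1L
    b <- min(n_fine, ceiling((trials$onset[i] + trials$duration[i]) / dt))
    if (a > n_fine) next
    box[a:b] <- box[a:b] + 1
    svr[a:b] <- svr[a:b] + sv_c[i]
    ider[a:b] <- ider[a:b] + ide_c[i]
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- function(x) {
    y <- stats::convolve(x, rev(h), type = "open")[seq_along(x)] * dt
    y
  }
  fine <- cbind(trials = conv(box), sv = conv(svr), ide = conv(ider))
  samp <- round(((seq_len(n_volumes) - 1) * TR) / dt) + 1L
  fine[samp, , drop = FALSE]
}
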