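# Volumetric helpers shared across modules. Volumes are plain 3D (or 4D)
# arrays carrying a "pixdim" attribute (voxel size in mm); time series data
# travel as T x V matrices with the spatial dim kept alongside.

#' Create a volume array
#'
#' @param data numeric vector or array.
#' @param dim 3-element spatial dimensions.
#' @param pixdim voxel size in mm (length 1 or 3).
#' @return array with a `pixdim` attribute.
#' @export
volume <- function(data = 0, dim, pixdim = 3) {
  v <- array(data, dim = dim)
  attr(v, "pixdim") <- rep(pixdim, length.out = 3)
  v
}

#' @rdname volume
#' @param x a volume.
#' @export
voxdim <- function(x) {
  p <- attr(x, "pixdim")
  if (is.null(p)) rep(3, 3) else rep(p, length.out = 3)
}

#' Write / read a volume as NIfTI
#'
#' Thin wrappers over RNifti preserving the voxel size.
#'
#' @param x 3D or 4D array with `pixdim` attribute.
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(unclass(x))
  RNifti::pixdim(img) <- c(voxdim(x), rep(1, length(dim(x)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  v <- array(as.vector(img), dim = dim(img))
  attr(v, "pixdim") <- RNifti::pixdim(img)[1:3]
  v
}

# world coordinates of voxel indices (mm), origin at the grid centre —
# an MNI-style symmetric affine for reporting peak locations
voxel_to_mm <- function(ijk, dim3, pixdim) {
  centre <- (dim3 + 1) / 2
  sweep(ijk, 2, centre) * rep(pixdim, each = nrow(ijk))
}

# map a t statistic with df degrees of freedom to a standard normal Z,
# stable in the far tails via log-scale probabilities
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  lp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z_abs <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  ifelse(is.na(t), NA_real_, ifelse(pos, z_abs, -z_abs))
}

# one-tailed permutation p to Z: Z = qnorm(1 - p); saturates at
# qnorm(1 - 1/(n_perm + 1))
p_to_z <- function(p) stats::qnorm(p, lower.tail = FALSE)

#' Gaussian spatial smoothing of volume data
#'
#' Smooths each volume with an isotropic Gaussian of the stated full width
#' at half maximum (`sigma = fwhm / 2.3548` mm, converted to voxels per
#' axis). The kernel rows are renormalised at the boundary so a constant
#' image is exactly preserved.
#'
#' @param x a 3D volume, 4D array (x,y,z,t), or T x V matrix (with `dim3`).
#' @param fwhm full width at half maximum in mm (default 5). `0` is a no-op.
#' @param dim3 spatial dimensions when `x` is a T x V matrix.
#' @param pixdim voxel size in mm.
#' @return smoothed data in the same shape as the input.
#' @export
smooth_volumes <- function(x, fwhm = 5, dim3 = NULL, pixdim = NULL) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(x)
  if (is.matrix(x)) {
    stopifnot(!is.null(dim3))
    if (is.null(pixdim)) pixdim <- rep(3, 3)
    arr <- array(t(x), dim = c(dim3, nrow(x)))
    sm <- smooth_array(arr, fwhm, rep(pixdim, length.out = 3))
    out <- t(matrix(sm, prod(dim3), nrow(x)))
    return(out)
  }
  pd <- if (is.null(pixdim)) voxdim(x) else rep(pixdim, length.out = 3)
  d <- dim(x)
  if (length(d) == 3) {
    out <- smooth_array(array(x, c(d, 1)), fwhm, pd)
    out <- array(out, d)
  } else {
    out <- smooth_array(x, fwhm, pd)
  }
  attr(out, "pixdim") <- pd
  out
}

smooth_array <- function(arr, fwhm, pixdim) {
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / pixdim[ax]
    K <- gauss_band(d[ax], sigma_vox)
    if (is.null(K)) next
    perm <- c(ax, setdiff(seq_along(d), ax))
    a <- aperm(arr, perm)
    dp <- dim(a)
    a <- K %*% matrix(a, d[ax], prod(dp[-1]))
    arr <- aperm(array(a, dp), order(perm))
  }
  arr
}

# row-normalised banded Gaussian convolution matrix (1D)
gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(NULL)
  half <- max(1L, ceiling(4 * sigma_vox))
  off <- -half:half
  k <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    t <- i + off[j]
    ok <- t >= 1 & t <= n
    K[cbind(i[ok], t[ok])] <- K[cbind(i[ok], t[ok])] + k[j]
  }
  K / rowSums(K)
}

# connected components of a logical 3D mask under 26-neighbour connectivity;
# returns an integer label volume (0 = background)
label_components <- function(mask3d) {
  d <- dim(mask3d)
  idx <- which(mask3d)
  labels <- array(0L, d)
  if (length(idx) == 0) return(labels)
  coord <- arrayInd(idx, d)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one direction per pair; undirected edges
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  ei <- integer(0); ej <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- coord + rep(offs[r, ], each = nrow(coord))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    tgt <- pos[nb[ok, , drop = FALSE]]
    src <- seq_along(idx)[ok]
    keep <- tgt > 0
    ei <- c(ei, src[keep]); ej <- c(ej, tgt[keep])
  }
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}
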