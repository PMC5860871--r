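#' Drift basis for temporal high-pass filtering
#'
#' Columns: intercept, linear trend, and sine/cosine pairs at
#' 1..`n_cycles` cycles per run.  Removing this basis implements linear
#' trend removal plus high-pass filtering of all frequencies up to
#' `n_cycles` cycles per scan.
#'
#' @param n_timepoints Run length in volumes.
#' @param n_cycles Highest drift frequency, in cycles per run.
#' @return Matrix with `n_timepoints` rows.
#' @export
drift_basis <- function(n_timepoints, n_cycles = 3) {
  t_idx <- seq_len(n_timepoints) - 1
  cols <- list(intercept = rep(1, n_timepoints),
               trend = t_idx - mean(t_idx))
  if (n_cycles >= 1) {
    for (k in seq_len(n_cycles)) {
      w <- 2 * pi * k * t_idx / n_timepoints
      cols[[paste0("sin", k)]] <- sin(w)
      cols[[paste0("cos", k)]] <- cos(w)
    }
  }
  do.call(cbind, cols)
}

#' Temporal high-pass filtering by drift regression
#'
#' Projects out, per voxel, the run mean, linear trend, and sine/cosine
#' pairs at 1..`n_cycles` cycles per run.  Regression (rather than FFT
#' masking) is deterministic and removes exactly the stated frequencies.
#'
#' @param run A [bold_run()].
#' @param n_cycles Highest removed frequency in cycles per run
#'   (default 3).
#' @return Filtered `bold_run`.
#' @export
highpass_detrend <- function(run, n_cycles = 3) {
  stopifnot(inherits(run, "bold_run"))
  if (n_cycles < 0) stop("'n_cycles' must be >= 0")
  nt <- n_vols(run)
  if (nt <= 2 * n_cycles + 2)
    stop("run too short: need > ", 2 * n_cycles + 2, " time points, have ", nt)
  B <- drift_basis(nt, n_cycles)
  Y <- run_matrix(run)
  coefs <- solve(crossprod(B), crossprod(B, Y))
  matrix_to_run(Y - B %*% coefs, run)
}

#' Voxelwise z-score normalization
#'
#' Each voxel's time course is centered and scaled to unit standard
#' deviation.  Constant voxels (zero temporal SD) are set to all-zero and
#' reported in a QC table attached as attribute `"qc"`.
#'
#' @param run A [bold_run()].
#' @return Normalized `bold_run`, with attribute `qc`: a data frame of
#'   flagged voxel indices (empty if none).
#' @export
zscore_voxelwise <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  Y <- run_matrix(run)
  mu <- colMeans(Y)
  sdv <- sqrt(colMeans(Y^2) - mu^2) * sqrt(nrow(Y) / (nrow(Y) - 1))
  const <- sdv <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  sdv[const] <- 1
  Y <- sweep(Y, 2, mu, "-")
  Y <- sweep(Y, 2, sdv, "/")
  if (any(const)) Y[, const] <- 0
  out <- matrix_to_run(Y, run)
  qc <- data.frame(voxel = which(const),
                   reason = rep("constant time course", sum(const)))
  attr(out, "qc") <- qc
  out
}

# 1D Gaussian convolution matrix with edge renormalization: each output
# point is a convex combination of inputs, so constants are preserved
# exactly on the borders.
gaussian_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma_vox))
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (i in idx) {
    j <- max(1L, i - radius):min(n, i + radius)
    w <- exp(-((j - i)^2) / (2 * sigma_vox^2))
    K[i, j] <- w / sum(w)
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Applies a separable 3D Gaussian kernel of the given full width at
#' half maximum to each volume, with `sigma_mm = fwhm_mm / (2 sqrt(2 ln 2))`.
#' Kernel rows are renormalized at the volume borders so constants are
#' preserved.  `fwhm_mm = 0` is the identity.
#'
#' @param x A [bold_run()], or a 3D array (single volume).
#' @param fwhm_mm Full width at half maximum of the kernel, mm (>= 0).
#' @param voxel_size_mm Voxel sizes, mm; taken from the run when `x` is
#'   a `bold_run`.
#' @return Same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (inherits(x, "bold_run")) {
    out <- x
    out$data <- smooth_array(x$data, fwhm_mm, x$voxel_size_mm)
    return(out)
  }
  if (is.null(voxel_size_mm))
    stop("'voxel_size_mm' is required when 'x' is a plain array")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  smooth_array(x, fwhm_mm, voxel_size_mm)
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, in the units of `fwhm`.
#'
#' @param fwhm Full width at half maximum.
#' @return The corresponding Gaussian SD.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# smooth a 3D or 4D array along its first three axes
smooth_array <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(arr)
  d <- dim(arr)
  is4d <- length(d) == 4L
  d3 <- d[1:3]
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  K1 <- gaussian_conv_matrix(d3[1], sig[1])
  K2 <- gaussian_conv_matrix(d3[2], sig[2])
  K3 <- gaussian_conv_matrix(d3[3], sig[3])
  rest <- if (is4d) d[4] else 1L
  # axis 1
  m <- matrix(arr, nrow = d3[1])
  m <- K1 %*% m
  a <- array(m, dim = c(d3, rest))
  # axis 2
  a <- aperm(a, c(2, 1, 3, 4))
  m <- K2 %*% matrix(a, nrow = d3[2])
  a <- aperm(array(m, dim = c(d3[2], d3[1], d3[3], rest)), c(2, 1, 3, 4))
  # axis 3
  a <- aperm(a, c(3, 1, 2, 4))
  m <- K3 %*% matrix(a, nrow = d3[3])
  a <- aperm(array(m, dim = c(d3[3], d3[1], d3[2], rest)), c(2, 3, 1, 4))
  if (is4d) array(a, dim = d) else array(a, dim = d3)
}

#' Standard preprocessing chain
#'
#' Runs [highpass_detrend()], [zscore_voxelwise()] and
#' [smooth_gaussian()] in that order; each step can be switched off.
#'
#' @param run A [bold_run()].
#' @param n_cycles High-pass cutoff in cycles per run; `NULL` skips.
#' @param zscore Apply voxelwise z-scoring?
#' @param fwhm_mm Smoothing FWHM in mm; 0 skips.
#' @return Preprocessed `bold_run`.
#' @export
preprocess_run <- function(run, n_cycles = 3, zscore = TRUE, fwhm_mm = 4) {
  if (!is.null(n_cycles)) run <- highpass_detrend(run, n_cycles)
  if (zscore) run <- zscore_voxelwise(run)
  if (fwhm_mm > 0) run <- smooth_gaussian(run, fwhm_mm)
  run
}
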