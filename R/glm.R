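#' Two-gamma HRF parameter set
#'
#' The canonical hemodynamic response function: a gamma-density peak
#' minus a scaled gamma-density undershoot,
#' `h(t) = g(t; peak_shape, peak_rate) - undershoot_ratio * g(t; undershoot_shape, undershoot_rate)`,
#' normalized so its maximum is 1 (so GLM betas carry signal units).
#' Defaults are the conventional values: peak shape 6, undershoot shape
#' 16, unit rates, ratio 1/6, 32 s support, giving a peak near 5 s.
#'
#' @param peak_shape,peak_rate Gamma parameters of the positive lobe.
#' @param undershoot_shape,undershoot_rate Gamma parameters of the
#'   undershoot lobe.
#' @param undershoot_ratio Undershoot amplitude relative to the peak
#'   lobe (>= 0).
#' @param length_s Kernel support in seconds.
#' @param dt_s Sampling step for [two_gamma_hrf()].
#' @return List of class `hrf_params`.
#' @export
hrf_params <- function(peak_shape = 6, peak_rate = 1,
                       undershoot_shape = 16, undershoot_rate = 1,
                       undershoot_ratio = 1 / 6,
                       length_s = 32, dt_s = 0.1) {
  if (peak_shape <= 0 || peak_rate <= 0 || undershoot_shape <= 0 ||
      undershoot_rate <= 0)
    stop("gamma shapes and rates must be positive")
  if (undershoot_ratio < 0) stop("'undershoot_ratio' must be >= 0")
  if (length_s <= 0 || dt_s <= 0) stop("'length_s' and 'dt_s' must be positive")
  structure(list(peak_shape = peak_shape, peak_rate = peak_rate,
                 undershoot_shape = undershoot_shape,
                 undershoot_rate = undershoot_rate,
                 undershoot_ratio = undershoot_ratio,
                 length_s = length_s, dt_s = dt_s),
            class = "hrf_params")
}

# unnormalized difference of gamma densities
hrf_raw <- function(t, p) {
  stats::dgamma(t, shape = p$peak_shape, rate = p$peak_rate) -
    p$undershoot_ratio *
      stats::dgamma(t, shape = p$undershoot_shape, rate = p$undershoot_rate)
}

# memoization for quantities that are pure functions of their arguments
# and recur for every simulated run (HRF peak, block regressors)
.hrf_cache <- new.env(parent = emptyenv())

hrf_key <- function(p) paste(unlist(p[c("peak_shape", "peak_rate",
                                        "undershoot_shape", "undershoot_rate",
                                        "undershoot_ratio", "length_s")]),
                             collapse = ",")

# peak value used for max-normalization, located by bounded 1-D search
hrf_peak_value <- function(p) {
  key <- paste0("peak:", hrf_key(p))
  hit <- .hrf_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- seq(0, p$length_s, length.out = 512)
  i <- which.max(hrf_raw(grid, p))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(t) hrf_raw(t, p), c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  .hrf_cache[[key]] <- opt$objective
  opt$objective
}

#' Evaluate the max-normalized HRF at arbitrary times
#'
#' Zero outside `[0, length_s]`.
#'
#' @param t Times in seconds.
#' @param params An [hrf_params()] set.
#' @return Numeric vector of HRF values, peak value 1.
#' @export
hrf_eval <- function(t, params = hrf_params()) {
  h <- hrf_raw(t, params) / hrf_peak_value(params)
  h[t < 0 | t > params$length_s] <- 0
  h
}

# running integral of the max-normalized HRF, frozen beyond length_s;
# closed form via the gamma CDF so boxcar regressors need no fine grid
hrf_integral <- function(t, params) {
  tt <- pmin(pmax(t, 0), params$length_s)
  (stats::pgamma(tt, shape = params$peak_shape, rate = params$peak_rate) -
     params$undershoot_ratio *
       stats::pgamma(tt, shape = params$undershoot_shape,
                     rate = params$undershoot_rate)) /
    hrf_peak_value(params)
}

#' Sample the two-gamma HRF kernel
#'
#' @param params An [hrf_params()] set.
#' @return List with `t` (sample times on `[0, length_s]` at `dt_s`)
#'   and `values` (kernel, max-normalized to 1).
#' @examples
#' h <- two_gamma_hrf()
#' h$t[which.max(h$values)]   # ~5 s peak
#' @export
two_gamma_hrf <- function(params = hrf_params()) {
  t <- seq(0, params$length_s, by = params$dt_s)
  list(t = t, values = hrf_eval(t, params), dt_s = params$dt_s)
}

#' Build the per-TOA GLM design matrix
#'
#' For each TOA condition, the impulse train of that condition's trial
#' onsets (across all its blocks and runs) is convolved with the HRF and
#' sampled at volume acquisition times; blocks with the same TOA share a
#' column.  With a nonzero event duration the convolution uses the exact
#' integral of the HRF over the event window.  An intercept is always
#' included; drift/trend confound columns matching [drift_basis()] are
#' appended when `drift_cycles` is not `NULL`, so that GLM estimates on
#' high-pass-filtered data are unbiased (data and model then span the
#' same filtered space).
#'
#' @param schedules List of [make_event_schedule()] blocks in the run.
#' @param tr_s Repetition time, seconds.
#' @param n_vols Run length in volumes.
#' @param hrf An [hrf_params()] set.
#' @param drift_cycles `NULL` for no drift columns, else the high-pass
#'   cutoff in cycles per run (adds trend + sin/cos pairs).
#' @return Object of class `design_matrix`: list with `X`, `toa_cols`
#'   (names of condition columns), `toas`, `tr_s`, `n_timepoints`.
#' @export
build_design_matrix <- function(schedules, tr_s, n_vols, hrf = hrf_params(),
                                drift_cycles = NULL) {
  stopifnot(length(schedules) >= 1)
  run_end <- (n_vols - 1) * tr_s
  for (s in schedules) {
    bad <- s$onsets_s[s$onsets_s > run_end]
    if (length(bad))
      stop("onset ", bad[1], " s beyond run end (", run_end, " s)")
  }
  toas <- sort(unique(vapply(schedules, `[[`, numeric(1), "toa_s")))
  t_vol <- (seq_len(n_vols) - 1) * tr_s
  cols <- matrix(0, n_vols, length(toas))
  colnames(cols) <- paste0("toa_", toas)
  for (s in schedules) {
    j <- match(s$toa_s, toas)
    x <- numeric(n_vols)
    if (s$duration_s == 0) {
      for (o in s$onsets_s) x <- x + hrf_eval(t_vol - o, hrf)
    } else {
      for (o in s$onsets_s)
        x <- x + hrf_integral(t_vol - o, hrf) -
          hrf_integral(t_vol - o - s$duration_s, hrf)
    }
    cols[, j] <- cols[, j] + x
  }
  if (!is.null(drift_cycles)) {
    X <- cbind(cols, drift_basis(n_vols, drift_cycles))
  } else {
    X <- cbind(cols, intercept = rep(1, n_vols))
  }
  structure(list(X = X, toa_cols = colnames(cols), toas = toas,
                 tr_s = tr_s, n_timepoints = n_vols, hrf = hrf),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d volumes x %d columns (%d TOA conditions: %s)\n",
              x$n_timepoints, ncol(x$X), length(x$toa_cols),
              paste(x$toas, collapse = ", ")))
  invisible(x)
}

#' Per-voxel ordinary least squares GLM
#'
#' Fits every voxel's time course on the design, returning one beta per
#' TOA condition plus residual variance and the omnibus F statistic of
#' the TOA set against the confound-only model (the task-responsiveness
#' statistic).
#'
#' @param run A [bold_run()] (or time x voxel matrix).
#' @param design A [build_design_matrix()] object.
#' @return Object of class `beta_map`: list with `beta` (voxel x TOA
#'   matrix), `toas`, `sigma2`, `df`, `fstat`, `p_task`, the F-pooling
#'   components `ess`/`rss`/`df_num`, and the grid `dim`.
#' @export
fit_glm <- function(run, design) {
  stopifnot(inherits(design, "design_matrix"))
  if (inherits(run, "bold_run")) {
    Y <- run_matrix(run)
    dim3 <- grid_dim(run)
  } else {
    Y <- as.matrix(run)
    dim3 <- NULL
  }
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop("run has ", nrow(Y), " volumes but design has ", nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  rss <- colSums(res^2)
  df <- nrow(Y) - qx$rank
  # confound-only model for the omnibus task F
  conf <- setdiff(colnames(X), design$toa_cols)
  X0 <- X[, conf, drop = FALSE]
  res0 <- Y - X0 %*% qr.coef(qr(X0), Y)
  rss0 <- colSums(res0^2)
  k <- length(design$toa_cols)
  ess <- pmax(rss0 - rss, 0)
  fstat <- (ess / k) / (rss / df)
  structure(
    list(beta = t(coefs[design$toa_cols, , drop = FALSE]),
         toas = design$toas, sigma2 = rss / df, df = df,
         fstat = fstat,
         p_task = stats::pf(fstat, k, df, lower.tail = FALSE),
         ess = ess, rss = rss, df_num = k,
         dim = dim3),
    class = "beta_map"
  )
}

#' @export
print.beta_map <- function(x, ...) {
  cat(sprintf("Beta map: %d voxels x %d TOA conditions (df = %d)\n",
              nrow(x$beta), ncol(x$beta), x$df))
  invisible(x)
}

#' Average beta maps across runs
#'
#' Betas are averaged per TOA condition; the F-pooling components
#' (extra and residual sums of squares and their degrees of freedom)
#' are summed, which is the fixed-effects combination of the per-run
#' omnibus tests.
#'
#' @param maps List of [fit_glm()] results on the same grid and design.
#' @return A combined `beta_map`.
#' @export
combine_beta_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  out <- maps[[1]]
  if (length(maps) > 1) {
    out$beta <- Reduce(`+`, lapply(maps, `[[`, "beta")) / length(maps)
    out$ess <- Reduce(`+`, lapply(maps, `[[`, "ess"))
    out$rss <- Reduce(`+`, lapply(maps, `[[`, "rss"))
    out$df <- sum(vapply(maps, `[[`, numeric(1), "df"))
    out$df_num <- sum(vapply(maps, `[[`, numeric(1), "df_num"))
    out$sigma2 <- out$rss / out$df
    out$fstat <- (out$ess / out$df_num) / (out$rss / out$df)
    out$p_task <- stats::pf(out$fstat, out$df_num, out$df, lower.tail = FALSE)
  }
  out
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up procedure: reject all p-values at or below the largest
#' `p_(k)` with `p_(k) <= k q / m`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return Logical vector, `TRUE` where rejected.
#' @export
bh_fdr <- function(pvals, q) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  if (length(q) != 1L || q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Select task-responsive voxels by pooled F + FDR
#'
#' Pools the omnibus task F across subjects by fixed-effects combination
#' (summing extra and residual sums of squares and degrees of freedom
#' over subjects), converts to a per-voxel p-value, and keeps voxels
#' surviving Benjamini-Hochberg FDR at `q`.
#'
#' @param beta_maps A `beta_map` or list of per-subject `beta_map`s on a
#'   common grid.
#' @param q FDR level (default 0.001, the conventional strict level for
#'   task localisation).
#' @return Logical mask; a 3D array when the maps carry a grid `dim`.
#' @export
select_task_responsive <- function(beta_maps, q = 0.001) {
  if (inherits(beta_maps, "beta_map")) beta_maps <- list(beta_maps)
  ess <- Reduce(`+`, lapply(beta_maps, `[[`, "ess"))
  rss <- Reduce(`+`, lapply(beta_maps, `[[`, "rss"))
  k <- sum(vapply(beta_maps, `[[`, numeric(1), "df_num"))
  df <- sum(vapply(beta_maps, `[[`, numeric(1), "df"))
  fstat <- (ess / k) / (rss / df)
  p <- stats::pf(fstat, k, df, lower.tail = FALSE)
  keep <- bh_fdr(p, q)
  if (!any(keep))
    warning("no task-responsive voxels at FDR q = ", q,
            "; downstream voxelwise stages have nothing to analyse")
  d <- beta_maps[[1]]$dim
  if (!is.null(d)) keep <- array(keep, dim = d)
  keep
}
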