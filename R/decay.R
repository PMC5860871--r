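# ---- variable-projection least-squares engine -------------------------
#
# For fixed tau the model is linear in (a, b): regress the betas on
# [1, exp(-toa/tau)].  The problem is therefore 1-D in tau: scan a
# log-spaced tau grid, then polish every local minimum of the profiled
# SSE by golden-section search in log(tau).  All steps are vectorized
# across series (columns of B), which is what makes whole-brain maps
# cheap.

# profiled SSE and slope for series j at tau_j; B is n_toa x m,
# tau is length m (one tau per series)
profile_sse <- function(tau, B, toa, Bc, SSb) {
  E <- exp(-outer(toa, 1 / tau))          # n_toa x m
  Ec <- E - rep(colMeans(E), each = length(toa))
  zz <- colSums(Ec^2)
  cross <- colSums(Ec * Bc)
  sse <- SSb - ifelse(zz > 1e-300, cross^2 / zz, 0)
  pmax(sse, 0)
}

# vectorized golden-section minimization of the profiled SSE in log-tau,
# one independent bracket per element of (lo, hi); cols selects the
# series each bracket belongs to
golden_refine <- function(loglo, loghi, cols, B, toa, Bc, SSb, iters = 70L) {
  gr <- (sqrt(5) - 1) / 2
  a <- loglo; b <- loghi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- profile_sse(exp(x1), B[, cols, drop = FALSE], toa,
                    Bc[, cols, drop = FALSE], SSb[cols])
  f2 <- profile_sse(exp(x2), B[, cols, drop = FALSE], toa,
                    Bc[, cols, drop = FALSE], SSb[cols])
  for (i in seq_len(iters)) {
    move1 <- f1 < f2
    # shrink toward x1 where f1 < f2, toward x2 otherwise
    b <- ifelse(move1, x2, b)
    a <- ifelse(move1, a, x1)
    x1 <- b - gr * (b - a)
    x2 <- a + gr * (b - a)
    f1 <- profile_sse(exp(x1), B[, cols, drop = FALSE], toa,
                      Bc[, cols, drop = FALSE], SSb[cols])
    f2 <- profile_sse(exp(x2), B[, cols, drop = FALSE], toa,
                      Bc[, cols, drop = FALSE], SSb[cols])
  }
  mid <- exp((a + b) / 2)
  list(tau = mid,
       sse = profile_sse(mid, B[, cols, drop = FALSE], toa,
                         Bc[, cols, drop = FALSE], SSb[cols]))
}

# core fitter: B is n_toa x m (one series per column); returns one row
# per series with a, b, tau, sse, reason
decay_ls <- function(B, toa, tau_bounds = c(0.1, 60), n_grid = 50L,
                     refine = TRUE) {
  n <- length(toa)
  if (n < 3) stop("need >= 3 distinct TOA values, got ", n)
  if (anyDuplicated(toa)) stop("TOA values must be distinct")
  if (tau_bounds[1] <= 0 || tau_bounds[2] <= tau_bounds[1])
    stop("'tau_bounds' must be increasing and positive")
  B <- as.matrix(B)
  m <- ncol(B)
  Bc <- B - rep(colMeans(B), each = n)
  SSb <- colSums(Bc^2)
  scale2 <- pmax(colMeans(B^2), .Machine$double.xmin)
  degen <- SSb <= 1e-24 * scale2 * n   # all betas (numerically) equal

  logtau <- seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = n_grid)
  taus <- exp(logtau)
  sse_grid <- matrix(0, n_grid, m)
  for (g in seq_len(n_grid))
    sse_grid[g, ] <- profile_sse(rep(taus[g], m), B, toa, Bc, SSb)

  best_g <- max.col(-t(sse_grid), ties.method = "first")
  best_tau <- taus[best_g]
  best_sse <- sse_grid[cbind(best_g, seq_len(m))]

  if (refine && m > 0) {
    # polish every local minimum of the gridded profile, not only the
    # global one, so no basin the grid can see is lost
    is_locmin <-
      sse_grid <= rbind(sse_grid[1, , drop = FALSE],
                        sse_grid[-n_grid, , drop = FALSE]) &
      sse_grid <= rbind(sse_grid[-1, , drop = FALSE],
                        sse_grid[n_grid, , drop = FALSE])
    cand <- which(is_locmin, arr.ind = TRUE)
    g <- cand[, 1]; j <- cand[, 2]
    lo <- logtau[pmax(g - 1L, 1L)]
    hi <- logtau[pmin(g + 1L, n_grid)]
    ref <- golden_refine(lo, hi, j, B, toa, Bc, SSb)
    better <- ref$sse < best_sse[j]
    if (any(better)) {
      # a series can host several refined minima; keep each only if it
      # improves on what that series currently holds
      for (ii in which(better)) {
        s <- j[ii]
        if (ref$sse[ii] < best_sse[s]) {
          best_sse[s] <- ref$sse[ii]
          best_tau[s] <- ref$tau[ii]
        }
      }
    }
  }

  # linear coefficients at the selected tau
  E <- exp(-outer(toa, 1 / best_tau))
  Ec <- E - rep(colMeans(E), each = n)
  zz <- colSums(Ec^2)
  b <- ifelse(zz > 1e-300, colSums(Ec * Bc) / zz, 0)
  a <- colMeans(B) - b * colMeans(E)

  reason <- rep("ok", m)
  reason[b < 0] <- "negative_b"
  tol_edge <- 1e-3
  at_edge <- best_tau <= tau_bounds[1] * (1 + tol_edge) |
    best_tau >= tau_bounds[2] / (1 + tol_edge)
  # a tau whose exponential regressor is numerically flat across the
  # design's TOAs (centered sum of squares < 1e-4) leaves (a, b)
  # ill-determined: such fits live in the short-tau boundary basin and
  # are flagged with it
  flat <- zz < 1e-4
  reason[at_edge | flat] <- "boundary"
  reason[degen] <- "nonidentifiable"
  a[degen] <- colMeans(B)[degen]
  b[degen] <- 0
  best_tau[degen] <- NA_real_
  best_sse[degen] <- 0

  data.frame(a = a, b = b, tau = best_tau, sse = best_sse,
             valid = reason == "ok", reason = reason)
}

#' Fit the exponential decay model to per-TOA betas
#'
#' Least-squares fit of `beta(TOA) = a + b * exp(-TOA / tau)` to one set
#' of per-condition GLM amplitudes.  Solved by variable projection: for
#' each `tau` on a log-spaced grid the linear pair `(a, b)` has a closed
#' form, and every local minimum of the profiled residual is polished by
#' golden-section search, so the global least-squares solution is found
#' deterministically without starting values.
#'
#' `b` is unconstrained in sign; fits with `b < 0` (no adaptation) or
#' with `tau` pinned at a bound are flagged via `reason` but their
#' parameters are kept.  Constant betas leave `tau` unidentified
#' (`reason = "nonidentifiable"`, `tau = NA`).
#'
#' @param betas Named numeric vector of betas (names = TOA in seconds),
#'   or unnamed with `toa` supplied.
#' @param toa TOA values in seconds matching `betas`.
#' @param tau_bounds Search interval for `tau`, seconds.
#' @param n_grid Number of log-spaced grid points for the `tau` scan.
#' @return Object of class `decay_fit` with components `coefficients`
#'   (`a`, `b`, `tau`), `sse`, `valid`, `reason`, `data`,
#'   `df.residual`, and the usual methods ([coef()], [predict()],
#'   [fitted()], [residuals()], [summary()], [plot()], [simulate()]).
#' @examples
#' toa <- c(3, 6, 9, 15)
#' beta <- 0.5 + 1.0 * exp(-toa / 4)
#' fit <- fit_decay(beta, toa)
#' coef(fit)           # a = 0.5, b = 1.0, tau = 4
#' predict(fit, data.frame(toa = 12))
#' @export
fit_decay <- function(betas, toa = as.numeric(names(betas)),
                      tau_bounds = c(0.1, 60), n_grid = 50L) {
  if (is.null(toa) || any(is.na(toa)))
    stop("TOA values must be given via names(betas) or 'toa'")
  if (length(betas) != length(toa))
    stop("'betas' and 'toa' lengths differ")
  res <- decay_ls(matrix(betas, ncol = 1), toa, tau_bounds, n_grid)
  cf <- c(a = res$a, b = res$b, tau = res$tau)
  names(cf) <- c("a", "b", "tau")
  fit <- structure(
    list(coefficients = cf, sse = res$sse, valid = res$valid,
         reason = res$reason,
         data = data.frame(toa = toa, beta = as.numeric(betas)),
         tau_bounds = tau_bounds, df.residual = length(toa) - 3L),
    class = "decay_fit"
  )
  fit
}

decay_predict <- function(cf, toa) {
  if (is.na(cf[["tau"]])) rep(cf[["a"]], length(toa))
  else cf[["a"]] + cf[["b"]] * exp(-toa / cf[["tau"]])
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
fitted.decay_fit <- function(object, ...) {
  decay_predict(coef(object), object$data$toa)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$beta - fitted(object)
}

#' @rdname fit_decay
#' @param object,x A `decay_fit`.
#' @param newdata Data frame with column `toa` (defaults to the fitted
#'   TOAs).
#' @param ... Unused.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  toa <- if (is.null(newdata)) object$data$toa else newdata$toa
  decay_predict(coef(object), toa)
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential adaptation decay fit: beta(TOA) = a + b * exp(-TOA/tau)\n")
  print(round(coef(x), digits))
  cat(sprintf("SSE %.3g on %d residual df%s\n", x$sse, x$df.residual,
              if (x$valid) "" else paste0("  [flag: ", x$reason, "]")))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  tss <- sum((object$data$beta - mean(object$data$beta))^2)
  out <- list(coefficients = coef(object), sse = object$sse,
              r.squared = if (tss > 0) 1 - object$sse / tss else NA_real_,
              sigma = sqrt(object$sse / max(object$df.residual, 1)),
              n = nrow(object$data), valid = object$valid,
              reason = object$reason)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential adaptation decay model\n")
  cat("  beta(TOA) = a + b * exp(-TOA/tau)\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nn = %d, SSE = %.4g, R^2 = %.3f, residual sigma = %.3g\n",
              x$n, x$sse, x$r.squared, x$sigma))
  if (!x$valid) cat("flag:", x$reason, "\n")
  invisible(x)
}

#' @export
plot.decay_fit <- function(x, ...) {
  toa_fine <- seq(0, max(x$data$toa) * 1.1, length.out = 200)
  graphics::plot(x$data$toa, x$data$beta, pch = 19,
                 xlab = "TOA (s)", ylab = expression(beta),
                 main = "BOLD adaptation decay", ...)
  graphics::lines(toa_fine, decay_predict(coef(x), toa_fine), col = "steelblue")
  invisible(x)
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sigma <- sqrt(object$sse / max(object$df.residual, 1))
  out <- as.data.frame(
    replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma))
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Fit the decay model to every voxel of a beta map
#'
#' Applies the variable-projection fit of [fit_decay()] to each masked
#' voxel; the grid scan and polish run vectorized across voxels.
#'
#' @param beta_map A [fit_glm()] result (or voxel x TOA matrix with
#'   TOAs as column order matching `toas`).
#' @param mask Logical array/vector selecting voxels; `NULL` fits all.
#' @param tau_bounds,n_grid,refine Passed to the fitter.
#' @param toas TOA values when `beta_map` is a plain matrix.
#' @return List of class `decay_map`: arrays/vectors `a`, `b`, `tau`,
#'   `sse`, `reason` (NA outside the mask), plus `dim` and `mask`.
#' @export
fit_decay_map <- function(beta_map, mask = NULL, tau_bounds = c(0.1, 60),
                          n_grid = 50L, refine = TRUE, toas = NULL) {
  if (inherits(beta_map, "beta_map")) {
    B <- beta_map$beta
    toas <- beta_map$toas
    d <- beta_map$dim
  } else {
    B <- as.matrix(beta_map)
    d <- NULL
    if (is.null(toas)) stop("'toas' required for a plain beta matrix")
  }
  nv <- nrow(B)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  midx <- which(as.logical(mask))
  if (!length(midx)) stop("empty mask: no voxels to fit")
  if (max(midx) > nv) stop("mask exceeds the beta map grid")
  res <- decay_ls(t(B[midx, , drop = FALSE]), toas, tau_bounds, n_grid,
                  refine = refine)
  blank <- function(mode = NA_real_) {
    v <- rep(mode, nv)
    if (!is.null(d)) array(v, dim = d) else v
  }
  out <- list(a = blank(), b = blank(), tau = blank(), sse = blank(),
              reason = blank(NA_character_), dim = d, mask = mask,
              toas = toas)
  out$a[midx] <- res$a; out$b[midx] <- res$b; out$tau[midx] <- res$tau
  out$sse[midx] <- res$sse; out$reason[midx] <- res$reason
  class(out) <- "decay_map"
  out
}

#' @export
print.decay_map <- function(x, ...) {
  fitted_vox <- sum(!is.na(x$reason))
  cat(sprintf("Decay parameter map: %d fitted voxels; tau median %.3g s; %d flagged\n",
              fitted_vox, stats::median(x$tau, na.rm = TRUE),
              sum(x$reason != "ok", na.rm = TRUE)))
  invisible(x)
}
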