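#' Mann-Whitney U test with z statistic
#'
#' Rank-sum comparison of two independent samples.  `U` is the
#' Mann-Whitney statistic of `x` (midranks under ties); `z` is the
#' normal approximation with tie-corrected variance and a continuity
#' correction.  For small samples (`n1 + n2 <= exact_max_n`) the
#' two-sided p-value is computed by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group labelings; otherwise from the normal
#' approximation.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max_n Largest combined sample size for which the exact
#'   permutation p-value is enumerated (default 12).
#' @param continuity Apply the 0.5 continuity correction to `z`?
#' @return List with `U`, `z`, `p` (two-sided), `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_z(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p
#' @export
mann_whitney_z <- function(x, y, exact_max_n = 12, continuity = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  d <- U - mu
  if (v <= 0) {
    z <- 0
  } else {
    dc <- if (continuity) sign(d) * max(abs(d) - 0.5, 0) else d
    z <- dc / sqrt(v)
  }
  if (n <= exact_max_n) {
    method <- "exact enumeration"
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(d) - 1e-12)
  } else {
    method <- "normal approximation"
    p <- if (v <= 0) 1 else min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, z = z, p = p, n1 = n1, n2 = n2, method = method)
}

#' Rank-test effect size
#'
#' `r = z / sqrt(n_total)`, the standard effect size for a Mann-Whitney
#' comparison.
#'
#' @param z Normal-approximation z value.
#' @param n_total Total number of observations across both groups
#'   (>= 2).
#' @return Effect size `r`.
#' @examples
#' effect_size_r(2.6, 39)   # 0.42 to two decimals
#' @export
effect_size_r <- function(z, n_total) {
  if (n_total < 2) stop("'n_total' must be >= 2")
  z / sqrt(n_total)
}

# stack per-subject tau volumes into a voxel x subject matrix
tau_stack <- function(maps) {
  if (is.matrix(maps)) return(maps)
  cols <- lapply(maps, function(m) {
    if (inherits(m, "decay_map")) as.numeric(m$tau) else as.numeric(m)
  })
  len <- vapply(cols, length, integer(1))
  if (length(unique(len)) != 1L) stop("tau maps are on different grids")
  do.call(cbind, cols)
}

#' Voxelwise Mann-Whitney comparison of tau maps
#'
#' Applies [mann_whitney_z()] to the per-subject `tau` values of each
#' masked voxel and attaches the effect size `r`.  Voxels where a
#' subject's fit left `tau` undefined use the remaining subjects; voxels
#' with fewer than two usable subjects in either group get `NA` results.
#'
#' @param tau_group1,tau_group2 Per-group subject `tau` maps: a list of
#'   [fit_decay_map()] results (or numeric arrays), or a voxel x subject
#'   matrix.
#' @param mask Logical array/vector of voxels to test; `NULL` tests all
#'   voxels with complete data.
#' @param dim Grid dimensions for the output arrays (taken from
#'   `decay_map` inputs when available).
#' @return Object of class `stat_map`: arrays `u`, `z`, `p`, `r`, plus
#'   `n1`, `n2`, `mask`, `dim`.
#' @export
voxelwise_group_map <- function(tau_group1, tau_group2, mask = NULL,
                                dim = NULL) {
  if (is.null(dim)) {
    probe <- if (is.list(tau_group1)) tau_group1[[1]] else NULL
    if (inherits(probe, "decay_map")) dim <- probe$dim
  }
  T1 <- tau_stack(tau_group1)
  T2 <- tau_stack(tau_group2)
  if (nrow(T1) != nrow(T2)) stop("group tau maps are on different grids")
  if (ncol(T1) < 2 || ncol(T2) < 2) stop("need >= 2 subjects per group")
  nv <- nrow(T1)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  midx <- which(as.logical(mask))
  if (max(midx) > nv) stop("mask exceeds the tau map grid")
  u <- z <- p <- r <- rep(NA_real_, nv)
  for (v in midx) {
    x <- T1[v, ]; y <- T2[v, ]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) next
    mw <- mann_whitney_z(x, y)
    u[v] <- mw$U; z[v] <- mw$z; p[v] <- mw$p
    r[v] <- effect_size_r(mw$z, length(x) + length(y))
  }
  shape <- function(v) if (!is.null(dim)) array(v, dim = dim) else v
  structure(list(u = shape(u), z = shape(z), p = shape(p), r = shape(r),
                 n1 = ncol(T1), n2 = ncol(T2), mask = shape(as.logical(mask)),
                 dim = dim),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("Voxelwise group stat map: %d tested voxels (n1 = %d, n2 = %d); max |z| = %.2f\n",
              sum(is.finite(x$z)), x$n1, x$n2,
              suppressWarnings(max(abs(x$z), na.rm = TRUE))))
  invisible(x)
}

# vectorized Mann-Whitney z across columns for tie-free data: per-column
# ranks are obtained from one global sort by offsetting each column into
# its own block
mw_z_matrix <- function(X, Y, continuity = TRUE) {
  n1 <- nrow(X); n2 <- nrow(Y); V <- ncol(X)
  M <- rbind(X, Y)
  n <- n1 + n2
  big <- 4 * (max(abs(M)) + 1)
  r <- rank(as.vector(M) + rep(seq_len(V) * big, each = n)) -
    rep((seq_len(V) - 1) * n, each = n)
  r <- matrix(r, n, V)
  U <- colSums(r[seq_len(n1), , drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sd_u <- sqrt(n1 * n2 * (n + 1) / 12)
  d <- U - mu
  if (continuity) d <- sign(d) * pmax(abs(d) - 0.5, 0)
  d / sd_u
}

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nn <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nn == 1,
                 "18" = nn >= 1 & nn <= 2,
                 "26" = nn >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected clusters of supra-threshold voxels
#'
#' Connected-component labeling of a binary 3D map under face (6),
#' face+edge (18), or face+edge+corner (26) adjacency.
#'
#' @param binary_map Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return List of class `cluster_labels`: `labels` (integer array, 0
#'   outside clusters), `extents` (voxel count per cluster), `members`
#'   (list of linear voxel indices per cluster), `connectivity`.
#' @export
label_clusters <- function(binary_map, connectivity = 26) {
  off <- connectivity_offsets(connectivity)
  d <- dim(binary_map)
  if (length(d) != 3L) stop("'binary_map' must be a 3D array")
  labels <- array(0L, dim = d)
  supra <- which(binary_map)
  members <- list()
  if (length(supra)) {
    coords <- arrayInd(supra, d)
    id_of <- array(0L, dim = d)   # row index into `coords` per voxel
    id_of[supra] <- seq_along(supra)
    visited <- logical(length(supra))
    cl <- 0L
    for (s in seq_along(supra)) {
      if (visited[s]) next
      cl <- cl + 1L
      queue <- s
      visited[s] <- TRUE
      comp <- integer(0)
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        comp <- c(comp, cur)
        nb <- sweep(off, 2, coords[cur, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        ids <- id_of[nb]
        ids <- ids[ids > 0L]
        new <- ids[!visited[ids]]
        if (length(new)) {
          visited[new] <- TRUE
          queue <- c(queue, new)
        }
      }
      members[[cl]] <- sort(supra[comp])
      labels[members[[cl]]] <- cl
    }
  }
  structure(list(labels = labels,
                 extents = vapply(members, length, integer(1)),
                 members = members, connectivity = connectivity),
            class = "cluster_labels")
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates `n_iter` null maps on the mask's grid, thresholds each
#' two-sidedly at `voxel_alpha`, and records the maximum
#' supra-threshold cluster extent.  The returned `k` is the smallest
#' extent whose null exceedance probability `P(max extent >= k)` is at
#' most `fwe_alpha`: requiring observed clusters to have at least `k`
#' voxels controls the family-wise error at `fwe_alpha`.
#'
#' Two null-map models are available:
#'
#' * `field = "gaussian"` — the classic construction: one white
#'   Gaussian field per iteration, smoothed to `smoothness_fwhm_mm` and
#'   standardized over the mask.
#' * `field = "rank"` — one smoothed Gaussian field **per subject**
#'   per iteration, converted to the same two-sample Mann-Whitney z map
#'   the pipeline thresholds (requires `n1`, `n2`).  Rank-statistic
#'   maps clump more at a fixed threshold than a Gaussian field with
#'   matched smoothness, so this model is the calibrated choice when
#'   correcting Mann-Whitney tau maps (see the methods vignette).
#'
#' @param mask Logical 3D array (>= 2 voxels).
#' @param smoothness_fwhm_mm Spatial smoothness of the null maps, mm
#'   FWHM (use the smoothing applied in preprocessing).
#' @param voxel_size_mm Voxel size, mm (scalar or length 3).
#' @param voxel_alpha Two-sided voxelwise (cluster-forming) threshold.
#' @param fwe_alpha Target family-wise error rate.
#' @param n_iter Number of simulated null maps (>= 100).
#' @param seed Optional RNG seed.
#' @param connectivity Cluster adjacency (6, 18 or 26).
#' @param field Null-map model, `"gaussian"` or `"rank"`.
#' @param n1,n2 Group sizes for `field = "rank"`.
#' @return Integer extent threshold `k`, with the simulated max-extent
#'   distribution in attribute `"max_extents"`.
#' @export
monte_carlo_cluster_threshold <- function(mask, smoothness_fwhm_mm = 4,
                                          voxel_size_mm = 3,
                                          voxel_alpha = 0.05,
                                          fwe_alpha = 0.05,
                                          n_iter = 1000, seed = NULL,
                                          connectivity = 26,
                                          field = c("gaussian", "rank"),
                                          n1 = NULL, n2 = NULL) {
  field <- match.arg(field)
  if (sum(mask) < 2) stop("degenerate mask: need >= 2 voxels")
  if (n_iter < 100) stop("'n_iter' must be >= 100")
  if (voxel_alpha <= 0 || voxel_alpha >= 1 || fwe_alpha <= 0 || fwe_alpha > 1)
    stop("alphas must lie in (0, 1)")
  if (field == "rank" && (is.null(n1) || is.null(n2)))
    stop("'n1' and 'n2' are required for field = \"rank\"")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(mask)
  nv <- prod(d)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  thr <- stats::qnorm(1 - voxel_alpha / 2)
  max_ext <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    if (field == "gaussian") {
      eps <- array(stats::rnorm(nv), dim = d)
      if (smoothness_fwhm_mm > 0)
        eps <- smooth_array(eps, smoothness_fwhm_mm, voxel_size_mm)
      v <- eps[mask]
      zmap <- (eps - mean(v)) / stats::sd(v)
    } else {
      ns <- n1 + n2
      eps <- array(stats::rnorm(nv * ns), dim = c(d, ns))
      if (smoothness_fwhm_mm > 0)
        eps <- smooth_array(eps, smoothness_fwhm_mm, voxel_size_mm)
      flat <- t(matrix(eps, nrow = nv))      # subject x voxel
      zmap <- array(mw_z_matrix(flat[seq_len(n1), , drop = FALSE],
                                flat[n1 + seq_len(n2), , drop = FALSE]),
                    dim = d)
    }
    supra <- abs(zmap) > thr & mask
    max_ext[i] <- if (any(supra)) max(label_clusters(supra, connectivity)$extents)
                  else 0L
  }
  k <- 1L
  while (mean(max_ext >= k) > fwe_alpha) k <- k + 1L
  structure(k, max_extents = max_ext)
}

#' Apply voxel threshold and cluster-extent correction to a stat map
#'
#' Thresholds the per-voxel two-sided p-values at `voxel_alpha`, labels
#' clusters of contiguous supra-threshold voxels, and marks clusters of
#' extent `>= k` as surviving the correction.
#'
#' @param stat_map A [voxelwise_group_map()] result.
#' @param voxel_alpha Cluster-forming voxelwise threshold.
#' @param k Extent threshold from [monte_carlo_cluster_threshold()]
#'   (>= 1).
#' @param connectivity Cluster adjacency (6, 18 or 26).
#' @return List of class `cluster_table`: `table` (one row per
#'   supra-threshold cluster: `cluster_id`, `extent`, `peak_z`,
#'   `peak_i/j/k`, `corrected_pass`), `labels` (cluster label array),
#'   `surviving_labels` (labels of surviving clusters only), `members`,
#'   `k`, `voxel_alpha`, `connectivity`.
#' @export
cluster_corrected_map <- function(stat_map, voxel_alpha = 0.05, k,
                                  connectivity = 26) {
  if (k < 1) stop("'k' must be >= 1")
  p <- stat_map$p
  d <- dim(p)
  supra <- is.finite(p) & p < voxel_alpha
  lab <- label_clusters(array(supra, dim = d), connectivity)
  n_cl <- length(lab$members)
  if (n_cl) {
    peak <- t(vapply(lab$members, function(m) {
      zz <- abs(stat_map$z[m])
      pk <- m[which.max(zz)]
      c(pk, max(zz))
    }, numeric(2)))
    ijk <- arrayInd(as.integer(peak[, 1]), d)
    tab <- data.frame(cluster_id = seq_len(n_cl),
                      extent = lab$extents,
                      peak_z = peak[, 2],
                      peak_i = ijk[, 1], peak_j = ijk[, 2], peak_k = ijk[, 3],
                      corrected_pass = lab$extents >= k)
  } else {
    tab <- data.frame(cluster_id = integer(0), extent = integer(0),
                      peak_z = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      corrected_pass = logical(0))
  }
  surviving <- lab$labels
  surviving[!(surviving %in% tab$cluster_id[tab$corrected_pass])] <- 0L
  structure(list(table = tab, labels = lab$labels,
                 surviving_labels = surviving, members = lab$members,
                 k = as.integer(k), voxel_alpha = voxel_alpha,
                 connectivity = connectivity),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("Cluster table: %d supra-threshold cluster(s), %d surviving extent >= %d\n",
              nrow(x$table), sum(x$table$corrected_pass), x$k))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
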