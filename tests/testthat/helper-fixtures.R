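# Small shared fixtures, all generated in code.

# abbreviated study design for fast unit tests: 4 trials/block, small
# grid, single run
tiny_design <- function(grid_dim = c(4, 4, 4), n_trials = 4, n_runs = 1,
                        gap_s = 15) {
  study_design(n_trials = n_trials, n_runs = n_runs, gap_s = gap_s,
               grid_dim = grid_dim)
}

silent_noise <- function(seed = NULL) {
  noise_spec(sigma = 0, drift_amp = 0, seed = seed)
}

# noiseless run from scalar ground truth on the design grid
noiseless_run <- function(des, a = 0.5, b = 1, tau = 4) {
  simulate_run(ground_truth(a, b, tau, dim = des$grid_dim), des$schedules,
               tr_s = des$tr_s, n_vols = des$n_vols, hrf = des$hrf,
               noise = silent_noise(), voxel_size_mm = des$voxel_size_mm)
}

# independent oracle: exhaustive Mann-Whitney enumeration over all
# choose(n, n1) labelings of the pooled sample (midranks)
oracle_mw_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  list(U = u_obs,
       p_two = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12),
       p_one_low = mean(u_all <= u_obs + 1e-12))
}

# independent oracle: Benjamini-Hochberg by brute-force scan over all m
# candidate thresholds
oracle_bh_scan <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# independent oracle: cluster extents via igraph connected components
oracle_extents_igraph <- function(binary_map, connectivity) {
  supra <- which(binary_map)
  if (!length(supra)) return(integer(0))
  d <- dim(binary_map)
  co <- arrayInd(supra, d)
  edges <- NULL
  if (length(supra) > 1) {
    for (i in seq_len(length(supra) - 1)) {
      dd <- abs(sweep(co[(i + 1):length(supra), , drop = FALSE], 2, co[i, ]))
      adj <- switch(as.character(connectivity),
                    "6" = rowSums(dd) == 1,
                    "18" = apply(dd, 1, max) == 1 & rowSums(dd) <= 2,
                    "26" = apply(dd, 1, max) == 1)
      j <- which(adj) + i
      if (length(j)) edges <- rbind(edges, cbind(i, j))
    }
  }
  g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  as.integer(table(igraph::components(g)$membership))
}

# independent oracle: Monte-Carlo max-extent run mirroring the null-map
# generation order (rnorm volume per iteration), components via igraph
oracle_mc_threshold <- function(dim3, mask, voxel_alpha, fwe_alpha, n_iter,
                                seed, connectivity = 26) {
  set.seed(seed)
  thr <- qnorm(1 - voxel_alpha / 2)
  max_ext <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    eps <- array(rnorm(prod(dim3)), dim = dim3)
    v <- eps[mask]
    z <- (eps - mean(v)) / sd(v)
    supra <- abs(z) > thr & mask
    ext <- oracle_extents_igraph(supra, connectivity)
    max_ext[i] <- if (length(ext)) max(ext) else 0L
  }
  k <- 1L
  while (mean(max_ext >= k) > fwe_alpha) k <- k + 1L
  k
}
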