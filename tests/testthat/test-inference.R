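test_that("Mann-Whitney U, z and exact p match enumeration oracles", {
  mw <- mann_whitney_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  or <- oracle_mw_enum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(or$p_one_low, 1 / 20)        # the worked one-sided example
  expect_equal(mw$p, or$p_two)
  expect_equal(mw$method, "exact enumeration")

  # equal multisets: central U, zero z
  mw0 <- mann_whitney_z(c(1, 2, 3), c(3, 2, 1))
  expect_equal(mw0$U, 4.5)
  expect_equal(mw0$z, 0)

  # antisymmetry under group swap
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    a <- mann_whitney_z(x, y); b <- mann_whitney_z(y, x)
    expect_equal(a$U, length(x) * length(y) - b$U)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney_z(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration matches across all small group sizes, with ties", {
  set.seed(41)
  for (n1 in 2:6) for (n2 in 2:6) {
    if (n1 + n2 > 12) next
    x <- sample(1:5, n1, replace = TRUE)     # ties across and within groups
    y <- sample(1:5, n2, replace = TRUE)
    mw <- mann_whitney_z(x, y)
    or <- oracle_mw_enum(x, y)
    expect_equal(mw$U, or$U)
    expect_equal(mw$p, or$p_two, tolerance = 1e-12)
  }
  # tie-free exact p agrees with the standard two-sample implementation
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    mw <- mann_whitney_z(x, y)
    wt <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
    expect_equal(mw$U, unname(wt$statistic))
  }
})

test_that("the normal approximation tracks the exact p for moderate samples", {
  set.seed(42)
  for (n in 5:7) for (i in 1:20) {
    x <- rnorm(n); y <- rnorm(n)
    exact <- mann_whitney_z(x, y)$p
    approx <- mann_whitney_z(x, y, exact_max_n = 0)$p
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("effect size r follows z / sqrt(N), including the auditory-cortex example", {
  expect_equal(round(effect_size_r(2.6, 39), 2), 0.42)
  expect_equal(effect_size_r(0, 10), 0)
  expect_equal(effect_size_r(sqrt(25), 25), 1)
  expect_error(effect_size_r(1, 1), ">= 2")
})

test_that("voxelwise group maps agree with per-voxel scalar tests", {
  set.seed(43)
  T1 <- matrix(rnorm(5 * 6, 10), 5, 6)
  T2 <- matrix(rnorm(5 * 7, 6), 5, 7)
  sm <- voxelwise_group_map(T1, T2)
  for (v in 1:5) {
    mw <- mann_whitney_z(T1[v, ], T2[v, ])
    expect_equal(sm$z[v], mw$z)
    expect_equal(sm$p[v], mw$p)
    expect_equal(sm$r[v], effect_size_r(mw$z, 13))
  }
  # identical cohorts: z = 0 everywhere
  sm0 <- voxelwise_group_map(T1, T1)
  expect_true(all(abs(sm0$z) < 1e-12))
  # relabeling flips z but not |z| or p
  sm_sw <- voxelwise_group_map(T2, T1)
  expect_equal(sm_sw$z, -sm$z)
  expect_equal(sm_sw$p, sm$p)
  expect_error(voxelwise_group_map(T1, T2[1:3, ]), "different grids")
})

test_that("cluster labeling matches adjacency oracles", {
  # corner-sharing toy: distinct under 6/18, merged under 26
  b <- array(FALSE, c(2, 2, 2)); b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE
  expect_length(label_clusters(b, 6)$extents, 2)
  expect_length(label_clusters(b, 18)$extents, 2)
  expect_length(label_clusters(b, 26)$extents, 1)
  # edge-sharing pair merges under 18 and 26, not 6
  e <- array(FALSE, c(2, 2, 2)); e[1, 1, 1] <- TRUE; e[2, 2, 1] <- TRUE
  expect_length(label_clusters(e, 6)$extents, 2)
  expect_length(label_clusters(e, 18)$extents, 1)

  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(label_clusters(one, 26)$extents, 1L)
  full <- array(TRUE, c(3, 4, 2))
  expect_equal(label_clusters(full, 6)$extents, 24L)
  expect_error(label_clusters(full, 10), "6, 18, 26")

  # random maps against the igraph components oracle
  set.seed(44)
  for (i in 1:15) {
    m <- array(runif(6^3) < 0.25, dim = c(6, 6, 6))
    for (conn in c(6, 18, 26)) {
      got <- sort(label_clusters(m, conn)$extents)
      want <- sort(oracle_extents_igraph(m, conn))
      expect_equal(got, want)
    }
  }
  # clusters partition the supra-threshold voxels exactly
  m <- array(runif(5^3) < 0.3, dim = c(5, 5, 5))
  lab <- label_clusters(m, 26)
  expect_equal(sum(lab$extents), sum(m))
  expect_setequal(unlist(lab$members), which(m))
})

test_that("the Monte-Carlo extent threshold matches a brute-force oracle", {
  mask <- array(TRUE, c(6, 6, 6))
  k <- monte_carlo_cluster_threshold(mask, smoothness_fwhm_mm = 0,
                                     voxel_alpha = 0.05, fwe_alpha = 0.05,
                                     n_iter = 400, seed = 77)
  k_oracle <- oracle_mc_threshold(c(6, 6, 6), mask, 0.05, 0.05, 400, 77)
  expect_equal(as.integer(k), k_oracle)

  # fwe_alpha -> 1 accepts any cluster
  k1 <- monte_carlo_cluster_threshold(mask, 0, voxel_alpha = 0.05,
                                      fwe_alpha = 1, n_iter = 100, seed = 1)
  expect_equal(as.integer(k1), 1L)

  # smoothness can only raise the threshold (same seed ladder)
  ks <- vapply(c(0, 4, 8), function(fw)
    as.integer(monte_carlo_cluster_threshold(mask, fw, voxel_size_mm = 3,
                                             n_iter = 300, seed = 5)),
    integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_gt(ks[3], ks[1])

  tiny <- array(FALSE, c(2, 2, 2)); tiny[1, 1, 1] <- TRUE
  expect_error(monte_carlo_cluster_threshold(tiny, 0), "degenerate mask")
  expect_error(monte_carlo_cluster_threshold(mask, 0, n_iter = 50), ">= 100")
})

test_that("cluster correction keeps exactly the clusters of extent >= k", {
  d <- c(6, 6, 1)
  p <- array(1, dim = d)
  z <- array(0, dim = d)
  p[1:3, 1, 1] <- 0.01; z[1:3, 1, 1] <- c(2, 3, 2.5)   # extent 3
  p[5:6, 3, 1] <- 0.01; z[5:6, 3, 1] <- 2.2            # extent 2
  sm <- structure(list(p = p, z = z, mask = array(TRUE, d), dim = d,
                       n1 = 5, n2 = 5), class = "stat_map")
  ct <- cluster_corrected_map(sm, voxel_alpha = 0.05, k = 3)
  expect_equal(nrow(ct$table), 2)
  expect_equal(sort(ct$table$extent), c(2, 3))
  expect_equal(sum(ct$table$corrected_pass), 1)
  expect_equal(ct$table$peak_z[ct$table$extent == 3], 3)
  # boundary behavior: k equal to the extent keeps the cluster
  ct2 <- cluster_corrected_map(sm, voxel_alpha = 0.05, k = 2)
  expect_equal(sum(ct2$table$corrected_pass), 2)
  # nothing significant -> empty table
  sm$p[] <- 0.5
  ct3 <- cluster_corrected_map(sm, voxel_alpha = 0.05, k = 1)
  expect_equal(nrow(ct3$table), 0)
})
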