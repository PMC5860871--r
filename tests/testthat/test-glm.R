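test_that("two-gamma HRF has the expected shape", {
  h <- two_gamma_hrf()
  expect_equal(h$values[1], 0, tolerance = 1e-12)    # h(0) = 0
  expect_equal(max(h$values), 1, tolerance = 1e-6)   # max-normalized
  # dense-grid oracle for the peak location
  tg <- seq(0, 32, by = 0.001)
  hv <- hrf_eval(tg, hrf_params())
  expect_equal(tg[which.max(hv)], 5.0, tolerance = 0.02)
  # no undershoot -> nonnegative everywhere
  h0 <- two_gamma_hrf(hrf_params(undershoot_ratio = 0))
  expect_true(all(h0$values >= 0))
  # default kernel does undershoot below zero
  expect_lt(min(h$values), 0)
  expect_error(hrf_params(peak_shape = -1), "positive")
})

test_that("design matrix columns are HRF convolutions of the event trains", {
  hp <- hrf_params()
  # single impulse at t = 0, TR = 1: column equals the HRF at 0, 1, 2, ...
  s <- make_event_schedule(toa_s = 5, n_trials = 1, start_s = 0)
  dm <- build_design_matrix(list(s), tr_s = 1, n_vols = 30, hrf = hp)
  expect_equal(unname(dm$X[, "toa_5"]), hrf_eval(0:29, hp), tolerance = 1e-12)

  # superposition oracle: two events 3 s apart = sum of shifted HRFs
  s2 <- make_event_schedule(toa_s = 3, n_trials = 2, start_s = 4)
  dm2 <- build_design_matrix(list(s2), tr_s = 1, n_vols = 50, hrf = hp)
  manual <- hrf_eval(0:49 - 4, hp) + hrf_eval(0:49 - 7, hp)
  expect_equal(unname(dm2$X[, "toa_3"]), manual, tolerance = 1e-12)

  # onset outside the run is rejected, naming the onset
  s_bad <- make_event_schedule(toa_s = 10, n_trials = 3, start_s = 0)
  expect_error(build_design_matrix(list(s_bad), 1, 15), "20")
})

test_that("boxcar events integrate the HRF over the event window", {
  hp <- hrf_params()
  s <- make_event_schedule(toa_s = 9, n_trials = 1, start_s = 0,
                           duration_s = 2)
  dm <- build_design_matrix(list(s), tr_s = 1, n_vols = 30, hrf = hp)
  # fine-grid numeric integration oracle
  fine <- seq(0, 2, by = 1e-4)
  oracle <- vapply(0:29, function(t)
    sum(hrf_eval(t - fine, hp)) * 1e-4, numeric(1))
  expect_equal(unname(dm$X[, "toa_9"]), oracle, tolerance = 1e-3)
})

test_that("OLS recovers noiseless coefficients and has orthogonal residuals", {
  des <- tiny_design(grid_dim = c(3, 3, 3))
  run <- noiseless_run(des, a = 0.5, b = 1, tau = 4)
  dm <- build_design_matrix(des$schedules, des$tr_s, des$n_vols,
                            hrf = des$hrf)
  bm <- fit_glm(run, dm)
  truth <- 0.5 + exp(-c(3, 6, 9, 15) / 4)
  expect_lt(max(abs(sweep(bm$beta, 2, truth) / truth)), 1e-8)
  expect_equal(bm$df, des$n_vols - ncol(dm$X))

  # residual orthogonality on a noisy fit
  set.seed(4)
  gt <- ground_truth(0.5, 1, 4, dim = c(3, 3, 3))
  runn <- simulate_run(gt, des$schedules, n_vols = des$n_vols,
                       noise = noise_spec(0.5, 1, seed = 8))
  bmn <- fit_glm(runn, dm)
  Y <- t(matrix(runn$data, nrow = 27))
  resid <- Y - dm$X %*% qr.coef(qr(dm$X), Y)
  expect_lt(max(abs(crossprod(dm$X, resid))), 1e-7)
})

test_that("closed-form OLS on an orthonormal toy design matches inner products", {
  # hand-computable 4-timepoint toy with orthonormal columns
  X <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)) # orthonormal
  y <- c(2.5, -1, 3, 0.5)
  beta <- qr.coef(qr(X), y)
  expect_equal(unname(beta), c(sum(X[, 1] * y), sum(X[, 2] * y)))
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  des <- tiny_design(grid_dim = c(2, 2, 2))
  dm <- build_design_matrix(des$schedules, des$tr_s, des$n_vols,
                            hrf = des$hrf)
  dm$X <- cbind(dm$X, dup = dm$X[, "toa_3"])
  run <- noiseless_run(des)
  expect_error(fit_glm(run, dm), "rank deficient")
})

test_that("beta scales inversely with the HRF kernel amplitude", {
  des <- tiny_design(grid_dim = c(2, 2, 2))
  run <- noiseless_run(des, a = 0.5, b = 1, tau = 4)
  dm <- build_design_matrix(des$schedules, des$tr_s, des$n_vols,
                            hrf = des$hrf)
  dm_scaled <- dm
  dm_scaled$X[, dm$toa_cols] <- dm$X[, dm$toa_cols] * 2
  b1 <- fit_glm(run, dm)$beta
  b2 <- fit_glm(run, dm_scaled)$beta
  expect_equal(b1, b2 * 2, tolerance = 1e-10)
})

test_that("pure-noise betas center on zero and shrink with run length", {
  hp <- hrf_params()
  s <- list(make_event_schedule(3, 4), make_event_schedule(9, 4, 30))
  mean_abs_beta <- function(nt, seed) {
    dm <- build_design_matrix(s, 1, nt, hrf = hp)
    set.seed(seed)
    Y <- matrix(rnorm(nt * 100), nt, 100)
    mean(abs(fit_glm(Y, dm)$beta))
  }
  short <- mean_abs_beta(80, 11)
  long <- mean_abs_beta(640, 12)
  expect_lt(long, short)
  # E[beta] ~ 0: mean over 100 noise voxels small relative to spread
  dm <- build_design_matrix(s, 1, 160, hrf = hp)
  set.seed(13)
  B <- fit_glm(matrix(rnorm(160 * 100), 160, 100), dm)$beta
  expect_lt(abs(mean(B)), 3 * sd(B) / sqrt(length(B)) + 0.05)
})

test_that("BH step-up matches the brute-force scan and its worked examples", {
  expect_equal(bh_fdr(c(0.001, 0.008, 0.039, 0.041), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_equal(bh_fdr(0.04, 0.05), TRUE)   # m = 1 reduces to the plain threshold
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, 1.5), "\\(0, 1\\)")
  # oracle equivalence on random p-vectors, m <= 12
  set.seed(20)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- round(runif(m)^2, 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_equal(bh_fdr(p, q), oracle_bh_scan(p, q))
  }
})

test_that("task-responsive selection keeps driven voxels and controls the FDR", {
  des <- tiny_design(grid_dim = c(4, 4, 4))
  dm <- build_design_matrix(des$schedules, des$tr_s, des$n_vols,
                            hrf = des$hrf)
  # strongly driven, noiseless: every voxel selected
  bm <- fit_glm(noiseless_run(des), dm)
  mask <- select_task_responsive(bm, q = 0.001)
  expect_true(all(mask))

  # half driven at high SNR: selection includes all driven voxels and
  # contaminates at most a small fraction of null voxels
  b_map <- array(rep(c(1, 0), each = 32), dim = c(4, 4, 4))
  gt <- ground_truth(array(0.5 * (b_map > 0), dim = c(4, 4, 4)),
                     b_map, array(4, dim = c(4, 4, 4)))
  driven <- b_map > 0
  hits <- 0; fps <- 0
  for (seed in 1:10) {
    run <- simulate_run(gt, des$schedules, n_vols = des$n_vols,
                        noise = noise_spec(0.05, 0, seed = seed))
    m <- select_task_responsive(fit_glm(run, dm), q = 0.01)
    hits <- hits + sum(m & driven)
    fps <- fps + sum(m & !driven)
  }
  expect_equal(hits, 10 * sum(driven))
  expect_lte(fps / max(hits + fps, 1), 0.01 + 0.02)

  # pure noise at q = 0.001: essentially nothing selected
  sel_frac <- replicate(20, {
    Y <- matrix(rnorm(des$n_vols * 64), des$n_vols, 64)
    suppressWarnings(mean(select_task_responsive(fit_glm(Y, dm), q = 0.001)))
  })
  expect_lte(mean(sel_frac), 0.001 + 0.003)
})
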