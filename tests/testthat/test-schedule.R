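test_that("event schedules place onsets at multiples of the TOA", {
  s <- make_event_schedule(toa_s = 3, n_trials = 16, start_s = 0)
  expect_equal(s$onsets_s, seq(0, 45, by = 3))
  expect_length(s$onsets_s, 16)
  expect_equal(diff(s$onsets_s), rep(3, 15))

  s1 <- make_event_schedule(toa_s = 5, n_trials = 1, start_s = 10)
  expect_equal(s1$onsets_s, 10)

  # enumeration oracle for the longest block: 0, 15, ..., 15*(16-1)
  onsets <- vapply(0:15, function(i) i * 15, numeric(1))
  s15 <- make_event_schedule(toa_s = 15, n_trials = 16)
  expect_equal(s15$onsets_s, onsets)
  expect_equal(s15$onsets_s[16], 225)
})

test_that("degenerate schedule arguments are rejected", {
  expect_error(make_event_schedule(toa_s = 0, n_trials = 4), "positive")
  expect_error(make_event_schedule(toa_s = -1, n_trials = 4), "positive")
  expect_error(make_event_schedule(toa_s = 3, n_trials = 0), "positive integer")
  expect_error(make_event_schedule(toa_s = 3, n_trials = 2.5),
               "positive integer")
})

test_that("run layout separates blocks and spans the full protocol", {
  lay <- layout_run(c(3, 6, 9, 15), n_trials = 16, gap_s = 20)
  ends <- vapply(lay$schedules, function(s) max(s$onsets_s), numeric(1))
  starts <- vapply(lay$schedules, function(s) s$onsets_s[1], numeric(1))
  expect_true(all(starts[-1] - ends[-4] == 20))
  expect_equal(lay$n_vols, 575)

  tab <- write_event_tsv(lay$schedules, tempfile(fileext = ".tsv"))
  expect_equal(nrow(tab), 64)
  expect_setequal(unique(tab$toa), c(3, 6, 9, 15))
})

test_that("noiseless forward model follows the decay amplitudes", {
  des <- tiny_design()
  # b = 0 removes all TOA dependence
  run0 <- noiseless_run(des, a = 1, b = 0, tau = 7)
  dm <- build_design_matrix(des$schedules, des$tr_s, des$n_vols,
                            hrf = des$hrf)
  bm <- fit_glm(run0, dm)
  expect_equal(unname(bm$beta[1, ]), rep(1, 4), tolerance = 1e-10)

  # amplitudes equal a + b exp(-TOA/tau) at every TOA
  run <- noiseless_run(des, a = 0.5, b = 1.0, tau = 4)
  bm <- fit_glm(run, dm)
  expect_equal(unname(bm$beta[5, ]), 0.5 + 1.0 * exp(-c(3, 6, 9, 15) / 4),
               tolerance = 1e-10)

  # regressing generated amplitudes on exp(-TOA/tau_true) leaves zero
  # residual when noise is off
  z <- exp(-c(3, 6, 9, 15) / 4)
  res <- residuals(lm(bm$beta[1, ] ~ z))
  expect_lt(max(abs(res)), 1e-10)
})

test_that("simulation is deterministic under a fixed seed", {
  des <- tiny_design()
  gt <- ground_truth(0.5, 1, 4, dim = des$grid_dim)
  ns <- noise_spec(sigma = 0.3, drift_amp = 1, seed = 99)
  r1 <- simulate_run(gt, des$schedules, n_vols = des$n_vols, noise = ns)
  r2 <- simulate_run(gt, des$schedules, n_vols = des$n_vols, noise = ns)
  expect_identical(r1$data, r2$data)
  ns2 <- noise_spec(sigma = 0.3, drift_amp = 1, seed = 100)
  r3 <- simulate_run(gt, des$schedules, n_vols = des$n_vols, noise = ns2)
  expect_false(identical(r1$data, r3$data))
})

test_that("overlapping blocks and mismatched grids are rejected", {
  des <- tiny_design()
  gt <- ground_truth(0.5, 1, 4, dim = des$grid_dim)
  overlapping <- list(make_event_schedule(3, 4, start_s = 0),
                      make_event_schedule(6, 4, start_s = 5))
  expect_error(simulate_run(gt, overlapping), "overlap")
  expect_error(ground_truth(array(1, c(2, 2, 2)), array(1, c(3, 3, 3)),
                            array(4, c(3, 3, 3))),
               "different grids")
  expect_error(ground_truth(0, 1, -2, dim = c(2, 2, 2)), "positive")
})

test_that("cohorts have the study structure and honest ground truth", {
  des <- tiny_design()
  coh <- make_group_cohort(n_control = 19, n_dyslexic = 20,
                           design = des, seed = 5)
  expect_equal(nrow(coh$subjects), 39)
  expect_equal(sum(coh$subjects$group == "control"), 19)
  expect_equal(sum(coh$subjects$group == "dyslexic"), 20)
  expect_equal(length(des$schedules) * des$n_runs *
                 vapply(des$schedules, `[[`, integer(1), "n_trials")[1],
               16)  # 4 blocks x 1 run x 4 trials in the abbreviated design

  # zero between-subject spread pins every subject at the group center
  coh0 <- make_group_cohort(n_control = 3, n_dyslexic = 3,
                            tau_control_s = 10, tau_dyslexic_s = 5,
                            between_subject_sd = 0, design = des, seed = 5)
  expect_equal(coh0$subjects$tau,
               rep(c(10, 5), each = 3), tolerance = 1e-12)
  expect_error(make_group_cohort(tau_control_s = -1, design = des),
               "positive")

  # subject realization is reproducible from the stored seeds
  runs_a <- simulate_subject_runs(coh, 4)
  runs_b <- simulate_subject_runs(coh, 4)
  expect_identical(runs_a[[1]]$data, runs_b[[1]]$data)
})

test_that("a cohort can be written to disk with manifest and ground truth", {
  dir <- tempfile("cohort")
  des <- tiny_design(grid_dim = c(3, 3, 3))
  coh <- make_group_cohort(n_control = 1, n_dyslexic = 1, design = des,
                           seed = 2)
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "events.tsv")))
  expect_equal(nrow(man), 2)
  run_back <- read_nifti(strsplit(man$runs[1], ";")[[1]][1])
  orig <- simulate_subject_runs(coh, 1)[[1]]
  expect_equal(run_back$data, orig$data, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "sub-01_truth.json"))
  expect_equal(truth$tau, coh$subjects$tau[1], tolerance = 1e-12)
})
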