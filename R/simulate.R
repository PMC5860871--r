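#' Noise specification for synthetic BOLD runs
#'
#' Describes the stochastic components added to the noiseless forward
#' model: additive Gaussian noise, a slow cosine drift with random
#' per-voxel frequency (1-3 cycles per run) and phase, and optional
#' spatial smoothness of the noise field.
#'
#' @param sigma Additive Gaussian noise SD, signal units (>= 0).
#' @param drift_amp Maximum amplitude of the low-frequency drift;
#'   per-voxel amplitudes are drawn uniformly on `[0, drift_amp]`.
#' @param spatial_fwhm_mm Smoothness of the noise field, mm FWHM (the
#'   smoothed field is rescaled back to marginal SD `sigma`); 0 gives
#'   spatially independent noise.
#' @param seed Optional RNG seed applied before the run is generated.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.3, drift_amp = 1, spatial_fwhm_mm = 0,
                       seed = NULL) {
  if (sigma < 0 || drift_amp < 0 || spatial_fwhm_mm < 0)
    stop("'sigma', 'drift_amp' and 'spatial_fwhm_mm' must be >= 0")
  structure(list(sigma = sigma, drift_amp = drift_amp,
                 spatial_fwhm_mm = spatial_fwhm_mm, seed = seed),
            class = "noise_spec")
}

#' Ground-truth parameter maps for the forward model
#'
#' Per-voxel `(a, b, tau)` of the decay model; scalars are broadcast
#' over the grid.
#'
#' @param a,b,tau Scalars or 3D arrays: asymptotic level, adaptation
#'   magnitude, and time constant (s).
#' @param dim Grid dimensions when scalars are given.
#' @return List of class `ground_truth` with `a_map`, `b_map`,
#'   `tau_map`, `dim`.
#' @export
ground_truth <- function(a, b, tau, dim = c(12, 12, 12)) {
  bc <- function(x) if (is.array(x)) x else array(x, dim = dim)
  a_map <- bc(a); b_map <- bc(b); tau_map <- bc(tau)
  dims <- list(dim(a_map), dim(b_map), dim(tau_map))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("ground-truth maps are on different grids")
  bad <- b_map != 0 & (!is.finite(tau_map) | tau_map <= 0)
  if (any(bad))
    stop("tau must be positive and finite wherever b is nonzero")
  structure(list(a_map = a_map, b_map = b_map, tau_map = tau_map,
                 dim = dim(a_map)),
            class = "ground_truth")
}

# HRF regressor of a single block's event train, sampled at volume
# times; memoized, since the same schedules recur for every simulated
# run of a cohort
block_regressor <- function(sched, tr_s, n_vols, hrf) {
  key <- paste("reg", hrf_key(hrf), tr_s, n_vols, sched$toa_s,
               sched$onsets_s[1], sched$n_trials, sched$duration_s,
               sep = ":")
  hit <- .hrf_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_vol <- (seq_len(n_vols) - 1) * tr_s
  x <- numeric(n_vols)
  if (sched$duration_s == 0) {
    for (o in sched$onsets_s) x <- x + hrf_eval(t_vol - o, hrf)
  } else {
    for (o in sched$onsets_s)
      x <- x + hrf_integral(t_vol - o, hrf) -
        hrf_integral(t_vol - o - sched$duration_s, hrf)
  }
  .hrf_cache[[key]] <- x
  x
}

#' Simulate one BOLD run from the decay forward model
#'
#' Each block's event train is convolved with the HRF and scaled, per
#' voxel, by the decay-model amplitude `a + b * exp(-TOA / tau)` of that
#' block's TOA; drift and Gaussian noise are added on top.  With an
#' all-zero [noise_spec()] the run is the exact noiseless forward model,
#' so the GLM stage recovers the block amplitudes to numerical
#' precision.
#'
#' @param truth A [ground_truth()] object.
#' @param schedules List of [make_event_schedule()] blocks with disjoint
#'   time spans.
#' @param tr_s Repetition time, seconds.
#' @param n_vols Run length in volumes; defaults to the last event plus
#'   a 20 s tail.
#' @param hrf An [hrf_params()] set.
#' @param noise A [noise_spec()].
#' @param voxel_size_mm Voxel size, mm.
#' @return A [bold_run()].
#' @export
simulate_run <- function(truth, schedules, tr_s = 1, n_vols = NULL,
                         hrf = hrf_params(), noise = noise_spec(),
                         voxel_size_mm = c(3, 3, 3)) {
  stopifnot(inherits(truth, "ground_truth"))
  spans <- t(vapply(schedules, function(s)
    c(s$onsets_s[1], schedule_end(s)), numeric(2)))
  o <- order(spans[, 1])
  if (any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)]))
    stop("block time spans overlap")
  if (is.null(n_vols))
    n_vols <- as.integer(ceiling((max(spans[, 2]) + 20) / tr_s))
  d <- truth$dim
  nv <- prod(d)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  # noiseless forward model: T x V signal
  X <- vapply(schedules, block_regressor, numeric(n_vols),
              tr_s = tr_s, n_vols = n_vols, hrf = hrf)
  toas <- vapply(schedules, `[[`, numeric(1), "toa_s")
  b_vec <- as.numeric(truth$b_map)
  tau_vec <- as.numeric(truth$tau_map)
  decay_term <- function(toa) ifelse(b_vec == 0, 0, b_vec * exp(-toa / tau_vec))
  amps <- t(vapply(toas, function(toa) as.numeric(truth$a_map) + decay_term(toa),
                   numeric(nv)))                    # n_blocks x V
  Y <- X %*% amps
  if (noise$drift_amp > 0) {
    freq <- sample(1:3, nv, replace = TRUE)
    phase <- stats::runif(nv, 0, 2 * pi)
    amp <- stats::runif(nv, 0, noise$drift_amp)
    t_frac <- (seq_len(n_vols) - 1) / n_vols
    D <- cos(outer(2 * pi * t_frac, freq) +
               rep(phase, each = n_vols))
    Y <- Y + D * rep(amp, each = n_vols)
  }
  if (noise$sigma > 0) {
    eps <- matrix(stats::rnorm(n_vols * nv), n_vols, nv)
    if (noise$spatial_fwhm_mm > 0) {
      arr <- array(t(eps), dim = c(d, n_vols))
      arr <- smooth_array(arr, noise$spatial_fwhm_mm, voxel_size_mm)
      eps <- t(matrix(arr, nrow = nv, ncol = n_vols))
      eps <- eps / stats::sd(eps)   # restore unit marginal SD
    }
    Y <- Y + noise$sigma * eps
  }
  bold_run(array(t(Y), dim = c(d, n_vols)), tr_s = tr_s,
           voxel_size_mm = voxel_size_mm)
}

#' Study design of the adaptation experiment
#'
#' The scanner protocol emulated by the cohort generator: four
#' constant-TOA blocks (3, 6, 9, 15 s) of 16 trials per run, three runs
#' per subject, TR 1 s, with a rest gap between blocks so block
#' responses do not overlap after HRF convolution.
#'
#' @param toas_s TOA conditions, seconds.
#' @param n_trials Trials per block.
#' @param n_runs Runs per subject.
#' @param tr_s Repetition time, seconds.
#' @param gap_s Rest between consecutive blocks, seconds.
#' @param duration_s Modeled event duration (0 = impulse).
#' @param block_order Order of TOA blocks within a run (indices into
#'   `toas_s`); default ascending.
#' @param grid_dim Synthetic voxel grid dimensions.
#' @param voxel_size_mm Voxel size, mm.
#' @param hrf An [hrf_params()] set.
#' @return List of class `study_design`, including the per-run
#'   `schedules` and run length `n_vols`.
#' @export
study_design <- function(toas_s = c(3, 6, 9, 15), n_trials = 16, n_runs = 3,
                         tr_s = 1, gap_s = 20, duration_s = 0,
                         block_order = seq_along(toas_s),
                         grid_dim = c(12, 12, 12), voxel_size_mm = c(3, 3, 3),
                         hrf = hrf_params()) {
  lay <- layout_run(toas_s[block_order], n_trials = n_trials, gap_s = gap_s,
                    tr_s = tr_s, duration_s = duration_s)
  structure(list(toas_s = toas_s, n_trials = n_trials, n_runs = n_runs,
                 tr_s = tr_s, gap_s = gap_s, duration_s = duration_s,
                 block_order = block_order, grid_dim = grid_dim,
                 voxel_size_mm = voxel_size_mm, hrf = hrf,
                 schedules = lay$schedules, n_vols = lay$n_vols),
            class = "study_design")
}

#' Generate a two-group synthetic cohort with known ground truth
#'
#' Emulates the study cohort: `n_control` good readers and `n_dyslexic`
#' dyslexic readers, each with subject-level decay parameters drawn
#' around the group centers (`tau` on the log scale, so it stays
#' positive and right-skewed) and three runs of four constant-TOA
#' blocks.  The cohort object is lazy: it stores the subject parameter
#' table and per-subject seeds; [simulate_subject_runs()] realizes any
#' subject's runs deterministically on demand, so arbitrarily large
#' cohorts never need to be held in memory at once.
#'
#' @param n_control,n_dyslexic Group sizes (>= 1).
#' @param tau_control_s,tau_dyslexic_s Group tau centers, seconds (> 0).
#' @param between_subject_sd SD of subject log-tau around the group
#'   center.
#' @param a_mean,b_mean,a_sd,b_sd Centers and between-subject SDs of the
#'   asymptotic level and adaptation magnitude.
#' @param noise A [noise_spec()] shared by all subjects (its `seed` is
#'   ignored; per-subject seeds are derived from `seed`).
#' @param design A [study_design()].
#' @param seed Master seed for the cohort.
#' @return Object of class `cohort`: list with `subjects` (data frame:
#'   `subject`, `group`, `a`, `b`, `tau`, `seed`), `design`, `noise`,
#'   `seed`.
#' @export
make_group_cohort <- function(n_control = 19, n_dyslexic = 20,
                              tau_control_s = 10, tau_dyslexic_s = 5,
                              between_subject_sd = 0.2,
                              a_mean = 0.5, b_mean = 1,
                              a_sd = 0.05, b_sd = 0.1,
                              noise = noise_spec(), design = study_design(),
                              seed = 1) {
  if (n_control < 1 || n_dyslexic < 1) stop("group sizes must be >= 1")
  if (tau_control_s <= 0 || tau_dyslexic_s <= 0)
    stop("group tau centers must be positive")
  if (between_subject_sd < 0) stop("'between_subject_sd' must be >= 0")
  set.seed(seed)
  n <- n_control + n_dyslexic
  grp <- factor(rep(c("control", "dyslexic"), c(n_control, n_dyslexic)),
                levels = c("control", "dyslexic"))
  centers <- ifelse(grp == "control", tau_control_s, tau_dyslexic_s)
  subjects <- data.frame(
    subject = sprintf("sub-%02d", seq_len(n)),
    group = grp,
    a = stats::rnorm(n, a_mean, a_sd),
    b = stats::rnorm(n, b_mean, b_sd),
    tau = exp(stats::rnorm(n, log(centers), between_subject_sd)),
    seed = sample.int(2^31 - 1000, n)
  )
  structure(list(subjects = subjects, design = design, noise = noise,
                 seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tb <- table(x$subjects$group)
  cat(sprintf(
    "Synthetic cohort: %d control + %d dyslexic subjects, %d run(s) of %d blocks, grid %s\n",
    tb[["control"]], tb[["dyslexic"]], x$design$n_runs,
    length(x$design$schedules), paste(x$design$grid_dim, collapse = "x")))
  invisible(x)
}

#' Ground-truth maps of one cohort subject
#'
#' @param cohort A [make_group_cohort()] object.
#' @param subject Subject index (row of `cohort$subjects`).
#' @return A [ground_truth()] object on the cohort grid.
#' @export
ground_truth_maps <- function(cohort, subject) {
  s <- cohort$subjects[subject, ]
  ground_truth(s$a, s$b, s$tau, dim = cohort$design$grid_dim)
}

#' Realize the BOLD runs of one cohort subject
#'
#' Deterministic given the cohort: run `r` of subject `i` is generated
#' under seed `subjects$seed[i] + r - 1`.
#'
#' @inheritParams ground_truth_maps
#' @return List of [bold_run()] objects, one per run.
#' @export
simulate_subject_runs <- function(cohort, subject) {
  des <- cohort$design
  truth <- ground_truth_maps(cohort, subject)
  base_seed <- cohort$subjects$seed[subject]
  lapply(seq_len(des$n_runs), function(r) {
    ns <- cohort$noise
    ns$seed <- base_seed + r - 1
    simulate_run(truth, des$schedules, tr_s = des$tr_s, n_vols = des$n_vols,
                 hrf = des$hrf, noise = ns,
                 voxel_size_mm = des$voxel_size_mm)
  })
}
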