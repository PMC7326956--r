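#' Subject configuration for the synthetic cohort generator
#'
#' Collects everything needed to generate one subject's four runs: the voxel
#' grid, baseline signal, noise model (AR(1) Gaussian with stationary sd
#' `noise_sd`), linear scanner drift, the activation topography, and the
#' learning rate that drives the widespread-to-focal change across feedback
#' runs. Defaults put the contrast-to-noise ratio at region cores near 1
#' (hand-area amplitude 2 signal units, `noise_sd` 2) with a drift slope of
#' 2% of the noise sd per volume, a regime where detrending matters.
#'
#' @param seed Integer seed; together with the run index it fully determines
#'   a run's data.
#' @param grid_dims Grid dimensions (each >= 8 for the default topography).
#' @param baseline Baseline signal level (arbitrary units; default 100 so
#'   amplitudes read as percent signal change).
#' @param noise_sd Stationary standard deviation of the AR(1) noise; > 0.
#' @param ar1 Lag-1 autocorrelation in `[0, 1)`.
#' @param drift_slope Linear drift in signal units per volume.
#' @param learning_rate Fraction in `[0, 1]`; see [topography_for_run()].
#' @param topography Base [activation_topography()]; defaults to
#'   [default_topography()] on `grid_dims`.
#' @param voxel_mm Isotropic voxel size in mm (used by smoothing).
#' @return A `subject_config` object.
#' @export
subject_config <- function(seed = 0L,
                           grid_dims = c(24L, 24L, 12L),
                           baseline = 100,
                           noise_sd = 2,
                           ar1 = 0.3,
                           drift_slope = 0.02 * noise_sd,
                           learning_rate = 0.4,
                           topography = default_topography(grid_dims),
                           voxel_mm = 3) {
  stopifnot(noise_sd > 0, ar1 >= 0, ar1 < 1,
            learning_rate >= 0, learning_rate <= 1,
            all(topography$grid_dims == grid_dims))
  structure(list(seed = as.integer(seed), grid_dims = as.integer(grid_dims),
                 baseline = baseline, noise_sd = noise_sd, ar1 = ar1,
                 drift_slope = drift_slope, learning_rate = learning_rate,
                 topography = topography, voxel_mm = voxel_mm),
            class = "subject_config")
}

#' Simulate one fMRI run
#'
#' Forward model: `baseline + sum over regions of
#' amplitude * sphere * (condition boxcar convolved with the canonical HRF)
#' + drift_slope * volume_index + AR(1) Gaussian noise`. The realization is
#' fully determined by `(config$seed, run_index)`. Condition boxcars use the
#' schedule's unshifted block labels.
#'
#' @param schedule A [build_schedule()] object.
#' @param topography The run's [activation_topography()] (already evolved for
#'   this run, see [topography_for_run()]).
#' @param config A [subject_config()].
#' @param run_index Run number in `0:3`.
#' @return A `synthetic_run`: list with `data` (voxels x volumes matrix,
#'   column-major grid flattening), `schedule`, `run_index`, `grid_dims`,
#'   `truth_masks` (per-condition logical 3D arrays).
#' @export
simulate_run <- function(schedule, topography, config, run_index) {
  stopifnot(inherits(schedule, "block_schedule"),
            inherits(topography, "activation_topography"),
            inherits(config, "subject_config"),
            run_index %in% 0:3)
  g <- config$grid_dims
  nv <- prod(g)
  nt <- schedule$n_volumes
  raw_labels <- rep(schedule$blocks$condition,
                    times = round(schedule$blocks$duration_s / schedule$tr_s))

  signal <- matrix(0, nv, nt)
  reg <- topography$regions
  regressors <- list(
    LGO = .condition_regressor(raw_labels, "LGO", schedule$tr_s),
    RGO = .condition_regressor(raw_labels, "RGO", schedule$tr_s)
  )
  for (i in seq_len(nrow(reg))) {
    if (reg$amplitude[i] <= 0) next
    m <- as.vector(.sphere_mask(g, c(reg$cx[i], reg$cy[i], reg$cz[i]),
                                reg$radius[i]))
    r <- switch(reg$selectivity[i],
                LGO  = regressors$LGO,
                RGO  = regressors$RGO,
                BOTH = regressors$LGO + regressors$RGO)
    signal[m, ] <- signal[m, ] + reg$amplitude[i] * rep(r, each = sum(m))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer((config$seed * 1000 + run_index) %%
                        .Machine$integer.max))
  noise <- matrix(0, nv, nt)
  noise[, 1L] <- stats::rnorm(nv, sd = config$noise_sd)
  if (nt > 1L) {
    innov_sd <- config$noise_sd * sqrt(1 - config$ar1^2)
    for (t in 2:nt)
      noise[, t] <- config$ar1 * noise[, t - 1L] +
        stats::rnorm(nv, sd = innov_sd)
  }

  drift <- config$drift_slope * (seq_len(nt) - 1L)
  data <- config$baseline + signal + noise
  data <- data + rep(drift, each = nv)

  structure(list(run_index = as.integer(run_index), data = data,
                 schedule = schedule, grid_dims = g,
                 truth_masks = .truth_masks(topography),
                 topography = topography),
            class = "synthetic_run")
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat("Synthetic fMRI run ", x$run_index, ": grid ",
      paste(x$grid_dims, collapse = "x"), ", ", ncol(x$data), " volumes, ",
      sum(x$truth_masks$LGO | x$truth_masks$RGO), " active voxels\n", sep = "")
  invisible(x)
}

#' Simulate one subject (runs 0-3)
#'
#' Run 0 uses the base (widespread) topography; runs 1-3 use
#' [topography_for_run()] with the subject's learning rate, producing the
#' progressively more focal activation that makes a classifier trained on
#' earlier runs stale.
#'
#' @param config A [subject_config()].
#' @param schedule A [build_schedule()]; defaults to the standard protocol.
#' @return An `nf_subject`: list of 4 `synthetic_run`s plus the config.
#' @export
simulate_subject <- function(config, schedule = build_schedule()) {
  runs <- lapply(0:3, function(r) {
    topo <- topography_for_run(config$topography, r, config$learning_rate)
    simulate_run(schedule, topo, config, r)
  })
  structure(list(runs = runs, config = config, schedule = schedule),
            class = "nf_subject")
}

#' Per-subject configurations for a cohort
#'
#' Subject `s` (0-based) uses seed `base_seed + s`. Subject-level variability
#' is modeled by jittering region amplitudes (multiplicative, +/-10%) and the
#' learning rate (additive, +/-0.1, clipped to `[0, 1]`), drawn
#' deterministically from the subject seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base_seed Integer base seed.
#' @param template A [subject_config()] used as the template.
#' @return List of `subject_config`s.
#' @export
cohort_configs <- function(n_subjects = 30L, base_seed = 0L,
                           template = subject_config()) {
  stopifnot(n_subjects >= 2L)
  lapply(seq_len(n_subjects) - 1L, function(s) {
    seed <- as.integer(base_seed + s)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer((seed * 1000 + 999) %% .Machine$integer.max))
    reg <- template$topography$regions
    reg$amplitude <- reg$amplitude * stats::runif(nrow(reg), 0.9, 1.1)
    lr <- min(1, max(0, template$learning_rate + stats::runif(1, -0.1, 0.1)))
    subject_config(seed = seed, grid_dims = template$grid_dims,
                   baseline = template$baseline, noise_sd = template$noise_sd,
                   ar1 = template$ar1, drift_slope = template$drift_slope,
                   learning_rate = lr,
                   topography = activation_topography(reg,
                                                      template$grid_dims),
                   voxel_mm = template$voxel_mm)
  })
}

#' Simulate a full cohort
#'
#' @inheritParams cohort_configs
#' @param schedule A [build_schedule()].
#' @return List of `nf_subject`s (length `n_subjects`). For large grids
#'   prefer generating subjects one at a time from [cohort_configs()].
#' @export
simulate_cohort <- function(n_subjects = 30L, base_seed = 0L,
                            template = subject_config(),
                            schedule = build_schedule()) {
  lapply(cohort_configs(n_subjects, base_seed, template),
         simulate_subject, schedule = schedule)
}

#' Export a run to NIfTI plus an events TSV
#'
#' @param run A `synthetic_run`.
#' @param nifti_path Output 4D NIfTI path (.nii or .nii.gz).
#' @param events_path Optional events TSV path (see [write_schedule_tsv()]).
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return `nifti_path`, invisibly.
#' @export
write_run_nifti <- function(run, nifti_path, events_path = NULL,
                            voxel_mm = 3) {
  stopifnot(inherits(run, "synthetic_run"))
  arr <- array(run$data, dim = c(run$grid_dims, ncol(run$data)))
  img <- RNifti::asNifti(arr, pixdim = c(rep(voxel_mm, 3),
                                         run$schedule$tr_s))
  RNifti::writeNifti(img, nifti_path)
  if (!is.null(events_path)) write_schedule_tsv(run$schedule, events_path)
  invisible(nifti_path)
}

#' Read a 4D NIfTI run with a block schedule
#'
#' Real-data entry point: wraps an external 4D image and its events file into
#' the same `synthetic_run` container the simulator produces (without truth
#' masks).
#'
#' @param nifti_path 4D NIfTI path.
#' @param schedule A [build_schedule()] or the result of
#'   [read_schedule_tsv()].
#' @param run_index Run number.
#' @return A `synthetic_run` (with `truth_masks = NULL`).
#' @export
read_run_nifti <- function(nifti_path, schedule, run_index = 0L) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  if (d[4] != schedule$n_volumes)
    stop("image has ", d[4], " volumes but the schedule implies ",
         schedule$n_volumes)
  structure(list(run_index = as.integer(run_index),
                 data = matrix(as.numeric(img), prod(d[1:3]), d[4]),
                 schedule = schedule, grid_dims = d[1:3],
                 truth_masks = NULL, topography = NULL),
            class = "synthetic_run")
}
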