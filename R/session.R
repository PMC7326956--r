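#' Session configuration
#'
#' Processing parameters shared by the real-time loop and the training path.
#'
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param mask Logical 3D array; `NULL` means all voxels (the whole-grid
#'   analogue of a whole-brain mask).
#' @param increment_deg Feedback increment per correct task volume.
#' @param mirror_arms Swap the cue-to-arm mapping (see [feedback_state()]).
#' @param label_shift_volumes Hemodynamic-lag shift applied to per-volume
#'   labels for training and metrics (default 0: labels follow the block
#'   bookkeeping literally).
#' @param contrasts Which binary models to train/evaluate.
#' @param cost SVM regularization constant.
#' @param train_discard_volumes Number of initial volumes dropped from
#'   training sets (default 0: the real-time path keeps all volumes).
#' @return A `session_config` list.
#' @export
session_config <- function(fwhm_mm = 8, voxel_mm = 3, mask = NULL,
                           increment_deg = 11, mirror_arms = FALSE,
                           label_shift_volumes = 0L,
                           contrasts = c("R_vs_LGO", "R_vs_RGO",
                                         "LGO_vs_RGO"),
                           cost = 1, train_discard_volumes = 0L) {
  stopifnot(all(contrasts %in% c("R_vs_LGO", "R_vs_RGO", "LGO_vs_RGO")))
  structure(list(fwhm_mm = fwhm_mm, voxel_mm = voxel_mm, mask = mask,
                 increment_deg = increment_deg, mirror_arms = mirror_arms,
                 label_shift_volumes = as.integer(label_shift_volumes),
                 contrasts = contrasts, cost = cost,
                 train_discard_volumes = as.integer(train_discard_volumes)),
            class = "session_config")
}

.contrast_classes <- function(contrast) {
  switch(contrast,
         R_vs_LGO   = c(neg = "REST", pos = "LGO"),
         R_vs_RGO   = c(neg = "REST", pos = "RGO"),
         LGO_vs_RGO = c(neg = "RGO", pos = "LGO"),
         stop("unknown contrast: ", contrast))
}

.session_mask <- function(config, grid_dims) {
  if (is.null(config$mask)) array(TRUE, dim = grid_dims) else config$mask
}

.shifted_labels <- function(run, config) {
  sched <- run$schedule
  sched$label_shift_volumes <- config$label_shift_volumes
  labels_for(sched)
}

# smooth -> mask: features shared by the training and real-time paths
.masked_features <- function(run, config) {
  sm <- smooth_run(run, config$fwhm_mm, config$voxel_mm)
  apply_mask(sm, .session_mask(config, run$grid_dims))
}

# strictly causal per-volume residuals of the streaming detrender
.streaming_residuals <- function(feats) {
  st <- detrend_state(nrow(feats))
  resid <- matrix(0, nrow(feats), ncol(feats))
  for (t in seq_len(ncol(feats))) {
    up <- detrend_update(st, feats[, t])
    st <- up$state
    resid[, t] <- up$residuals
  }
  resid
}

# train the configured contrasts from masked features + labels
.train_models_from <- function(feats, labels, config) {
  detr <- batch_detrend(feats)
  keep0 <- seq_len(ncol(detr)) > config$train_discard_volumes
  models <- list()
  for (ct in config$contrasts) {
    cls <- .contrast_classes(ct)
    sel <- keep0 & labels %in% cls
    models[[ct]] <- train_linear_svm(detr[, sel, drop = FALSE],
                                     labels[sel], c = config$cost,
                                     positive_class = cls[["pos"]])
  }
  models
}

# train all configured contrasts on one run
.train_models <- function(run, config) {
  .train_models_from(.masked_features(run, config),
                     .shifted_labels(run, config), config)
}

#' Simulated real-time classification of one feedback run
#'
#' Reproduces the per-volume loop of a closed-loop session: each volume is
#' smoothed, masked, incrementally detrended, classified by the model
#' matching the current block's cue, the decision trace is drift-corrected,
#' and — during task blocks — the feedback arm is raised on a task call.
#' Rest-block volumes are classified and logged but drive no feedback.
#' Smoothing uses only the current volume, so it is applied to the whole run
#' up front; detrending and output correction are strictly causal.
#'
#' @param run A `synthetic_run`.
#' @param models Named list of `linear_svm`s, at least `R_vs_LGO` and
#'   `R_vs_RGO`; an optional `LGO_vs_RGO` model is evaluated on the same
#'   features for offline metrics.
#' @param config A [session_config()].
#' @return A `session_run`: decision traces per contrast, per-volume
#'   feedback-driving predictions, the feedback history, and per-run metrics
#'   (TPV per rest-task contrast, pairwise accuracy if available).
#' @export
run_realtime <- function(run, models, config = session_config()) {
  stopifnot(inherits(run, "synthetic_run"),
            all(c("R_vs_LGO", "R_vs_RGO") %in% names(models)))
  feats <- .masked_features(run, config)
  for (m in models)
    if (length(m$weights) != nrow(feats))
      stop("model has ", length(m$weights), " weights but the mask selects ",
           nrow(feats), " voxels")
  .realtime_from_resid(run, .streaming_residuals(feats), models, config)
}

# real-time loop given precomputed streaming residuals (model-independent)
.realtime_from_resid <- function(run, resid, models, config) {
  nt <- ncol(resid)
  traces <- lapply(models, function(m) {
    raw <- decision_value(m, resid)
    detrend_decisions(raw, m$positive_class, m$negative_class)
  })

  vb <- .volume_blocks(run$schedule)
  fb <- feedback_state(config$increment_deg, config$mirror_arms)
  predicted <- rep(NA_character_, nt)
  for (t in seq_len(nt)) {
    cue <- vb$condition[t]
    if (cue %in% c("LGO", "RGO")) {
      m_name <- paste0("R_vs_", cue)
      call_t <- if (traces[[m_name]]$corrected[t] > 0) "task" else "rest"
      predicted[t] <- call_t
      fb <- feedback_step(fb, cue, call_t, is_block_end = vb$is_block_end[t],
                          volume = t - 1L)
    }
  }

  labels <- .shifted_labels(run, config)
  metrics <- list()
  if (any(labels == "LGO"))
    metrics$tpv_R_vs_LGO <- tpv(traces$R_vs_LGO$labels, labels, "LGO")
  if (any(labels == "RGO"))
    metrics$tpv_R_vs_RGO <- tpv(traces$R_vs_RGO$labels, labels, "RGO")
  if (!is.null(traces$LGO_vs_RGO))
    metrics$acc_LGO_vs_RGO <- pairwise_accuracy(traces$LGO_vs_RGO$labels,
                                                labels)

  structure(list(run_index = run$run_index, traces = traces,
                 predicted = predicted, feedback = fb, metrics = metrics,
                 labels = labels),
            class = "session_run")
}

#' Fit a closed-loop neurofeedback session
#'
#' The central fitting function. Trains the initial classifiers on run 0,
#' then replays feedback runs 1-3 through the simulated real-time loop under
#' one of two training strategies: `"incremental"` retrains every contrast
#' after each feedback run using only that run's newly acquired data (run
#' `r` is always classified by the model trained on run `r - 1`), while
#' `"static"` keeps the run-0 models throughout. Retraining labels come from
#' the known block schedule. Streaming detrend state is reset at every run
#' boundary (runs are separate scans).
#'
#' @param subject An `nf_subject` (see [simulate_subject()]) or a list with
#'   `$runs` holding four `synthetic_run`s (runs 0-3).
#' @param strategy `"incremental"` or `"static"`.
#' @param config A [session_config()].
#' @return An `nf_session`: per-feedback-run `session_run` results, the model
#'   generations per contrast (4 under incremental, 1 under static), the
#'   strategy, config, and subject seed.
#' @examples
#' \donttest{
#' subj <- simulate_subject(subject_config(seed = 1, grid_dims = c(10, 10, 8),
#'   topography = default_topography(c(10, 10, 8))))
#' fit <- nf_session(subj, "incremental")
#' summary(fit)
#' }
#' @export
nf_session <- function(subject, strategy = c("incremental", "static"),
                       config = session_config()) {
  strategy <- match.arg(strategy)
  .fit_sessions(subject, strategy, config)[[strategy]]
}

# Fit one subject under one or both strategies, preprocessing each run and
# training each model generation exactly once (run 1 under the static
# strategy reuses the incremental run-1 result: same model, same data).
.fit_sessions <- function(subject, strategies, config) {
  runs <- subject$runs
  if (length(runs) != 4L) stop("subject must have 4 runs (0-3)")
  mask <- .session_mask(config, runs[[1L]]$grid_dims)
  need_incr <- "incremental" %in% strategies

  generations <- list(.train_models(runs[[1L]], config))
  results <- list(incremental = vector("list", 3L),
                  static = vector("list", 3L))
  for (r in 1:3) {
    run <- runs[[r + 1L]]
    feats <- .masked_features(run, config)
    for (m in generations[[1L]])
      if (length(m$weights) != nrow(feats))
        stop("model/mask feature mismatch in run ", r)
    resid <- .streaming_residuals(feats)
    if (need_incr) {
      results$incremental[[r]] <-
        .realtime_from_resid(run, resid, generations[[r]], config)
      generations[[r + 1L]] <-
        .train_models_from(feats, .shifted_labels(run, config), config)
    }
    if ("static" %in% strategies) {
      results$static[[r]] <- if (need_incr && r == 1L)
        results$incremental[[1L]] else
          .realtime_from_resid(run, resid, generations[[1L]], config)
    }
  }
  out <- lapply(stats::setNames(strategies, strategies), function(strat) {
    gens <- if (strat == "incremental") generations else generations[1L]
    structure(list(strategy = strat, results = results[[strat]],
                   generations = gens, config = config,
                   seed = subject$config$seed,
                   grid_dims = runs[[1L]]$grid_dims, mask = mask),
              class = "nf_session")
  })
  out
}

#' @export
print.nf_session <- function(x, ...) {
  cat("Neurofeedback session (", x$strategy, " strategy, ",
      length(x$generations), " model generation(s))\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
summary.nf_session <- function(object, ...) {
  rows <- do.call(rbind, lapply(seq_along(object$results), function(r) {
    m <- object$results[[r]]$metrics
    data.frame(run = r,
               tpv_R_vs_LGO = m$tpv_R_vs_LGO %||% NA_real_,
               tpv_R_vs_RGO = m$tpv_R_vs_RGO %||% NA_real_,
               acc_LGO_vs_RGO = m$acc_LGO_vs_RGO %||% NA_real_)
  }))
  class(rows) <- c("summary.nf_session", "data.frame")
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.nf_session <- function(object, contrast = "R_vs_LGO",
                            generation = length(object$generations), ...) {
  coef(object$generations[[generation]][[contrast]])
}

#' @export
predict.nf_session <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "synthetic_run"))
  gens <- object$generations
  run_realtime(newdata, gens[[length(gens)]], object$config)
}

#' @export
plot.nf_session <- function(x, ...) {
  s <- summary(x)
  graphics::matplot(s$run, s[, -1L], type = "b", pch = 16, lty = 1,
                    xlab = "feedback run", ylab = "percent", ylim = c(0, 100),
                    main = paste0("Decoding performance (", x$strategy, ")"),
                    xaxt = "n", ...)
  graphics::axis(1, at = s$run)
  graphics::legend("bottomleft", legend = colnames(s)[-1L], col = 1:3,
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
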