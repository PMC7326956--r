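#' Run the cohort experiment
#'
#' Simulates each subject of a seeded cohort, fits an [nf_session()] under
#' each requested strategy, and collects the per-run decoding metrics.
#' Subjects are generated one at a time so memory stays flat at the default
#' grid. Optionally keeps each subject's run-0 weight maps for group-level
#' weight analyses.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param base_seed Integer base seed; subject `s` uses `base_seed + s`.
#' @param template A [subject_config()] template.
#' @param strategies Character subset of `c("incremental", "static")`.
#' @param config A [session_config()].
#' @param schedule A [build_schedule()].
#' @param keep_weight_maps Keep run-0 weight maps per subject/contrast.
#' @return An `nf_cohort`: `metrics` data.frame with one row per
#'   `(subject, run, contrast, strategy)`, plus `weight_maps` when requested.
#' @export
run_cohort <- function(n_subjects = 30L, base_seed = 0L,
                       template = subject_config(),
                       strategies = c("incremental", "static"),
                       config = session_config(),
                       schedule = build_schedule(),
                       keep_weight_maps = FALSE) {
  stopifnot(all(strategies %in% c("incremental", "static")))
  configs <- cohort_configs(n_subjects, base_seed, template)
  rows <- list()
  wmaps <- if (keep_weight_maps) list() else NULL
  for (s in seq_along(configs)) {
    subj <- simulate_subject(configs[[s]], schedule)
    fits <- .fit_sessions(subj, strategies, config)
    for (strat in strategies) {
      fit <- fits[[strat]]
      for (r in 1:3) {
        m <- fit$results[[r]]$metrics
        for (ct in names(m)) {
          contrast <- sub("^(tpv|acc)_", "", ct)
          metric <- if (startsWith(ct, "tpv")) "TPV" else "accuracy"
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s - 1L, run = r, contrast = contrast,
            strategy = strat, metric = metric, value = m[[ct]],
            stringsAsFactors = FALSE)
        }
      }
      if (keep_weight_maps && strat == strategies[[1L]]) {
        wmaps[[s]] <- lapply(fit$generations[[1L]], weight_map,
                             mask = fit$mask)
      }
    }
  }
  structure(list(metrics = do.call(rbind, rows),
                 n_subjects = n_subjects, base_seed = base_seed,
                 strategies = strategies, weight_maps = wmaps),
            class = "nf_cohort")
}

#' @export
print.nf_cohort <- function(x, ...) {
  cat("Neurofeedback cohort: ", x$n_subjects, " subjects, strategies: ",
      paste(x$strategies, collapse = ", "), "\n", sep = "")
  print(cohort_report(x)$table)
  invisible(x)
}

#' Summarize cohort decoding performance
#'
#' Produces the standard performance table — mean (sd) per run, contrast and
#' strategy — plus, per contrast and strategy, the one-way repeated-measures
#' ANOVA across feedback runs 1-3 and the post-hoc paired t-tests between run
#' pairs (two-sided, uncorrected).
#'
#' @param cohort An `nf_cohort`, or its `metrics` data.frame.
#' @return List with `table` (summary data.frame), `anova` and `posthoc`
#'   (named lists of `stat_result`s), and `wide` (subject x run matrices per
#'   contrast/strategy).
#' @export
cohort_report <- function(cohort) {
  metrics <- if (inherits(cohort, "nf_cohort")) cohort$metrics else cohort
  stopifnot(is.data.frame(metrics),
            all(c("subject", "run", "contrast", "strategy", "value") %in%
                  names(metrics)))
  combos <- unique(metrics[, c("contrast", "strategy")])
  tab_rows <- list(); anova <- list(); posthoc <- list(); wide <- list()
  for (i in seq_len(nrow(combos))) {
    ct <- combos$contrast[i]; strat <- combos$strategy[i]
    sub <- metrics[metrics$contrast == ct & metrics$strategy == strat, ]
    runs <- sort(unique(sub$run))
    W <- sapply(runs, function(r) {
      s <- sub[sub$run == r, ]
      s$value[order(s$subject)]
    })
    key <- paste(ct, strat, sep = ".")
    wide[[key]] <- W
    for (j in seq_along(runs)) {
      tab_rows[[length(tab_rows) + 1L]] <- data.frame(
        contrast = ct, strategy = strat, run = runs[j],
        mean = mean(W[, j]), sd = stats::sd(W[, j]),
        stringsAsFactors = FALSE)
    }
    if (length(runs) >= 2L && nrow(W) >= 2L) {
      anova[[key]] <- rm_anova(W)
      ph <- list()
      for (a in seq_along(runs)) for (b in seq_along(runs)) {
        if (a < b) {
          ph[[paste0("run", runs[a], "_vs_run", runs[b])]] <-
            paired_t(W[, a], W[, b])
        }
      }
      posthoc[[key]] <- ph
    }
  }
  list(table = do.call(rbind, tab_rows), anova = anova, posthoc = posthoc,
       wide = wide)
}

#' Write the cohort performance table as TSV
#'
#' @param report Output of [cohort_report()] (or an `nf_cohort`).
#' @param path File path.
#' @export
write_report_tsv <- function(report, path) {
  if (inherits(report, "nf_cohort")) report <- cohort_report(report)
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Group t-map of classifier weight maps
#'
#' Trains the run-0 model of the given contrast for every subject of a seeded
#' cohort, scatters the weights into image space, and returns the one-sample
#' group t-map — the standard test of where classifier weights are
#' consistently nonzero across participants.
#'
#' @param n_subjects,base_seed,template See [cohort_configs()].
#' @param contrast One of `"R_vs_LGO"`, `"R_vs_RGO"`, `"LGO_vs_RGO"`.
#' @param config A [session_config()].
#' @param schedule A [build_schedule()].
#' @return A `tmap` (see [group_t_map()]).
#' @export
group_weight_map <- function(n_subjects, base_seed = 0L,
                             template = subject_config(),
                             contrast = "R_vs_LGO",
                             config = session_config(contrasts = contrast),
                             schedule = build_schedule()) {
  configs <- cohort_configs(n_subjects, base_seed, template)
  mask <- .session_mask(config, template$grid_dims)
  maps <- lapply(configs, function(cf) {
    run0 <- simulate_run(schedule, cf$topography, cf, 0L)
    models <- .train_models(run0, config)
    weight_map(models[[contrast]], mask)
  })
  group_t_map(maps)
}
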