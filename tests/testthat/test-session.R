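test_that("feedback controller raises, holds and resets by the block rules", {
  st <- feedback_state()
  st <- feedback_step(st, "LGO", "task", volume = 0L)
  expect_equal(st$left_arm_deg, 11)
  expect_equal(st$right_arm_deg, 0)
  st <- feedback_step(st, "LGO", "rest", volume = 1L)
  expect_equal(st$left_arm_deg, 11)
  st <- feedback_step(st, "RGO", "task", volume = 2L)
  expect_equal(st$right_arm_deg, 11)
  # a fully correct 15-volume block reaches 165 deg then resets to 0
  st <- feedback_state()
  for (v in 1:15)
    st <- feedback_step(st, "LGO", "task", is_block_end = (v == 15L),
                        volume = v)
  expect_equal(max(st$history$angle_deg), 165)
  expect_equal(st$left_arm_deg, 0)
  # the angle equals increment * correct-count at every step
  expect_equal(st$history$angle_deg, 11 * (1:15))
})

test_that("mirrored arm mapping swaps the driven arm", {
  st <- feedback_step(feedback_state(mirror = TRUE), "LGO", "task")
  expect_equal(st$right_arm_deg, 11)
  expect_equal(st$left_arm_deg, 0)
})

test_that("a perfectly separable run is decoded without error once the
           streaming detrender has seen a full task-rest cycle", {
  # The cumulative detrender absorbs the first task block's step response
  # into its fitted slope, so a handful of early task volumes are
  # unavoidably attenuated even at infinite SNR; after one full cycle the
  # fit stabilizes and decoding of noise-free data must be perfect.
  run <- boxcar_run()
  config <- session_config()
  models <- nfdecode:::.train_models(run, config)
  res <- run_realtime(run, models, config)
  lab <- res$labels
  late <- seq_along(lab) > 128   # second half of the run
  for (task in c("LGO", "RGO")) {
    hit <- res$traces[[paste0("R_vs_", task)]]$labels == task
    expect_true(all(hit[late & lab == task]))
    pair_hit <- res$traces$LGO_vs_RGO$labels == task
    expect_true(all(pair_hit[late & lab == task]))
  }
  expect_gte(res$metrics$tpv_R_vs_LGO, 75)
  expect_gte(res$metrics$tpv_R_vs_RGO, 75)
  expect_gte(res$metrics$acc_LGO_vs_RGO, 80)
  # correct task volumes raised the cued arm; block ends reset to 0
  expect_true(any(grepl("raise", res$feedback$history$action)))
  expect_equal(res$feedback$left_arm_deg, 0)
  expect_equal(res$feedback$right_arm_deg, 0)
  # a fully correct block reaches 15 x 11 = 165 degrees
  expect_equal(max(res$feedback$history$angle_deg), 165)
})

test_that("a null model predicts rest everywhere and never moves the arms", {
  run <- boxcar_run()
  null_model <- structure(list(weights = rep(0, prod(small_grid)),
                               bias = -1, positive_class = "LGO",
                               negative_class = "REST", c = 1),
                          class = "linear_svm")
  null_rgo <- null_model; null_rgo$positive_class <- "RGO"
  res <- run_realtime(run, list(R_vs_LGO = null_model, R_vs_RGO = null_rgo),
                      session_config(contrasts = c("R_vs_LGO", "R_vs_RGO")))
  expect_equal(res$metrics$tpv_R_vs_LGO, 0)
  expect_equal(res$metrics$tpv_R_vs_RGO, 0)
  expect_true(all(res$feedback$history$action %in%
                    c("hold", "hold+reset")))
  expect_equal(res$feedback$left_arm_deg, 0)
  expect_equal(res$feedback$right_arm_deg, 0)
})

test_that("model/mask feature mismatch is rejected", {
  run <- boxcar_run()
  small_model <- structure(list(weights = c(1, 2), bias = 0,
                                positive_class = "LGO",
                                negative_class = "REST", c = 1),
                           class = "linear_svm")
  expect_error(run_realtime(run, list(R_vs_LGO = small_model,
                                      R_vs_RGO = small_model)),
               "weights")
})

test_that("sessions are deterministic and track strategy bookkeeping", {
  subj <- simulate_subject(small_config(seed = 9))
  f1 <- nf_session(subj, "incremental")
  f2 <- nf_session(subj, "incremental")
  expect_equal(summary(f1), summary(f2))
  expect_identical(f1$results[[3L]]$traces$R_vs_LGO$corrected,
                   f2$results[[3L]]$traces$R_vs_LGO$corrected)
  expect_length(f1$generations, 4L)
  expect_named(f1$generations[[2L]],
               c("R_vs_LGO", "R_vs_RGO", "LGO_vs_RGO"))
  fs <- nf_session(subj, "static")
  expect_length(fs$generations, 1L)
})

test_that("run 1 is identical across strategies", {
  subj <- simulate_subject(small_config(seed = 10))
  fits <- nfdecode:::.fit_sessions(subj, c("incremental", "static"),
                                   session_config())
  expect_identical(fits$incremental$results[[1L]]$traces$R_vs_LGO$raw,
                   fits$static$results[[1L]]$traces$R_vs_LGO$raw)
  expect_identical(fits$incremental$results[[1L]]$metrics,
                   fits$static$results[[1L]]$metrics)
  # and the two fitting paths agree with independent single-strategy fits
  solo <- nf_session(subj, "static")
  expect_equal(summary(solo), summary(fits$static))
})

test_that("future runs cannot leak into earlier results", {
  subj <- simulate_subject(small_config(seed = 11))
  pert <- subj
  pert$runs[[4L]]$data <- pert$runs[[4L]]$data +
    matrix(rnorm(length(pert$runs[[4L]]$data), sd = 5),
           nrow(pert$runs[[4L]]$data))
  for (strat in c("incremental", "static")) {
    a <- nf_session(subj, strat)
    b <- nf_session(pert, strat)
    for (r in 1:2) {
      expect_identical(a$results[[r]]$traces$R_vs_LGO$corrected,
                       b$results[[r]]$traces$R_vs_LGO$corrected)
      expect_identical(a$results[[r]]$metrics, b$results[[r]]$metrics)
      expect_identical(a$results[[r]]$feedback$history,
                       b$results[[r]]$feedback$history)
    }
    expect_false(identical(a$results[[3L]]$traces$R_vs_LGO$raw,
                           b$results[[3L]]$traces$R_vs_LGO$raw))
  }
})

test_that("feedback angles equal increment times within-block correct count", {
  subj <- simulate_subject(small_config(seed = 12))
  fit <- nf_session(subj, "incremental")
  res <- fit$results[[2L]]
  vb <- nfdecode:::.volume_blocks(subj$schedule)
  hist <- res$feedback$history
  expect_equal(nrow(hist), sum(vb$condition != "REST"))
  # recompute angles from the logged actions block by block
  task_vols <- which(vb$condition != "REST")
  count <- 0
  for (i in seq_along(task_vols)) {
    v <- task_vols[i]
    if (grepl("^raise", hist$action[i])) count <- count + 1
    expect_equal(hist$angle_deg[i], 11 * count)
    if (vb$is_block_end[v]) count <- 0
  }
})

test_that("stationary subjects show no strategy gap on average", {
  # learning_rate 0 removes the nonstationarity, so incremental retraining
  # should neither help nor hurt beyond sampling noise
  diffs <- c()
  for (s in 1:12) {
    cfg <- small_config(seed = 100 + s, learning_rate = 0)
    subj <- simulate_subject(cfg)
    fits <- nfdecode:::.fit_sessions(subj, c("incremental", "static"),
                                     session_config())
    si <- summary(fits$incremental); ss <- summary(fits$static)
    diffs <- c(diffs, mean(si$tpv_R_vs_LGO[2:3] - ss$tpv_R_vs_LGO[2:3]))
  }
  expect_lt(abs(mean(diffs)), 6)
})
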