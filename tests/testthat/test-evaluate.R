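test_that("TPV counts correctly classified task volumes only", {
  labels <- c(rep("REST", 5), rep("LGO", 4), rep("REST", 3), rep("LGO", 2))
  preds <- c(rep("LGO", 5), "LGO", "REST", "LGO", "LGO", rep("REST", 3),
             "REST", "LGO")
  expect_equal(tpv(preds, labels, "LGO"), 100 * 4 / 6)
  expect_equal(tpv(labels, labels, "LGO"), 100)
  expect_error(tpv(preds, labels, "RGO"), "no volumes")
  # brute-force counting oracle on random vectors
  set.seed(51)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    lab <- sample(c("REST", "LGO", "RGO"), n, replace = TRUE)
    if (!any(lab == "LGO")) next
    pred <- sample(c("REST", "LGO", "RGO"), n, replace = TRUE)
    hits <- 0; total <- 0
    for (v in seq_len(n)) {
      if (lab[v] == "LGO") {
        total <- total + 1
        if (pred[v] == "LGO") hits <- hits + 1
      }
    }
    expect_equal(tpv(pred, lab, "LGO"), 100 * hits / total)
  }
})

test_that("pairwise accuracy ignores rest volumes", {
  labels <- c("REST", "LGO", "RGO", "LGO", "RGO", "REST")
  expect_equal(pairwise_accuracy(labels, labels), 100)
  expect_equal(pairwise_accuracy(rep("LGO", 6), labels), 50)
  set.seed(52)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    lab <- sample(c("REST", "LGO", "RGO"), n, replace = TRUE)
    if (!any(lab %in% c("LGO", "RGO"))) next
    pred <- sample(c("LGO", "RGO"), n, replace = TRUE)
    task <- lab %in% c("LGO", "RGO")
    expect_equal(pairwise_accuracy(pred, lab),
                 100 * sum(pred[task] == lab[task]) / sum(task))
  }
  expect_error(pairwise_accuracy(rep("REST", 3), rep("REST", 3)), "volumes")
})

test_that("repeated-measures ANOVA has the classical df and F", {
  set.seed(53)
  res <- rm_anova(matrix(rnorm(90), 30, 3))
  expect_equal(res$df, c(2, 58))
  # identical columns: no condition variance
  same <- matrix(rep(rnorm(6), 3), 6, 3)
  expect_equal(rm_anova(same)$statistic, 0)
  # 4 x 3 toy against a from-scratch sums-of-squares decomposition
  Y <- matrix(c(3, 5, 2, 7,
                4, 6, 4, 9,
                6, 7, 3, 8), 4, 3)
  res <- rm_anova(Y)
  n <- 4; k <- 3
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_oracle <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  expect_equal(res$statistic, F_oracle, tolerance = 1e-9)
  expect_equal(res$p,
               pf(F_oracle, k - 1, (k - 1) * (n - 1), lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("ANOVA with two conditions reduces to the squared paired t", {
  set.seed(54)
  for (i in 1:5) {
    Y <- matrix(rnorm(24), 12, 2)
    a <- rm_anova(Y)
    t <- paired_t(Y[, 1], Y[, 2])
    expect_equal(a$statistic, t$statistic^2, tolerance = 1e-9)
    expect_equal(a$p, t$p, tolerance = 1e-9)
  }
})

test_that("paired t-test matches hand computation and flags degeneracy", {
  res <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$df, 2)
  flip <- paired_t(c(1, 1, 1), c(2, 3, 4))
  expect_equal(flip$statistic, -res$statistic, tolerance = 1e-9)
  expect_equal(flip$p, res$p, tolerance = 1e-12)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
})

test_that("GLM t-maps are calibrated on null data", {
  reg <- small_topography()$regions
  reg$amplitude <- 0
  rates <- c(); all_t <- c()
  for (seed in 1:3) {
    cfg <- subject_config(seed = seed, grid_dims = small_grid, noise_sd = 1,
                          ar1 = 0, drift_slope = 0.02,
                          topography = activation_topography(reg, small_grid))
    run <- simulate_run(build_schedule(), cfg$topography, cfg, 0L)
    maps <- glm_activation(run, fwhm_mm = 0)  # unsmoothed: voxels stay iid
    crit <- qt(0.975, maps$LGO$df)
    rates <- c(rates, mean(abs(maps$LGO$t) > crit))
    all_t <- c(all_t, as.vector(maps$RGO$t))
    df_glm <- maps$RGO$df
  }
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
  ks <- ks.test(pt(all_t, df = df_glm), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("GLM localizes high-SNR activation inside the truth masks", {
  cfg <- subject_config(seed = 55, grid_dims = small_grid, noise_sd = 0.5,
                        topography = small_topography())
  run <- simulate_run(build_schedule(), cfg$topography, cfg, 0L)
  maps <- glm_activation(run)
  peak_lgo <- which.max(maps$LGO$t)
  peak_rgo <- which.max(maps$RGO$t)
  expect_true(run$truth_masks$LGO[peak_lgo])
  expect_true(run$truth_masks$RGO[peak_rgo])
  # BOTH-selective voxels cancel in the LGO > RGO contrast
  both_core <- which(run$truth_masks$LGO & run$truth_masks$RGO)
  expect_lt(median(abs(maps$LGO_gt_RGO$t[both_core])),
            median(abs(maps$LGO$t[both_core])))
  expect_error(glm_activation(run, drop_initial_volumes = 254L))
})

test_that("group t-maps match the per-voxel scalar test and flag constants", {
  set.seed(56)
  maps <- lapply(1:6, function(i) array(rnorm(24, mean = 0.5), c(4, 3, 2)))
  g <- group_t_map(maps)
  expect_equal(g$df, 5)
  M <- sapply(maps, as.vector)
  for (v in c(1, 10, 24)) {
    tt <- t.test(M[v, ])
    expect_equal(g$t[v], unname(tt$statistic), tolerance = 1e-9)
  }
  const <- lapply(1:4, function(i) array(2, c(2, 2, 2)))
  gc <- group_t_map(const)
  expect_true(all(is.infinite(gc$t)))
  expect_true(all(!gc$defined))
  expect_true(all(threshold_tmap(gc)))
  expect_error(group_t_map(const[1]), ">= 2")
})

test_that("cluster-extent filtering keeps only large components", {
  tm <- structure(list(t = array(0, c(6, 6, 1)), df = 10,
                       contrast = "x", defined = array(TRUE, c(6, 6, 1))),
                  class = "tmap")
  tm$t[1:3, 1, 1] <- 100   # 3-voxel cluster
  tm$t[5, 5, 1] <- 100     # singleton
  supra <- threshold_tmap(tm, p = 0.001, cluster_k = 2L)
  expect_equal(sum(supra), 3L)
  expect_true(all(supra[1:3, 1, 1]))
})

test_that("dice coefficient behaves on standard cases", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(dice_coefficient(a, a), 1)
  b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
  expect_equal(dice_coefficient(a, b), 0.5)
})

test_that("cohort reports summarize and test the metric table", {
  # perfect-decoder cohort: all means 100, no condition variance
  perfect <- expand.grid(subject = 0:4, run = 1:3, contrast = "R_vs_LGO",
                         strategy = "static", stringsAsFactors = FALSE)
  perfect$metric <- "TPV"; perfect$value <- 100
  rep1 <- cohort_report(perfect)
  expect_true(all(rep1$table$mean == 100))
  expect_equal(rep1$anova$R_vs_LGO.static$statistic, 0)
  # row bookkeeping on a small simulated cohort
  co <- run_cohort(n_subjects = 2, base_seed = 0,
                   template = small_config(),
                   config = session_config())
  expect_equal(nrow(co$metrics), 2 * 3 * 3 * 2)
  expect_true(all(co$metrics$value >= 0 & co$metrics$value <= 100))
  rep2 <- cohort_report(co)
  expect_equal(nrow(rep2$table), 3 * 2 * 3)
  expect_s3_class(rep2$anova$R_vs_LGO.incremental, "stat_result")
  path <- tempfile(fileext = ".tsv")
  write_report_tsv(rep2, path)
  expect_true(file.exists(path))
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(rep2$table))
  unlink(path)
})
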