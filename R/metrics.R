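#' Task predictive value
#'
#' Percentage of task-labeled volumes correctly classified as the task:
#' `100 * (# task volumes predicted as task) / (# task volumes)`. Rest
#' volumes enter neither numerator nor denominator (rest blocks are not
#' monitored during feedback).
#'
#' @param predictions Per-volume predicted labels (condition names).
#' @param labels Per-volume true condition labels.
#' @param task_condition The task condition being scored (`"LGO"` or
#'   `"RGO"`).
#' @return Percentage in `[0, 100]`.
#' @export
tpv <- function(predictions, labels, task_condition) {
  stopifnot(length(predictions) == length(labels),
            task_condition %in% c("LGO", "RGO"))
  task <- labels == task_condition
  if (!any(task)) stop("no volumes labeled ", task_condition)
  100 * sum(predictions[task] == task_condition) / sum(task)
}

#' Pairwise LGO/RGO classification accuracy
#'
#' Percentage of correctly classified LGO and RGO volumes over all LGO and
#' RGO volumes; rest volumes are ignored.
#'
#' @inheritParams tpv
#' @return Percentage in `[0, 100]`.
#' @export
pairwise_accuracy <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  task <- labels %in% c("LGO", "RGO")
  if (!any(task)) stop("no LGO/RGO volumes")
  100 * sum(predictions[task] == labels[task]) / sum(task)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F-test across conditions (here typically the three feedback
#' runs), assuming sphericity (no correction):
#' `F = MS_condition / MS_error` with `df = (k - 1, (k - 1)(n - 1))`.
#' Implemented with [stats::aov()] and an `Error(subject/condition)` stratum.
#'
#' @param values Numeric matrix, subjects x conditions; complete (no NA).
#' @return A `stat_result`: list with `statistic` (F), `df` (length 2), `p`.
#' @examples
#' set.seed(1)
#' rm_anova(matrix(rnorm(90), 30, 3))$df  # 2 58
#' @export
rm_anova <- function(values) {
  stopifnot(is.matrix(values), nrow(values) >= 2L, ncol(values) >= 2L)
  if (any(!is.finite(values))) stop("values must be complete and finite")
  n <- nrow(values); k <- ncol(values)
  d <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ condition + Error(subject / condition), data = d)
  tab <- summary(fit)[["Error: subject:condition"]][[1L]]
  Fv <- tab["condition", "F value"]
  pv <- tab["condition", "Pr(>F)"]
  if (tab["condition", "Sum Sq"] <= 1e-12 * max(sum(values^2), 1)) {
    # no condition variance (up to rounding): report F = 0 rather than the
    # 0/0 indeterminate of an exactly balanced table
    Fv <- 0
    pv <- 1
  }
  structure(list(statistic = Fv,
                 df = c(tab["condition", "Df"], tab["Residuals", "Df"]),
                 p = pv,
                 method = "one-way repeated-measures ANOVA",
                 degenerate = FALSE),
            class = "stat_result")
}

#' Paired-sample t-test
#'
#' Two-sided paired t-test `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`.
#' A zero-variance difference vector is flagged degenerate rather than
#' reported as an (infinite or undefined) statistic.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return A `stat_result`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(list(statistic = NA_real_, df = length(d) - 1L,
                          p = NA_real_, method = "paired t-test",
                          degenerate = TRUE),
                     class = "stat_result"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, method = "paired t-test",
                 degenerate = FALSE),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(x$method, ": degenerate (zero variance)\n", sep = "")
  } else if (length(x$df) == 2L) {
    cat(sprintf("%s: F(%g, %g) = %.4g, p = %.4g\n", x$method, x$df[1L],
                x$df[2L], x$statistic, x$p))
  } else {
    cat(sprintf("%s: t(%g) = %.4g, p = %.4g\n", x$method, x$df,
                x$statistic, x$p))
  }
  invisible(x)
}
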