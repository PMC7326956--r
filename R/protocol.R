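#' Conditions used in the motor-imagery block design
#'
#' `REST` is the baseline fixation condition; `LGO` and `RGO` are imagined
#' left / right hand gripping-and-opening task conditions.
#' @keywords internal
#' @name conditions
NULL

.conditions <- c("REST", "LGO", "RGO")

#' Build a block-design scan schedule
#'
#' Constructs the condition timeline of one fMRI run: `n_rest` rest blocks
#' bracketing `n_lgo + n_rgo` task blocks, every block lasting `block_s`
#' seconds sampled at one volume per `tr_s` seconds. The default arguments
#' reproduce the standard motor-imagery protocol: 9 rest and 8 task blocks
#' (4 LGO, 4 RGO) of 30 s at TR 2.0 s, i.e. 255 volumes.
#'
#' @param n_rest Number of rest blocks. Must equal `n_lgo + n_rgo + 1` so that
#'   rest blocks bracket every task block.
#' @param n_lgo,n_rgo Number of imagined left / right hand task blocks.
#' @param block_s Block duration in seconds; must be an integer multiple of
#'   `tr_s`.
#' @param tr_s Repetition time (seconds per volume).
#' @param order_rule `"alternate"` (LGO, RGO, LGO, ... truncated to the
#'   requested counts) or `"shuffled"` (seed-deterministic permutation of the
#'   task-block conditions).
#' @param seed Integer seed used only when `order_rule = "shuffled"`.
#' @param label_shift_volumes Non-negative integer: per-volume labels are
#'   delayed by this many volumes (a crude hemodynamic-lag adjustment).
#'   Default 0, so task-volume counts match the literal block bookkeeping.
#' @return A `block_schedule` object: list with `tr_s`, `blocks` (data.frame
#'   of `condition`, `duration_s`, `onset_s`), `label_shift_volumes`,
#'   `n_volumes`.
#' @examples
#' sched <- build_schedule()
#' sched$n_volumes                     # 255
#' table(labels_for(sched))
#' @export
build_schedule <- function(n_rest = 9L, n_lgo = 4L, n_rgo = 4L,
                           block_s = 30, tr_s = 2.0,
                           order_rule = c("alternate", "shuffled"),
                           seed = 0L, label_shift_volumes = 0L) {
  order_rule <- match.arg(order_rule)
  stopifnot(n_rest >= 1L, n_lgo >= 0L, n_rgo >= 0L, tr_s > 0, block_s > 0,
            label_shift_volumes >= 0L)
  vols_per_block <- block_s / tr_s
  if (abs(vols_per_block - round(vols_per_block)) > 1e-9) {
    stop("block_s (", block_s, " s) is not an integer multiple of tr_s (",
         tr_s, " s)")
  }
  if (n_rest != n_lgo + n_rgo + 1L) {
    stop("n_rest (", n_rest, ") must equal n_lgo + n_rgo + 1 (",
         n_lgo + n_rgo + 1L, ") so rest blocks bracket every task block")
  }
  task <- c(rep("LGO", n_lgo), rep("RGO", n_rgo))
  n_task <- n_lgo + n_rgo
  if (n_task > 0L) {
    if (order_rule == "alternate") {
      # strict alternation starting with LGO, truncated to the given counts
      alt <- character(0)
      l <- n_lgo; r <- n_rgo; want <- "LGO"
      while (l + r > 0L) {
        if (want == "LGO" && l > 0L) { alt <- c(alt, "LGO"); l <- l - 1L }
        else if (want == "RGO" && r > 0L) { alt <- c(alt, "RGO"); r <- r - 1L }
        else if (l > 0L) { alt <- c(alt, "LGO"); l <- l - 1L }
        else { alt <- c(alt, "RGO"); r <- r - 1L }
        want <- if (want == "LGO") "RGO" else "LGO"
      }
      task <- alt
    } else {
      task <- local({
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(as.integer(seed))
        sample(task)
      })
    }
  }
  cond <- "REST"
  for (tc in task) cond <- c(cond, tc, "REST")
  blocks <- data.frame(
    condition  = cond,
    duration_s = rep(block_s, length(cond)),
    stringsAsFactors = FALSE
  )
  blocks$onset_s <- cumsum(c(0, blocks$duration_s))[seq_len(nrow(blocks))]
  out <- structure(
    list(tr_s = tr_s, blocks = blocks,
         label_shift_volumes = as.integer(label_shift_volumes),
         n_volumes = as.integer(round(sum(blocks$duration_s) / tr_s))),
    class = "block_schedule"
  )
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.block_schedule <- function(x, ...) {
  tab <- table(factor(x$blocks$condition, levels = .conditions))
  cat("Block-design schedule: ", nrow(x$blocks), " blocks (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n",
      sep = "")
  cat("  TR ", x$tr_s, " s, ", x$n_volumes, " volumes, label shift ",
      x$label_shift_volumes, " volume(s)\n", sep = "")
  invisible(x)
}

#' Per-volume condition labels of a schedule
#'
#' Volume `v` (0-based) carries the condition of the block covering the
#' half-open interval containing time `v * tr_s`, delayed by
#' `label_shift_volumes`; trailing positions keep the final block's condition.
#'
#' @param schedule A [build_schedule()] object.
#' @return Character vector of length `schedule$n_volumes` with values in
#'   `REST`, `LGO`, `RGO`.
#' @export
labels_for <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  vols <- rep(schedule$blocks$condition,
              times = round(schedule$blocks$duration_s / schedule$tr_s))
  s <- schedule$label_shift_volumes
  if (s > 0L) {
    n <- length(vols)
    # delay by s volumes: label(v) = unshifted label(v - s); the first s
    # positions keep the first block's condition
    vols <- vols[c(rep(1L, min(s, n)), seq_len(max(n - s, 0L)))]
  }
  vols
}

#' Write / read a schedule as a BIDS-style events TSV
#'
#' Three columns: `onset_s`, `duration_s`, `condition`. TR and label shift are
#' not part of the events format and must be re-supplied on read.
#'
#' @param schedule A [build_schedule()] object.
#' @param path File path.
#' @return `write_schedule_tsv` returns `path` invisibly; `read_schedule_tsv`
#'   returns a `block_schedule`.
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "block_schedule"))
  utils::write.table(
    schedule$blocks[, c("onset_s", "duration_s", "condition")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @param tr_s,label_shift_volumes See [build_schedule()].
#' @export
read_schedule_tsv <- function(path, tr_s = 2.0, label_shift_volumes = 0L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "duration_s", "condition") %in% names(tab)))
  if (!all(tab$condition %in% .conditions))
    stop("unknown condition in ", path)
  if (any(abs(tab$duration_s / tr_s - round(tab$duration_s / tr_s)) > 1e-9))
    stop("block durations in ", path, " are not multiples of tr_s = ", tr_s)
  blocks <- data.frame(condition = tab$condition,
                       duration_s = tab$duration_s,
                       onset_s = tab$onset_s,
                       stringsAsFactors = FALSE)
  structure(
    list(tr_s = tr_s, blocks = blocks,
         label_shift_volumes = as.integer(label_shift_volumes),
         n_volumes = as.integer(round(sum(blocks$duration_s) / tr_s))),
    class = "block_schedule"
  )
}

# Block index (1-based into schedule$blocks) covering each volume, and whether
# each volume is the last one of its block. Used by the real-time loop.
.volume_blocks <- function(schedule) {
  reps <- round(schedule$blocks$duration_s / schedule$tr_s)
  idx <- rep(seq_along(reps), times = reps)
  last <- c(idx[-1L] != idx[-length(idx)], TRUE)
  list(block = idx, is_block_end = last,
       condition = schedule$blocks$condition[idx])
}
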