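#' Robot-arm feedback controller
#'
#' Emulates the feedback rule of robot-mediated motor-imagery neurofeedback:
#' each task volume classified as task raises the arm matching the cued hand
#' by a fixed increment (default 11 degrees); an incorrect (rest)
#' classification leaves the arms unchanged; at the end of a task block the
#' cued arm resets to its downward position, so angles are 0 at the start of
#' every block. The LGO cue drives the left arm and RGO the right; set
#' `mirror = TRUE` to swap the mapping.
#'
#' @param increment_deg Degrees added per correct task classification.
#' @param mirror Logical; swap the cue-to-arm mapping.
#' @return A `feedback_state`: `left_arm_deg`, `right_arm_deg`,
#'   `increment_deg`, `mirror`, and a `history` data.frame of
#'   `(volume, arm, action)`.
#' @export
feedback_state <- function(increment_deg = 11, mirror = FALSE) {
  stopifnot(increment_deg > 0)
  structure(list(left_arm_deg = 0, right_arm_deg = 0,
                 increment_deg = increment_deg, mirror = mirror,
                 history = data.frame(volume = integer(0),
                                      arm = character(0),
                                      action = character(0),
                                      angle_deg = numeric(0),
                                      stringsAsFactors = FALSE)),
            class = "feedback_state")
}

#' @rdname feedback_state
#' @param state A `feedback_state`.
#' @param cue The cued task condition, `"LGO"` or `"RGO"`.
#' @param predicted `"task"` or `"rest"`: the classifier's call for this
#'   volume.
#' @param is_block_end Logical; reset the cued arm to 0 after the update.
#' @param volume Optional volume index recorded in the history.
#' @return `feedback_step`: the updated `feedback_state`.
#' @export
feedback_step <- function(state, cue, predicted, is_block_end = FALSE,
                          volume = NA_integer_) {
  stopifnot(inherits(state, "feedback_state"),
            cue %in% c("LGO", "RGO"), predicted %in% c("task", "rest"))
  arm <- if (xor(cue == "LGO", state$mirror)) "left" else "right"
  field <- paste0(arm, "_arm_deg")
  action <- "hold"
  if (predicted == "task") {
    state[[field]] <- state[[field]] + state$increment_deg
    action <- "raise"
  }
  angle <- state[[field]]
  if (is_block_end) {
    state[[field]] <- 0
    action <- paste0(action, "+reset")
  }
  state$history <- rbind(state$history,
                         data.frame(volume = as.integer(volume), arm = arm,
                                    action = action, angle_deg = angle,
                                    stringsAsFactors = FALSE))
  state
}

#' @export
print.feedback_state <- function(x, ...) {
  cat("Feedback state: left ", x$left_arm_deg, " deg, right ",
      x$right_arm_deg, " deg (increment ", x$increment_deg, " deg, ",
      nrow(x$history), " events)\n", sep = "")
  invisible(x)
}
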