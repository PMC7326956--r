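#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used throughout neuroimaging: a response gamma density
#' (shape 6, scale 1 s; mode 5 s) minus an undershoot gamma (shape 16,
#' scale 1 s; mode 15 s) weighted 1/6, rescaled to unit peak. Task regressors
#' are built by convolving condition boxcars with this impulse response.
#'
#' @param tr_s Sampling interval in seconds (one sample per volume).
#' @param duration_s Length of the sampled response in seconds (>= 30 so the
#'   undershoot is covered).
#' @return Numeric vector: the HRF sampled at `0, tr_s, 2*tr_s, ...` up to
#'   `duration_s`, with unit peak.
#' @examples
#' h <- canonical_hrf(2.0, 32)
#' plot(seq(0, 32, by = 2), h, type = "b", xlab = "s", ylab = "HRF")
#' @export
canonical_hrf <- function(tr_s = 2.0, duration_s = 32) {
  stopifnot(tr_s > 0, duration_s >= 30)
  t <- seq(0, duration_s, by = tr_s)
  h <- .hrf_shape(t)
  # unit peak taken from a dense evaluation so it is independent of tr_s
  peak <- max(.hrf_shape(seq(0, duration_s, by = 0.01)))
  h / peak
}

# unnormalized double-gamma shape
.hrf_shape <- function(t) {
  stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
}

# Condition regressor: per-volume boxcar (1 where label == condition)
# convolved with the canonical HRF, truncated to the run length.
.condition_regressor <- function(labels, condition, tr_s) {
  box <- as.numeric(labels == condition)
  h <- canonical_hrf(tr_s, max(32, tr_s * 16))
  n <- length(box)
  full <- stats::convolve(box, rev(h), type = "open")
  full[seq_len(n)]
}
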