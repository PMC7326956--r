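#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with
#' `sigma_voxels = fwhm_mm / (2 sqrt(2 log 2) * voxel_mm)` per axis and
#' half-sample reflection boundary handling, which conserves total mass on
#' the small grids used here. `smooth_volume` smooths one 3D array;
#' `smooth_run` smooths every volume of a voxels-x-volumes matrix (smoothing
#' uses only the current volume, so smoothing a run up front is identical to
#' smoothing volume by volume in the real-time loop).
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Kernel full width at half maximum in mm (default 8).
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm = 8, voxel_mm = 3) {
  stopifnot(length(dim(volume)) == 3L, fwhm_mm > 0, voxel_mm > 0)
  ks <- .smoothing_mats(dim(volume), fwhm_mm, voxel_mm)
  .smooth4d(array(volume, c(dim(volume), 1L)), ks)[, , , 1L]
}

#' @rdname smooth_volume
#' @param run A `synthetic_run`, or a voxels-x-volumes matrix with `grid_dims`
#'   supplied.
#' @param grid_dims Grid dimensions when `run` is a bare matrix.
#' @export
smooth_run <- function(run, fwhm_mm = 8, voxel_mm = 3, grid_dims = NULL) {
  if (inherits(run, "synthetic_run")) {
    ks <- .smoothing_mats(run$grid_dims, fwhm_mm, voxel_mm)
    arr <- array(run$data, c(run$grid_dims, ncol(run$data)))
    out <- run
    out$data <- matrix(.smooth4d(arr, ks), nrow(run$data), ncol(run$data))
    return(out)
  }
  stopifnot(is.matrix(run), !is.null(grid_dims),
            prod(grid_dims) == nrow(run))
  ks <- .smoothing_mats(grid_dims, fwhm_mm, voxel_mm)
  arr <- array(run, c(grid_dims, ncol(run)))
  matrix(.smooth4d(arr, ks), nrow(run), ncol(run))
}

# One banded convolution matrix per axis. Boundary handling is half-sample
# reflection (... c b a | a b c ...), which conserves total mass for a
# unit-sum symmetric kernel.
.smoothing_mats <- function(grid_dims, fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_mm)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  lapply(grid_dims, function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (o in -r:r) {
        s <- i + o
        while (s < 1L || s > n) {
          if (s < 1L) s <- 1L - s
          if (s > n) s <- 2L * n + 1L - s
        }
        K[i, s] <- K[i, s] + w[o + r + 1L]
      }
    }
    K
  })
}

# separable smoothing of a 4D array (x, y, z, t) via per-axis matmuls
.smooth4d <- function(arr, ks) {
  d <- dim(arr)
  m <- ks[[1L]] %*% matrix(arr, d[1], prod(d[-1]))
  arr <- array(m, d)
  arr <- aperm(arr, c(2L, 1L, 3L, 4L))
  m <- ks[[2L]] %*% matrix(arr, d[2], prod(d[-2]))
  arr <- aperm(array(m, d[c(2L, 1L, 3L, 4L)]), c(2L, 1L, 3L, 4L))
  arr <- aperm(arr, c(3L, 1L, 2L, 4L))
  m <- ks[[3L]] %*% matrix(arr, d[3], prod(d[-3]))
  aperm(array(m, d[c(3L, 1L, 2L, 4L)]), c(2L, 3L, 1L, 4L))
}

#' Extract masked voxel time series
#'
#' Rows are the masked voxels in fixed column-major grid order (recorded in
#' the `"mask_index"` attribute); columns are volumes. Smoothing precedes
#' masking in the pipeline.
#'
#' @param run A `synthetic_run` or a voxels-x-volumes matrix.
#' @param mask Logical 3D array (or vector) with at least one `TRUE` voxel.
#' @return features x volumes matrix with attribute `mask_index`.
#' @export
apply_mask <- function(run, mask) {
  data <- if (inherits(run, "synthetic_run")) run$data else run
  stopifnot(is.matrix(data))
  idx <- which(as.vector(mask))
  if (length(as.vector(mask)) != nrow(data))
    stop("mask has ", length(as.vector(mask)), " voxels but data has ",
         nrow(data), " rows")
  if (length(idx) == 0L) stop("mask selects no voxels")
  out <- data[idx, , drop = FALSE]
  attr(out, "mask_index") <- idx
  out
}

#' Streaming per-voxel linear detrending
#'
#' `detrend_state` initializes constant-memory running sums
#' (`n, sum t, sum t^2, sum y, sum t*y` per voxel, `t` the 1-based volume
#' index); `detrend_update` ingests one volume and emits the current
#' residuals of the cumulative ordinary-least-squares line fit per voxel.
#' For `n <= 2` the residual is exactly 0 (a line interpolates two points),
#' and for every later `n` the emitted residual equals the step-`n` residual
#' of a batch OLS fit to all `n` samples seen so far.
#'
#' @param n_voxels Number of voxels (features) tracked.
#' @return `detrend_state`: a list of running sums.
#' @export
detrend_state <- function(n_voxels) {
  stopifnot(n_voxels >= 1L)
  structure(list(n = 0L, st = 0, stt = 0,
                 sy = numeric(n_voxels), sty = numeric(n_voxels),
                 n_voxels = as.integer(n_voxels)),
            class = "detrend_state")
}

#' @rdname detrend_state
#' @param state A `detrend_state`.
#' @param y_t Numeric vector of length `n_voxels`: the new volume's values.
#' @return `detrend_update`: list with the updated `state` and `residuals`.
#' @export
detrend_update <- function(state, y_t) {
  stopifnot(inherits(state, "detrend_state"),
            length(y_t) == state$n_voxels)
  if (any(!is.finite(y_t))) stop("non-finite values in detrend input")
  n <- state$n + 1L
  t <- as.numeric(n)
  state$n <- n
  state$st <- state$st + t
  state$stt <- state$stt + t * t
  state$sy <- state$sy + y_t
  state$sty <- state$sty + t * y_t
  if (n <= 2L) {
    res <- numeric(state$n_voxels)
  } else {
    denom <- n * state$stt - state$st^2
    b <- (n * state$sty - state$st * state$sy) / denom
    a <- (state$sy - b * state$st) / n
    res <- y_t - (a + b * t)
  }
  list(state = state, residuals = res)
}

#' Batch linear detrending
#'
#' Residuals of a single OLS line (intercept + slope on the 1-based index)
#' fit over the full series; the offline analogue of the streaming detrender,
#' used to prepare training data.
#'
#' @param series Numeric vector (length >= 3) or a features x volumes matrix
#'   (each row detrended independently).
#' @return Residuals, same shape as the input.
#' @export
batch_detrend <- function(series) {
  if (is.matrix(series)) {
    nt <- ncol(series)
    if (nt < 3L) stop("need at least 3 volumes to detrend")
    X <- cbind(1, seq_len(nt))
    beta <- series %*% X %*% solve(crossprod(X))
    return(series - beta %*% t(X))
  }
  if (length(series) < 3L) stop("need at least 3 samples to detrend")
  t <- seq_along(series)
  stats::lm.fit(cbind(1, t), series)$residuals
}
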