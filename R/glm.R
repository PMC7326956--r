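#' GLM activation maps for one run
#'
#' Mass-univariate OLS on a design of intercept, linear drift, and one
#' boxcar-convolved-with-HRF regressor per task condition. Returns per-voxel
#' t-maps for each condition against baseline and the LGO > RGO contrast,
#' with `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` and
#' `df = volumes - rank(X)`. By default the run is smoothed first and the
#' first 5 volumes are discarded (the usual guard against initial signal
#' inhomogeneity in offline analysis).
#'
#' @param run A `synthetic_run`.
#' @param schedule Block schedule; defaults to the run's own.
#' @param fwhm_mm,voxel_mm Smoothing parameters; `fwhm_mm = 0` skips
#'   smoothing.
#' @param drop_initial_volumes Volumes discarded before fitting (default 5).
#' @return Named list of `tmap` objects (`LGO`, `RGO`, `LGO_gt_RGO`), each a
#'   list with `t` (3D array), `df`, `contrast`, `defined` (logical array).
#' @export
glm_activation <- function(run, schedule = run$schedule, fwhm_mm = 8,
                           voxel_mm = 3, drop_initial_volumes = 5L) {
  stopifnot(inherits(run, "synthetic_run"))
  data <- if (fwhm_mm > 0)
    smooth_run(run, fwhm_mm, voxel_mm)$data else run$data
  keep <- seq_len(ncol(data)) > drop_initial_volumes
  data <- data[, keep, drop = FALSE]
  raw_labels <- rep(schedule$blocks$condition,
                    times = round(schedule$blocks$duration_s / schedule$tr_s))
  nt <- sum(keep)
  X <- cbind(intercept = 1,
             drift = scale(seq_len(ncol(run$data))[keep])[, 1L],
             LGO = .condition_regressor(raw_labels, "LGO",
                                        schedule$tr_s)[keep],
             RGO = .condition_regressor(raw_labels, "RGO",
                                        schedule$tr_s)[keep])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  df <- nt - qx$rank
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- t(qr.coef(qx, t(data)))          # voxels x 4
  fitted <- beta %*% t(X)
  sigma2 <- rowSums((data - fitted)^2) / df

  contrasts <- list(LGO = c(0, 0, 1, 0), RGO = c(0, 0, 0, 1),
                    LGO_gt_RGO = c(0, 0, 1, -1))
  out <- lapply(names(contrasts), function(nm) {
    cv <- contrasts[[nm]]
    se2 <- sigma2 * as.numeric(t(cv) %*% XtXinv %*% cv)
    tval <- as.numeric(beta %*% cv) / sqrt(se2)
    defined <- se2 > 0 & is.finite(tval)
    tval[!defined] <- 0
    structure(list(t = array(tval, run$grid_dims), df = df, contrast = nm,
                   defined = array(defined, run$grid_dims)),
              class = "tmap")
  })
  names(out) <- names(contrasts)
  out
}

#' @export
print.tmap <- function(x, ...) {
  cat("t-map (", x$contrast, "): df = ", x$df, ", max |t| = ",
      signif(max(abs(x$t)), 4), "\n", sep = "")
  invisible(x)
}

#' Group-level one-sample t-map
#'
#' Per-voxel one-sample t-test of subject maps against 0 (`df = n - 1`).
#' Voxels with zero between-subject variance are flagged undefined.
#'
#' @param subject_maps List of >= 2 numeric 3D arrays on the same grid.
#' @return A `tmap` with `n` recorded.
#' @export
group_t_map <- function(subject_maps) {
  stopifnot(is.list(subject_maps), length(subject_maps) >= 2L)
  d <- dim(subject_maps[[1L]])
  for (m in subject_maps) stopifnot(identical(dim(m), d))
  n <- length(subject_maps)
  M <- vapply(subject_maps, as.vector, numeric(prod(d)))
  mu <- rowMeans(M)
  sdv <- sqrt(rowSums((M - mu)^2) / (n - 1L))
  tval <- mu / (sdv / sqrt(n))
  defined <- sdv > 0
  tval[!defined & mu > 0] <- Inf
  tval[!defined & mu < 0] <- -Inf
  tval[!defined & mu == 0] <- 0
  structure(list(t = array(tval, d), df = n - 1L, contrast = "group",
                 defined = array(defined, d), n = n),
            class = "tmap")
}

#' Threshold a t-map
#'
#' Two-sided voxelwise threshold at significance `p` (default 0.001, the
#' usual cluster-defining threshold), with an optional cluster-extent filter
#' keeping only 6-connected components of at least `cluster_k` voxels.
#' Undefined voxels with infinite t (zero variance, nonzero mean) count as
#' suprathreshold.
#'
#' @param tmap A `tmap`.
#' @param p Voxelwise two-sided significance level.
#' @param cluster_k Minimum cluster extent in voxels (0 disables).
#' @return Logical 3D array of suprathreshold voxels.
#' @export
threshold_tmap <- function(tmap, p = 0.001, cluster_k = 0L) {
  stopifnot(inherits(tmap, "tmap"), p > 0, p < 1)
  crit <- stats::qt(1 - p / 2, df = tmap$df)
  supra <- abs(tmap$t) > crit
  if (cluster_k > 0L) supra <- .cluster_filter(supra, cluster_k)
  supra
}

# keep only 6-connected components with >= k voxels (BFS flood fill)
.cluster_filter <- function(supra, k) {
  d <- dim(supra)
  lab <- array(0L, d)
  nxt <- 0L
  keep <- array(FALSE, d)
  idx <- which(supra)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  coords <- arrayInd(idx, d)
  lookup <- array(0L, d); lookup[idx] <- seq_along(idx)
  for (start in seq_along(idx)) {
    if (lab[idx[start]] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    members <- integer(0)
    lab[idx[start]] <- nxt
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, cur)
      cc <- coords[cur, ]
      for (o in seq_len(6L)) {
        nb <- cc + offs[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- lookup[nb[1L], nb[2L], nb[3L]]
        if (li > 0L && lab[idx[li]] == 0L) {
          lab[idx[li]] <- nxt
          queue <- c(queue, li)
        }
      }
    }
    if (length(members) >= k) keep[idx[members]] <- TRUE
  }
  keep
}

#' Dice overlap coefficient
#'
#' `2 |A & B| / (|A| + |B|)` for two logical masks of equal shape.
#'
#' @param a,b Logical arrays.
#' @return Numeric in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Export a t-map or mask to NIfTI
#'
#' @param x A `tmap` or a numeric/logical 3D array.
#' @param path Output path.
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @export
write_map_nifti <- function(x, path, voxel_mm = 3) {
  arr <- if (inherits(x, "tmap")) x$t else x
  storage.mode(arr) <- "double"
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(voxel_mm, 3)), path)
  invisible(path)
}
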