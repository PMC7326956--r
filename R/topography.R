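#' Activation topography: spherical regions on a voxel grid
#'
#' A topography is a set of spherical active regions, each with a center,
#' radius (voxels), response amplitude (signal units, i.e. percent of a
#' baseline of 100), a condition selectivity (`LGO`, `RGO`, or `BOTH`), and a
#' relevance tag. `relevant` regions are genuinely task-related and persist
#' across feedback runs (their radius contracts as the subject's activation
#' becomes more focal); `transient` regions reflect the widespread activity of
#' early learning and their amplitude decays run by run.
#'
#' @param regions data.frame with columns `cx, cy, cz` (1-based voxel
#'   coordinates), `radius`, `amplitude`, `selectivity`, `relevance`.
#' @param grid_dims Integer vector of 3 grid dimensions.
#' @return An `activation_topography` object.
#' @export
activation_topography <- function(regions, grid_dims) {
  stopifnot(is.data.frame(regions),
            all(c("cx", "cy", "cz", "radius", "amplitude",
                  "selectivity", "relevance") %in% names(regions)),
            length(grid_dims) == 3L)
  stopifnot(all(regions$radius >= 1), all(regions$amplitude >= 0),
            all(regions$selectivity %in% c("LGO", "RGO", "BOTH")),
            all(regions$relevance %in% c("relevant", "transient")))
  centers <- as.matrix(regions[, c("cx", "cy", "cz")])
  lo <- sweep(centers, 2, rep(1, 3)) - regions$radius
  hi <- sweep(centers, 2, grid_dims) + regions$radius
  if (any(lo < 0) || any(hi > 0))
    stop("region sphere extends outside the grid")
  structure(list(regions = regions, grid_dims = as.integer(grid_dims)),
            class = "activation_topography")
}

#' Default motor-imagery topography
#'
#' Minimal structure emulating a motor-imagery session on a small grid: two
#' contralateral hand-area regions (one LGO-selective, one RGO-selective), a
#' medial SMA-like region responding to both tasks, and four transient
#' bilateral regions that model the widespread activity of run 0 / early
#' feedback and fade with learning.
#'
#' @param grid_dims Grid dimensions; each must be >= 8.
#' @return An [activation_topography()].
#' @export
default_topography <- function(grid_dims = c(24L, 24L, 12L)) {
  stopifnot(all(grid_dims >= 8L))
  g <- grid_dims
  q1 <- round(g[1] / 4); q3 <- g[1] - q1
  mid <- round(g / 2)
  regions <- data.frame(
    name        = c("hand_R", "hand_L", "SMA",
                    "trans1", "trans2", "trans3", "trans4"),
    # right-hemisphere hand area responds to left-hand imagery and vice versa
    cx          = c(q3, q1, mid[1], q1, q3, q1, q3),
    cy          = c(mid[2], mid[2], mid[2] + 2, q1, q1, g[2] - q1, g[2] - q1),
    cz          = c(mid[3] + 1, mid[3] + 1, mid[3] + 1,
                    mid[3] - 2, mid[3] - 2, mid[3] - 2, mid[3] - 2),
    radius      = c(4, 4, 3, 3, 3, 3, 3),
    amplitude   = c(2.0, 2.0, 1.5, 1.5, 1.5, 1.5, 1.5),
    selectivity = c("LGO", "RGO", "BOTH", "BOTH", "BOTH", "BOTH", "BOTH"),
    relevance   = c("relevant", "relevant", "relevant",
                    "transient", "transient", "transient", "transient"),
    stringsAsFactors = FALSE
  )
  activation_topography(regions, grid_dims)
}

#' Evolve a topography across feedback runs
#'
#' Models the learning-driven shift from widespread to focal activation:
#' transient-region amplitudes decay by `(1 - learning_rate)^run_index` and
#' relevant-region radii contract by `(1 - learning_rate / 2)^run_index`
#' (floored at 1 voxel, amplitude unchanged). Run 0 returns the base
#' topography unchanged.
#'
#' @param base An [activation_topography()].
#' @param run_index Run number in `0:3` (0 = pre-feedback training run).
#' @param learning_rate Fraction in `[0, 1]` controlling the per-run decay.
#' @return An `activation_topography` for that run.
#' @export
topography_for_run <- function(base, run_index, learning_rate) {
  stopifnot(inherits(base, "activation_topography"),
            run_index %in% 0:3, learning_rate >= 0, learning_rate <= 1)
  reg <- base$regions
  tr_ix <- reg$relevance == "transient"
  reg$amplitude[tr_ix] <- reg$amplitude[tr_ix] * (1 - learning_rate)^run_index
  rel <- reg$relevance == "relevant"
  reg$radius[rel] <- pmax(1, reg$radius[rel] * (1 - learning_rate / 2)^run_index)
  activation_topography(reg, base$grid_dims)
}

# logical 3D array of voxels inside one sphere
.sphere_mask <- function(grid_dims, center, radius) {
  g <- grid_dims
  dx <- (seq_len(g[1]) - center[1])^2
  dy <- (seq_len(g[2]) - center[2])^2
  dz <- (seq_len(g[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, "+"), dz, "+")
  array(d2 <= radius^2, dim = g)
}

# per-condition truth masks: voxels of regions with positive amplitude whose
# selectivity includes the condition
.truth_masks <- function(topo) {
  g <- topo$grid_dims
  out <- list(LGO = array(FALSE, g), RGO = array(FALSE, g))
  reg <- topo$regions
  for (i in seq_len(nrow(reg))) {
    if (reg$amplitude[i] <= 0) next
    m <- .sphere_mask(g, c(reg$cx[i], reg$cy[i], reg$cz[i]), reg$radius[i])
    if (reg$selectivity[i] %in% c("LGO", "BOTH")) out$LGO <- out$LGO | m
    if (reg$selectivity[i] %in% c("RGO", "BOTH")) out$RGO <- out$RGO | m
  }
  out
}
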