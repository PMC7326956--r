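# Small-scale fixtures used across tests. Unit tests run on a reduced grid
# (10 x 10 x 8) with a correspondingly shrunken topography so the full
# pipeline stays fast; acceptance tests use the default scale.

small_grid <- c(10L, 10L, 8L)

small_topography <- function(grid_dims = small_grid) {
  regions <- data.frame(
    name        = c("hand_R", "hand_L", "SMA", "trans1", "trans2"),
    cx          = c(8, 3, 5, 3, 8),
    cy          = c(5, 5, 7, 3, 3),
    cz          = c(5, 5, 5, 3, 3),
    radius      = c(2, 2, 2, 2, 2),
    amplitude   = c(2.0, 2.0, 1.5, 1.5, 1.5),
    selectivity = c("LGO", "RGO", "BOTH", "BOTH", "BOTH"),
    relevance   = c("relevant", "relevant", "relevant",
                    "transient", "transient"),
    stringsAsFactors = FALSE
  )
  activation_topography(regions, grid_dims)
}

small_config <- function(seed = 1L, ...) {
  subject_config(seed = seed, grid_dims = small_grid,
                 topography = small_topography(), ...)
}

# a run whose signal follows the condition boxcar exactly (no HRF lag, no
# noise): trivially separable, used for perfect-decoder checks
boxcar_run <- function(amplitude = 10, baseline = 100,
                       schedule = build_schedule(), grid_dims = small_grid) {
  labels <- labels_for(schedule)
  nv <- prod(grid_dims)
  data <- matrix(baseline, nv, schedule$n_volumes)
  lgo_mask <- as.vector(nfdecode:::.sphere_mask(grid_dims, c(8, 5, 5), 2))
  rgo_mask <- as.vector(nfdecode:::.sphere_mask(grid_dims, c(3, 5, 5), 2))
  data[lgo_mask, labels == "LGO"] <- baseline + amplitude
  data[rgo_mask, labels == "RGO"] <- baseline + amplitude
  truth <- list(LGO = array(lgo_mask, grid_dims),
                RGO = array(rgo_mask, grid_dims))
  structure(list(run_index = 0L, data = data, schedule = schedule,
                 grid_dims = grid_dims, truth_masks = truth,
                 topography = NULL),
            class = "synthetic_run")
}

expect_stat_close <- function(x, y, tol = 1e-8) {
  expect_true(max(abs(x - y)) < tol)
}
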