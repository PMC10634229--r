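# Small in-code fixtures shared across test files.

tiny_grid <- function(shape = c(10, 10, 10), spacing = 2.0) {
  grid_spec(shape, spacing)
}

# a bias map from explicit striosome fractions on the first voxels of a grid
bias_from_scores <- function(scores, grid = tiny_grid()) {
  p_str <- array(0, grid$shape)
  p_str[seq_along(scores)] <- scores
  p_mat <- array(0, grid$shape)
  p_mat[seq_along(scores)] <- 1 - scores
  memb <- array(FALSE, grid$shape)
  memb[seq_along(scores)] <- TRUE
  compute_bias_map(scalar_volume(grid, p_str), scalar_volume(grid, p_mat),
                   binary_mask(grid, memb))
}

box_mask <- function(grid, i, j, k) {
  memb <- array(FALSE, grid$shape)
  memb[i, j, k] <- TRUE
  binary_mask(grid, memb)
}

# minimal thalamic record table so stage_stats can run on parcel-only tests
fabricate_records <- function() {
  set.seed(1)
  expand.grid(subject = paste0("S", 1:4),
              hemisphere = c("left", "right"),
              nucleus = c("CM", "AV"),
              stringsAsFactors = FALSE) |>
    transform(n_str = 10L, n_mat = 10L,
              matrix_fraction = runif(16, 0.4, 0.6))
}

# one cached noiseless subject and one noisy subject at 2 mm (cheap, reused)
local_phantom <- local({
  cache <- new.env()
  function(noise = TRUE) {
    key <- if (noise) "noisy" else "clean"
    if (is.null(cache[[key]])) {
      p <- if (noise) cohort_params(n_subjects = 1, spacing = 2.0, seed = 42)
      else cohort_params(n_subjects = 1, spacing = 2.0, seed = 42,
                         noise_sd = 0, share_dispersion = 0,
                         asymmetry_delta = 0)
      cache[[key]] <- generate_subject(p, 1L)
    }
    cache[[key]]
  }
})
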