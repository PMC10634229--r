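test_that("bias map is the normalized fraction and scale-invariant", {
  b <- bias_from_scores(c(0.8, 0.5, 1.0))
  got <- b$f[b$support$membership]
  expect_equal(got, c(0.8, 0.5, 1.0))

  # scale invariance: multiply both maps by c > 0
  g <- tiny_grid()
  ps <- array(0, g$shape); pm <- array(0, g$shape)
  set.seed(4)
  ps[1:50] <- runif(50); pm[1:50] <- runif(50)
  memb <- array(FALSE, g$shape); memb[1:50] <- TRUE
  m <- binary_mask(g, memb)
  b1 <- compute_bias_map(scalar_volume(g, ps), scalar_volume(g, pm), m)
  b2 <- compute_bias_map(scalar_volume(g, 7.3 * ps),
                         scalar_volume(g, 7.3 * pm), m)
  expect_equal(b1$f, b2$f)

  # zero-sum voxels are dropped and counted
  ps[3] <- 0; pm[3] <- 0
  b3 <- compute_bias_map(scalar_volume(g, ps), scalar_volume(g, pm), m)
  expect_equal(b3$n_dropped, 1L)
  expect_false(b3$support$membership[3])
})

test_that("select_top_voxels honors sd and fixed_n rules", {
  # all equal scores, sd mode, strict inequality -> empty
  b <- bias_from_scores(rep(0.7, 8))
  expect_equal(n_voxels(select_top_voxels(b, "striosome", "sd")), 0)

  # nine zeros and a one: cutoff = 0.1 + 1.5 * sd ~ 0.574 -> only the 1
  b2 <- bias_from_scores(c(rep(0, 9), 1))
  sel <- select_top_voxels(b2, "striosome", "sd", param = 1.5)
  expect_equal(which(sel$membership), 10L)

  # fixed_n argmax/argmin
  b3 <- bias_from_scores(c(0.9, 0.8, 0.2, 0.1))
  expect_equal(which(select_top_voxels(b3, "striosome", "fixed_n",
                                       param = 1)$membership), 1L)
  expect_equal(which(select_top_voxels(b3, "matrix", "fixed_n",
                                       param = 1)$membership), 4L)

  # ties broken by ascending linear index
  b4 <- bias_from_scores(c(0.5, 0.9, 0.9, 0.1))
  expect_equal(which(select_top_voxels(b4, "striosome", "fixed_n",
                                       param = 1)$membership), 2L)
  expect_error(select_top_voxels(b4, "striosome", "fixed_n", param = 99),
               "exceeds")

  # fixed_n selection equals a full sort oracle on random maps
  set.seed(11)
  for (rep in 1:20) {
    sc <- runif(60)
    bb <- bias_from_scores(sc)
    N <- sample(1:25, 1)
    sel <- which(select_top_voxels(bb, "striosome", "fixed_n",
                                   param = N)$membership)
    oracle <- order(-sc, seq_along(sc))[1:N]
    expect_setequal(sel, oracle)
  }
})

test_that("equal-volume masks are disjoint with equal counts, always", {
  b <- bias_from_scores(seq(0.05, 0.95, length.out = 10))
  cm <- make_equal_volume_masks(b, N = 3)
  expect_equal(which(cm$striosome_like$membership), 8:10)
  expect_equal(which(cm$matrix_like$membership), 1:3)

  # full bipartition of a two-valued map
  b2 <- bias_from_scores(rep(c(0.2, 0.8), each = 5))
  cm2 <- make_equal_volume_masks(b2, N = 5)
  expect_equal(which(cm2$matrix_like$membership), 1:5)
  expect_equal(which(cm2$striosome_like$membership), 6:10)

  # property: disjoint equal counts on 100 random maps (incl. heavy ties)
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    sc <- if (rep %% 3 == 0) sample(c(0.3, 0.5, 0.7), n, replace = TRUE)
          else runif(n)
    bb <- bias_from_scores(sc)
    N <- sample(seq_len(n %/% 2), 1)
    cm3 <- make_equal_volume_masks(bb, N = N)
    expect_equal(n_voxels(cm3$striosome_like), N)
    expect_equal(n_voxels(cm3$matrix_like), N)
    expect_equal(sum(cm3$striosome_like$membership &
                       cm3$matrix_like$membership), 0L)
  }
  expect_error(make_equal_volume_masks(b, N = 6), "exceeds")
})

test_that("noiseless phantoms yield exactly the extreme-g voxels", {
  ph <- local_phantom(noise = FALSE)
  h <- "left"
  bias <- compute_bias_map(ph$striatal_ctt[[h]]$P_str,
                           ph$striatal_ctt[[h]]$P_mat, ph$striatum[[h]])
  cm <- make_equal_volume_masks(bias, N = 50)
  sup <- which(bias$support$membership)
  gv <- ph$g[[h]]$values[sup]
  oracle_str <- sup[order(-gv, sup)][1:50]
  expect_setequal(which(cm$striosome_like$membership), oracle_str)
  oracle_mat <- sup[order(gv, sup)][1:50]
  expect_setequal(which(cm$matrix_like$membership), oracle_mat)
})

test_that("jitter displaces by the enumerated expectation and is seeded", {
  g <- grid_spec(c(30, 30, 30), 2.0)
  memb <- array(FALSE, g$shape)
  memb[8:23, 8:23, 8:23] <- TRUE
  bounds <- binary_mask(g, array(TRUE, g$shape))
  mask <- binary_mask(g, memb)

  j0 <- jitter_mask(mask, bounds, max_shift = 0L, seed = 1)
  expect_identical(j0$mask$membership, mask$membership)
  expect_equal(j0$mean_displacement_voxels, 0)

  j1 <- jitter_mask(mask, bounds, max_shift = 3L, seed = 5)
  j2 <- jitter_mask(mask, bounds, max_shift = 3L, seed = 5)
  expect_identical(j1$mask$membership, j2$mask$membership)
  expect_equal(j1$mean_displacement_voxels, j2$mean_displacement_voxels)

  # expectation oracle: mean Euclidean norm over the 7^3 offset lattice
  off <- expand.grid(-3:3, -3:3, -3:3)
  expected <- mean(sqrt(rowSums(off^2)))  # ~3.3329
  expect_lt(abs(j1$mean_displacement_voxels - expected), 0.07)
  expect_lte(n_voxels(j1$mask), n_voxels(mask))  # dedup may shrink
})

test_that("seed_region_bias counts suprathreshold shares", {
  g <- tiny_grid()
  ps <- array(0, g$shape); pm <- array(0, g$shape)
  shares <- c(0.9, 0.5, 0.95, 0.9, 0.88, 0.9, 0.9, 0.92, 0.91, 0.05)
  ps[1:10] <- shares; pm[1:10] <- 1 - shares
  region <- box_mask(g, 1:10, 1, 1)
  r <- seed_region_bias(scalar_volume(g, ps), scalar_volume(g, pm), region,
                        supra = 0.87)
  expect_equal(r$frac_striosome_favoring, 0.8)
  expect_equal(r$frac_matrix_favoring, 0.1)
  expect_equal(r$mean_p_striosome, mean(shares))
  expect_error(seed_region_bias(scalar_volume(g, ps), scalar_volume(g, pm),
                                binary_mask(g, array(FALSE, g$shape))),
               "empty")
})

test_that("jittered target masks degrade seed-region bias", {
  ph <- local_phantom(noise = FALSE)
  h <- "left"
  bias <- compute_bias_map(ph$striatal_ctt[[h]]$P_str,
                           ph$striatal_ctt[[h]]$P_mat, ph$striatum[[h]])
  cm <- make_equal_volume_masks(bias, N = 83)
  jit_s <- jitter_mask(cm$striosome_like, ph$masks[[h]]$subcortical,
                       seed = 3)$mask
  jit_m <- jitter_mask(cm$matrix_like, ph$masks[[h]]$subcortical,
                       seed = 4)$mask
  g <- ph$g[[h]]
  region <- box_mask(ph$grid, 10:13, 40:43, 30:33)
  precise <- make_seed_region_ctt(region, cm$striosome_like, cm$matrix_like,
                                  g, noise_sd = 0.02, seed = 6)
  impre <- make_seed_region_ctt(region, jit_s, jit_m, g, noise_sd = 0.02,
                                seed = 6)
  rp <- seed_region_bias(precise$P_to_str, precise$P_to_mat, region)
  ri <- seed_region_bias(impre$P_to_str, impre$P_to_mat, region)
  expect_gt(rp$mean_p_striosome, ri$mean_p_striosome)
  expect_gte(rp$frac_striosome_favoring, ri$frac_striosome_favoring)
})

test_that("relative_locations reports centroid offsets per nucleus", {
  ph <- local_phantom(noise = FALSE)
  h <- "left"
  bias <- compute_bias_map(ph$striatal_ctt[[h]]$P_str,
                           ph$striatal_ctt[[h]]$P_mat, ph$striatum[[h]])
  cm <- make_equal_volume_masks(bias, N = 40)
  tab <- relative_locations(cm, ph$masks[[h]]$caudate, ph$masks[[h]]$putamen)
  expect_equal(nrow(tab), 80)
  # reconstruct absolute positions and compare against the centroids
  cen <- list(caudate = centroid_mm(ph$masks[[h]]$caudate),
              putamen = centroid_mm(ph$masks[[h]]$putamen))
  idx <- mask_indices(cm$striosome_like)
  mm <- index_to_mm(ph$grid, idx)
  str_rows <- tab[tab$compartment == "striosome", ]
  expect_equal(sort(as.numeric(str_rows$dx +
                                 sapply(str_rows$nucleus,
                                        function(n) cen[[n]][1]))),
               sort(mm[, 1]))
})
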