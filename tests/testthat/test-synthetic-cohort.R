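test_that("geometry is seeded-deterministic, disjoint, and mirror-balanced", {
  g <- default_grid(2.0)
  geo1 <- make_striatal_geometry(g, seed = 5L)
  geo2 <- make_striatal_geometry(g, seed = 5L)
  expect_identical(geo1$masks$left$caudate$membership,
                   geo2$masks$left$caudate$membership)
  expect_identical(geo1$nucleus_labels$right$labels,
                   geo2$nucleus_labels$right$labels)

  structs <- c("caudate", "putamen", "gpi", "thalamus")
  for (h in c("left", "right")) {
    mm <- sapply(structs, function(s) geo1$masks[[h]][[s]]$membership)
    expect_true(all(rowSums(mm) <= 1))  # pairwise disjoint
  }
  # left/right volumes match after reflection (mirror-symmetric design)
  for (s in structs) {
    expect_lte(abs(n_voxels(geo1$masks$left[[s]]) -
                     n_voxels(geo1$masks$right[[s]])), 2)
  }
  # >= 16 contiguous-by-construction parcels, all at least 4 voxels
  tab <- table(geo1$nucleus_labels$left$labels[
    geo1$nucleus_labels$left$labels > 0])
  expect_gte(length(tab), 16)
  expect_gte(min(tab), 4)
  expect_error(make_striatal_geometry(grid_spec(c(10, 10, 10), 2)), "small")
})

test_that("compartment field follows the planted gradient", {
  g <- default_grid(2.0)
  geo <- make_striatal_geometry(g, seed = 2L)
  striatum <- binary_mask(g, geo$masks$left$caudate$membership |
                               geo$masks$left$putamen$membership)
  flat <- make_compartment_field(g, striatum, "left",
                                 gradient_weights = c(0, 0, 0), noise_sd = 0)
  expect_equal(unique(flat$values[striatum$membership]), 0.5)

  med <- make_compartment_field(g, striatum, "left",
                                gradient_weights = c(2, 0, 0), noise_sd = 0)
  idx <- which(striatum$membership, arr.ind = TRUE)
  x <- index_to_mm(g, idx)[, 1]
  terc <- quantile(x, c(1 / 3, 2 / 3))
  gv <- med$values[striatum$membership]
  # left hemisphere: larger x is more medial
  expect_gt(mean(gv[x > terc[2]]), mean(gv[x < terc[1]]))

  a <- make_compartment_field(g, striatum, "left", noise_sd = 0.1, seed = 9L)
  b <- make_compartment_field(g, striatum, "left", noise_sd = 0.1, seed = 9L)
  expect_identical(a$values, b$values)
})

test_that("striatal probability pair inverts through the bias map", {
  ph <- local_phantom(noise = FALSE)
  h <- "left"
  pair <- ph$striatal_ctt[[h]]
  bias <- compute_bias_map(pair$P_str, pair$P_mat, ph$striatum[[h]])
  gv <- ph$g[[h]]$values[bias$support$membership]
  fv <- bias$f[bias$support$membership]
  expect_equal(fv, gv, tolerance = 1e-12)

  # rank correlation survives noise_sd = 0.05 on >= 2000 voxels
  p15 <- cohort_params(n_subjects = 1, spacing = 1.5, noise_sd = 0.05,
                       seed = 8)
  ph2 <- generate_subject(p15, 1L, components = "striatal")
  b2 <- compute_bias_map(ph2$striatal_ctt$left$P_str,
                         ph2$striatal_ctt$left$P_mat, ph2$striatum$left)
  sup <- b2$support$membership
  expect_gte(sum(sup), 2000)
  expect_gt(cor(b2$f[sup], ph2$g$left$values[sup], method = "spearman"), 0.9)
})

test_that("thalamic pair encodes bias, asymmetry, and edge attenuation", {
  g <- default_grid(2.0)
  geo <- make_striatal_geometry(g, seed = 3L)
  labs <- geo$nucleus_labels$left
  bias <- default_nucleus_bias()

  # noiseless extreme bias: interior voxels carry (0, 1)
  b1 <- bias; b1[] <- 1
  pr <- make_thalamic_ctt_pair(labs, "left", b1, asymmetry_delta = 0,
                               noise_sd = 0, share_dispersion = 0,
                               edge_attenuation_depth = 1L)
  thal_mask <- binary_mask(g, labs$labels > 0L)
  dpt <- striothal:::boundary_depth(thal_mask, 1L)
  interior <- thal_mask$membership & dpt >= 2
  expect_true(all(pr$p_mat$values[interior] == 1))
  expect_true(all(pr$p_str$values[interior] == 0))

  # noiseless beta = 0.5 leaves every interior voxel in the 0.45-0.55 band
  b5 <- bias; b5[] <- 0.5
  pr5 <- make_thalamic_ctt_pair(labs, "left", b5, asymmetry_delta = 0,
                                noise_sd = 0, share_dispersion = 0)
  thal <- binary_mask(g, labs$labels > 0L)
  pair5 <- renormalize_and_trim(pr5$p_str, pr5$p_mat, thal)
  ct5 <- count_suprathreshold(pair5, labs)
  expect_true(all(ct5$n_str == 0L))
  expect_true(all(ct5$n_mat == 0L))

  # boundary voxels attenuated below the 0.5 trim
  boundary <- thal_mask$membership & dpt == 0
  expect_gt(sum(boundary), 0)
  sums <- pr$p_mat$values + pr$p_str$values
  expect_true(all(sums[boundary] < 0.5))

  # interior pair sums are exactly 1 before trimming
  expect_equal(unique(sums[interior]), 1)

  expect_error(
    make_thalamic_ctt_pair(labs, "left", bias[-1]), "missing")
})

test_that("bundle densities plant peaks, scale linearly, separate offsets", {
  ph <- local_phantom(noise = FALSE)
  g <- ph$grid
  gpi <- ph$masks$left$gpi
  thal <- ph$masks$left$thalamus
  striatum <- ph$striatum$left

  d0 <- make_bundle_density(g, striatum, gpi, thal, c(0, 0, 0))
  pk <- peak_location(d0, gpi)
  expect_equal(pk$index, as.integer(mm_to_index(g, centroid_mm(gpi))))

  d2 <- make_bundle_density(g, striatum, gpi, thal, c(0, 0, 0),
                            amplitude = 2)
  expect_equal(d2$values, 2 * d0$values)

  dplus <- make_bundle_density(g, striatum, gpi, thal, c(0, 3, 0))
  dminus <- make_bundle_density(g, striatum, gpi, thal, c(0, -3, 0))
  dy <- peak_location(dplus, gpi)$mm[2] - peak_location(dminus, gpi)$mm[2]
  expect_lte(abs(dy - 6), g$spacing[2])

  expect_error(
    make_bundle_density(g, striatum, gpi, thal, c(50, 0, 0)), "outside")
})

test_that("cohorts are deterministic and carry the planted truth", {
  p <- cohort_params(n_subjects = 2, spacing = 2.0, seed = 13)
  c1 <- generate_cohort(p, components = "thalamic")
  c2 <- generate_cohort(p, components = "thalamic")
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$subjects[[2]]$thalamic_ctt$left$p_mat$values,
                   c2$subjects[[2]]$thalamic_ctt$left$p_mat$values)
  # different subjects get different draws
  expect_false(identical(c1$subjects[[1]]$thalamic_ctt$left$p_mat$values,
                         c1$subjects[[2]]$thalamic_ctt$left$p_mat$values))
  expect_setequal(c1$truth$nucleus, names(default_nucleus_bias()))
  expect_error(cohort_params(n_subjects = 0), "n_subjects")
})
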