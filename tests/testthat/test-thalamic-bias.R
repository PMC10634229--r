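test_that("renormalize_and_trim drops low-sum voxels and rescales", {
  g <- tiny_grid()
  ps <- array(0, g$shape); pm <- array(0, g$shape)
  ps[1:3] <- c(0.3, 0.4, 0.6); pm[1:3] <- c(0.1, 0.4, 0.2)
  thal <- box_mask(g, 1:3, 1, 1)
  pr <- renormalize_and_trim(scalar_volume(g, ps), scalar_volume(g, pm),
                             thal)
  expect_equal(pr$n_trimmed, 1L)           # (0.3, 0.1) sums to 0.4 < 0.5
  expect_false(pr$retained$membership[1])
  expect_equal(pr$p_str$values[2], 0.5)    # (0.4, 0.4) -> (0.5, 0.5)
  expect_equal(pr$p_str$values[3], 0.75)   # (0.6, 0.2) -> (0.75, 0.25)
  expect_equal(pr$p_mat$values[3], 0.25)
  # retained sums are exactly 1
  kept <- which(pr$retained$membership)
  expect_equal(pr$p_str$values[kept] + pr$p_mat$values[kept], rep(1, 2),
               tolerance = 1e-12)
})

test_that("suprathreshold counting respects the indeterminate band", {
  g <- tiny_grid()
  shares <- c(0.75, 0.55, 0.46, 0.30, 0.5)
  ps <- array(0, g$shape); pm <- array(0, g$shape)
  ps[1:5] <- shares; pm[1:5] <- 1 - shares
  thal <- box_mask(g, 1:5, 1, 1)
  lab <- array(0L, g$shape); lab[1:5] <- 1L
  labs <- label_volume(g, lab, c(CM = 1L))
  pr <- renormalize_and_trim(scalar_volume(g, ps), scalar_volume(g, pm),
                             thal)
  ct <- count_suprathreshold(pr, labs)
  # 0.75 and 0.55 count striosome (inclusive >=), 0.30 counts matrix
  # (matrix share 0.70), 0.46 and 0.5 fall in the band
  expect_equal(ct$n_str, 2L)
  expect_equal(ct$n_mat, 1L)
  expect_equal(ct$n_retained, 5L)
  expect_lte(ct$n_str + ct$n_mat, ct$n_retained)
})

test_that("matrix_fraction is a complement-consistent proportion", {
  expect_equal(matrix_fraction(99, 0), 0)     # 100 % striosome-favoring
  expect_equal(matrix_fraction(0, 50), 1)
  expect_equal(matrix_fraction(25, 25), 0.5)
  expect_true(is.na(matrix_fraction(0, 0)))
  # complement sums to one exactly
  expect_equal(matrix_fraction(13, 29) + matrix_fraction(29, 13), 1)
})

test_that("nucleus volume filter is inclusive at four voxels", {
  vols <- c(A = 13.5, B = 13.4, C = 32, D = 31.9)
  f15 <- nucleus_volume_filter(vols[1:2], 1.5)
  expect_equal(f15$retained, c(TRUE, FALSE))
  f20 <- nucleus_volume_filter(vols[3:4], 2.0)
  expect_equal(f20$retained, c(TRUE, FALSE))
  expect_equal(unique(f15$min_volume_mm3), 13.5)
  expect_equal(unique(f20$min_volume_mm3), 32)
})

test_that("hemisphere QC applies the 10 % rule then zero-compartment rule", {
  totals <- data.frame(
    subject = rep(c("S1", "S2", "S3"), each = 2),
    hemisphere = rep(c("left", "right"), 3),
    n_str = c(50, 60, 50, 55, 2, 40),
    n_mat = c(50, 40, 50, 45, 2, 0),
    voxel_volume_mm3 = 8)
  qc <- hemisphere_qc(totals, qc_fraction = 0.10)
  # left volumes (in voxels): 100, 100, 4; mean 68 -> cutoff 6.8 -> S3 out
  expect_true(any(qc$exclusions$subject == "S3" &
                    qc$exclusions$hemisphere == "left" &
                    qc$exclusions$reason == "low_volume"))
  # S3 right has n_mat = 0 -> zero_compartment
  expect_true(any(qc$exclusions$subject == "S3" &
                    qc$exclusions$hemisphere == "right" &
                    qc$exclusions$reason == "zero_compartment"))
  expect_equal(nrow(qc$kept), 4)
  # comfortable cohorts produce an empty report
  ok <- totals[totals$subject != "S3", ]
  expect_equal(nrow(hemisphere_qc(ok)$exclusions), 0)
})

test_that("hemispheric comparison flags split nuclei correctly", {
  set.seed(3)
  rec <- rbind(
    data.frame(subject = paste0("S", 1:10), hemisphere = "left",
               nucleus = "A", matrix_fraction = 0.9 + rnorm(10, 0, 0.01)),
    data.frame(subject = paste0("S", 1:10), hemisphere = "right",
               nucleus = "A", matrix_fraction = 0.1 + rnorm(10, 0, 0.01)),
    data.frame(subject = paste0("S", 1:10), hemisphere = "left",
               nucleus = "B", matrix_fraction = 0.7 + rnorm(10, 0, 0.05)),
    data.frame(subject = paste0("S", 1:10), hemisphere = "right",
               nucleus = "B", matrix_fraction = 0.7 + rnorm(10, 0, 0.05)))
  hc <- hemispheric_comparison(rec)
  a <- hc[hc$nucleus == "A", ]
  expect_true(a$significant)
  # both sides of A are significantly biased (opposite directions), so the
  # one-significant-one-neutral split rule does not fire
  expect_false(a$split)
  b <- hc[hc$nucleus == "B", ]
  expect_false(b$significant)

  # identical sides give t = 0, p = 1
  rec2 <- rbind(
    data.frame(subject = paste0("S", 1:5), hemisphere = "left",
               nucleus = "C", matrix_fraction = c(0.6, 0.7, 0.65, 0.6, 0.7)),
    data.frame(subject = paste0("S", 1:5), hemisphere = "right",
               nucleus = "C", matrix_fraction = c(0.6, 0.7, 0.65, 0.6, 0.7)))
  hc2 <- hemispheric_comparison(rec2)
  expect_equal(hc2$t, 0)
  expect_equal(hc2$p, 1)

  # significant difference with one neutral side -> split
  rec3 <- rbind(
    data.frame(subject = paste0("S", 1:10), hemisphere = "left",
               nucleus = "D", matrix_fraction = 0.75 + rnorm(10, 0, 0.03)),
    data.frame(subject = paste0("S", 1:10), hemisphere = "right",
               nucleus = "D", matrix_fraction = 0.5 + rnorm(10, 0, 0.03)))
  hc3 <- hemispheric_comparison(rec3)
  expect_true(hc3$significant)
  expect_true(hc3$split)
})

test_that("classify_nucleus recovers planted verdicts", {
  rec <- data.frame(nucleus = "X", matrix_fraction = rep(0.5, 10))
  expect_equal(classify_nucleus(rec)$verdict, "neutral")
  set.seed(5)
  rec2 <- data.frame(nucleus = "Y",
                     matrix_fraction = 0.9 + rnorm(30, 0, 0.02))
  expect_equal(classify_nucleus(rec2)$verdict, "matrix-biased")
  rec3 <- data.frame(nucleus = "Z",
                     matrix_fraction = 0.2 + rnorm(30, 0, 0.02))
  expect_equal(classify_nucleus(rec3)$verdict, "striosome-biased")
  # the one-sample variant agrees on direction
  expect_equal(classify_nucleus(rec2, method = "one_sample")$verdict,
               "matrix-biased")
  expect_error(classify_nucleus(data.frame(nucleus = "W",
                                           matrix_fraction = NA_real_)),
               "QC")
})

test_that("laterality consistency reproduces the exact coin probability", {
  # 18 of 20: 1 in 5,519
  set.seed(8)
  ml <- stats::setNames(runif(20, 0.5, 0.9), paste0("N", 1:20))
  mr <- ml - 0.05
  mr[c(3, 11)] <- ml[c(3, 11)] + 0.05  # two nuclei go the other way
  lat <- laterality_consistency(ml, mr)
  expect_equal(lat$k, 18)
  expect_equal(lat$n, 20)
  expect_equal(lat$one_in, 5519)
  # ties reduce n
  mr[7] <- ml[7]
  lat2 <- laterality_consistency(ml, mr)
  expect_equal(lat2$n, 19)
  expect_equal(lat2$k, 17)
  # n = 2, k = 2 -> 1 in 4
  lat3 <- laterality_consistency(c(a = 1, b = 1), c(a = 0, b = 0))
  expect_equal(lat3$one_in, 4)
  expect_error(laterality_consistency(numeric(0), numeric(0)), "no compar")
})

test_that("nucleus-level bias recovery on a phantom cohort", {
  # 8 subjects at 1.5 mm, thalamic stage only: pooled count-based fractions
  # track planted beta + delta/2 for clearly biased nuclei
  p <- cohort_params(n_subjects = 8, spacing = 1.5, seed = 31)
  cohort <- generate_cohort(p, components = "thalamic")
  cfg <- default_config(p)
  th <- stage_thalamus(cohort, cfg)
  pooled <- tapply(th$records$matrix_fraction, th$records$nucleus, mean)
  truth <- p$nucleus_bias + p$asymmetry_delta / 2
  err <- abs(pooled[names(truth)] - truth)
  expect_lt(max(err), 0.08)
  # CM (beta 0.76) classifies matrix-biased with mean near planted truth
  cls <- classify_nucleus(th$records)
  cm <- cls[cls$nucleus == "CM", ]
  expect_equal(cm$verdict, "matrix-biased")
  expect_lt(abs(cm$mean - (0.76 + p$asymmetry_delta / 2)), 0.05)
})
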