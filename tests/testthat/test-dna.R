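coarse <- c(0.5, 0.3, 0.3)                       # voxel (z, y, x) um

test_that("nucleus segmentation enforces the minimum-volume rule", {
  big <- make_dna_scene(1, 0.1, voxel_um = coarse,
                        nucleus_semiaxes_um = c(3, 6, 7), seed = 1)
  nuc <- segment_nucleus_3d(big$dapi, coarse, threshold = 50)
  expect_gt(nuc$volume_um3, 500)

  small <- make_dna_scene(1, 0.1, voxel_um = coarse,
                          nucleus_semiaxes_um = c(2, 4, 4.5), seed = 2)
  expect_error(segment_nucleus_3d(small$dapi, coarse, threshold = 50),
               "500")

  ## debris next to the nucleus is discarded by the size rule
  withdeb <- big$dapi
  withdeb[2:4, 2:6, 2:6] <- 150
  nuc2 <- segment_nucleus_3d(withdeb, coarse, threshold = 50)
  expect_false(any(nuc2$mask[2:4, 2:6, 2:6]))
})

test_that("triangle threshold separates a peaked background from a bright tail", {
  set.seed(3)
  x <- c(rnorm(2e4, 20, 3), runif(500, 80, 200))
  thr <- triangle_threshold(x)
  expect_gt(thr, 20 + 2.5 * 3)   # above the bulk of the background peak
  expect_lt(thr, 80)             # below the bright tail
  expect_equal(triangle_threshold(rep(7, 100)), 7)
})

test_that("foci are segmented inside the nucleus with touching-object separation", {
  sc <- make_dna_scene(6, rep(0.02, 6), voxel_um = coarse,
                       nucleus_semiaxes_um = c(3, 6, 7),
                       focus_radius_um = 0.5, seed = 4)
  nuc <- segment_nucleus_3d(sc$dapi, coarse, threshold = 50)
  foci <- segment_foci(sc$label, nuc, coarse, min_voxels = 3)
  expect_equal(foci$n_foci, 6L)

  ## two touching spheres with distinct peaks split into two records
  d <- c(12, 40, 40)
  lab <- array(0, d)
  gz <- (seq_len(12) - 0.5) * coarse[1]
  gy <- (seq_len(40) - 0.5) * coarse[2]
  gx <- (seq_len(40) - 0.5) * coarse[3]
  for (ctr in list(c(3, 6, 5.4), c(3, 6, 6.6))) {
    q <- outer(((gz - ctr[1]) / 0.8)^2,
               outer(((gy - ctr[2]) / 0.8)^2, ((gx - ctr[3]) / 0.8)^2, "+"), "+")
    lab[q <= 1] <- 200
  }
  nuc_all <- list(mask = array(TRUE, d), sum_intensity = sum(lab) + 1)
  out <- segment_foci(lab, nuc_all, coarse, threshold = 100, min_voxels = 3)
  expect_equal(out$n_foci, 2L)

  expect_warning(
    none <- segment_foci(array(0, d) + 1e-9, nuc_all, coarse, threshold = 1),
    "no focus")
  expect_equal(none$n_foci, 0L)
})

test_that("noise-only focus channels yield no foci at the triangle threshold", {
  ## the triangle threshold adapts to the histogram, so on pure noise it
  ## sits at a noise quantile; the size exclusion (noise clusters stay far
  ## below the voxel span of a diffraction-limited focus) rejects the rest
  d <- c(10, 64, 64)
  nuc_all <- list(mask = array(TRUE, d), sum_intensity = 1)
  zero_runs <- vapply(1:20, function(s) {
    set.seed(900 + s)
    noise <- array(rpois(prod(d), 4) + rnorm(prod(d), 0, 0.5), d)
    out <- suppressWarnings(segment_foci(noise, nuc_all, c(0.25, 0.1, 0.1)))
    out$n_foci == 0
  }, logical(1))
  expect_gte(mean(zero_runs), 0.95)
})

test_that("DNA amounts follow ratio x C x GS", {
  f <- cell_cycle_factors()
  expect_equal(unname(f$C["G1"]), 1)
  expect_equal(unname(f$C["G2"]), 1.98)
  expect_true(all(diff(f$C) >= 0))

  sc <- make_dna_scene(4, c(0.04, 0.03, 0.02, 0.01), voxel_um = coarse,
                       nucleus_semiaxes_um = c(3, 6, 7),
                       focus_radius_um = 0.5, seed = 5)
  nuc <- segment_nucleus_3d(sc$dapi, coarse, threshold = 50)
  foci <- segment_foci(sc$label, nuc, coarse, threshold = 100, min_voxels = 3)
  q <- quantify_focus_dna(foci, nuc, sc$dapi, stage = "mS", voxel_um = coarse)
  expect_equal(nrow(q$records), 4L)
  got <- sort(q$records$ratio)
  expect_lt(max(abs(got - sort(sc$truth$fractions)) / sort(sc$truth$fractions)),
            0.02)
  expect_equal(q$records$dna_kbp, q$records$ratio * 1.27 * 9.682e6)
  expect_true(!is.null(q$histogram$median_kbp))
  ## conservation: foci cannot carry more DNA than the cell has
  expect_lte(sum(q$records$dna_kbp), 1.27 * 9.682e6)
  expect_error(quantify_focus_dna(foci, nuc, sc$dapi, stage = "M",
                                  voxel_um = coarse), "stage")
})

test_that("quantification is invariant to global intensity rescaling", {
  sc <- make_dna_scene(2, c(0.05, 0.02), voxel_um = coarse,
                       nucleus_semiaxes_um = c(3, 6, 7),
                       focus_radius_um = 0.5, seed = 6)
  nuc <- segment_nucleus_3d(sc$dapi, coarse, threshold = 50)
  foci <- segment_foci(sc$label, nuc, coarse, threshold = 100, min_voxels = 3)
  q1 <- quantify_focus_dna(foci, nuc, sc$dapi, "G1", coarse)
  nuc2 <- segment_nucleus_3d(sc$dapi * 7, coarse, threshold = 350)
  q2 <- quantify_focus_dna(foci, nuc2, sc$dapi * 7, "G1", coarse)
  expect_equal(q1$records$dna_kbp, q2$records$dna_kbp, tolerance = 1e-9)
})

test_that("worked DNA arithmetic from the published constants", {
  rec <- data.frame(ratio = c(0.5, 1e-5))
  f <- cell_cycle_factors()
  expect_equal(0.5 * f$C[["G1"]] * f$GS_kbp, 4.841e6)
  expect_equal(1e-5 * f$C[["mS"]] * f$GS_kbp, 122.96, tolerance = 1e-3)
})

test_that("object-overlap colocalization percentages", {
  a <- array(0L, c(4, 10, 10))
  a[2, 2:3, 2:3] <- 1L; a[2, 6:7, 6:7] <- 2L
  expect_equal(colocalization_fraction(a, a), 100)
  b <- array(0L, c(4, 10, 10)); b[4, 9, 9] <- 1L
  expect_equal(colocalization_fraction(a, b), 0)
  four <- array(0L, c(1, 12, 4))
  for (i in 1:4) four[1, 3 * i - 2, 2] <- i
  three <- four; three[four == 4L] <- 0L
  expect_equal(colocalization_fraction(four, three), 75)
  empty <- array(0L, c(4, 10, 10))
  expect_true(is.na(colocalization_fraction(empty, b)))
})

test_that("combing conversion and lambda calibration", {
  expect_equal(combing_convert(100, 2), 200)
  expect_equal(combing_convert(50, 1), 50)
  expect_equal(combing_calibrate(rep(24.25, 10)), 2.0)
  expect_equal(combing_calibrate(c(24, 24.5)), 48.5 / 24.25)
  expect_error(combing_convert(-1), "positive")
  expect_error(combing_calibrate(0), "positive")
})
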