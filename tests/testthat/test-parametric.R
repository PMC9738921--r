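mk_static <- function(arr, spacing = c(1, 1, 1)) {
  attr(arr, "spacing") <- spacing
  arr
}

test_that("brain reference is the plain mask mean", {
  a <- array(1, c(3, 3, 3))
  m <- array(FALSE, c(3, 3, 3)); m[1:3, 1, 1] <- TRUE
  expect_equal(brain_reference(a, voi_mask(m, c(1, 1, 1), "brain")), 1)
  a[1:3, 1, 1] <- c(1, 2, 3)
  expect_equal(brain_reference(a, voi_mask(m, c(1, 1, 1), "brain")), 2)
  expect_error(brain_reference(a, voi_mask(array(FALSE, c(3, 3, 3)),
                                           c(1, 1, 1), "brain")), "empty")
})

test_that("tumour segmentation thresholds, keeps the largest component, is monotone", {
  a <- array(1, c(3, 3, 3))
  a[1, 1, 1] <- 2; a[2, 1, 1] <- 2
  all_reg <- voi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  got <- segment_tumor(a, 1, all_reg, factor = 1.6)
  expect_equal(sum(got$mask), 2L)
  expect_true(all(got$mask[cbind(1:2, 1, 1)]))

  expect_error(segment_tumor(array(1, c(3, 3, 3)), 1, all_reg), "threshold")

  # two disjoint blobs: only the larger survives
  b <- array(0, c(7, 7, 3))
  b[1:3, 1:3, 1] <- 2; b[6:7, 6:7, 3] <- 2
  got2 <- segment_tumor(b, 1, voi_mask(array(TRUE, dim(b)), c(1, 1, 1)))
  expect_equal(sum(got2$mask), 9L)

  # monotone in factor on a noisy field
  set.seed(3)
  c3 <- array(runif(8 * 8 * 8, 0.5, 3), c(8, 8, 8))
  c3[4:5, 4:5, 4:5] <- 3
  reg <- voi_mask(array(TRUE, dim(c3)), c(1, 1, 1))
  m16 <- segment_tumor(c3, 1, reg, 1.6)$mask
  m18 <- segment_tumor(c3, 1, reg, 1.8)$mask
  expect_true(all(!m18 | m16))
})

test_that("striatum segmentation keeps voxels above 70% of the seed maximum", {
  a <- array(0, c(3, 3, 1))
  a[1:3, 1, 1] <- c(10, 8, 6)
  seed <- voi_mask(array(c(rep(TRUE, 3), rep(FALSE, 6)), c(3, 3, 1)),
                   c(1, 1, 1), "striatum")
  got <- segment_striatum(a, seed)
  expect_equal(which(got$mask), which(a >= 7 & seed$mask))
  expect_equal(sum(got$mask), 2L)
  uni <- array(5, c(3, 3, 1))
  expect_equal(segment_striatum(uni, seed)$mask, seed$mask)
  expect_error(segment_striatum(a, voi_mask(array(FALSE, c(3, 3, 1)),
                                            c(1, 1, 1), "striatum")), "empty")
})

test_that("TBR map divides by the reference and is scale invariant", {
  a <- mk_static(array(3.2, c(2, 2, 2)))
  expect_equal(tbr_map(a, 1.6)$values, array(2, c(2, 2, 2)),
               ignore_attr = TRUE)
  expect_equal(tbr_map(mk_static(array(1.6, c(2, 2, 2))), 1.6)$values,
               array(1, c(2, 2, 2)), ignore_attr = TRUE)
  set.seed(4)
  b <- mk_static(array(runif(27, 1, 3), c(3, 3, 3)))
  for (cc in c(0.5, 7)) {
    expect_equal(tbr_map(mk_static(b * cc), 1.3 * cc)$values,
                 tbr_map(b, 1.3)$values, tolerance = 1e-12)
  }
})

test_that("SG TAC smoothing reproduces polynomials up to degree 2", {
  t <- frame_midpoints(frame_schedule())
  expect_equal(fit_tac(tac(t, rep(2, 30)))$values, rep(2, 30))
  expect_equal(fit_tac(tac(t, 0.3 * t + 1))$values, 0.3 * t + 1,
               tolerance = 1e-10)
  q <- 0.1 * t^2
  expect_lt(max(abs(fit_tac(tac(t, q))$values - q)), 1e-9)
  expect_error(fit_tac(tac(1:5, 1:5)), "7 frames")
})

test_that("kinetic TAC fit recovers rise/washout curves exactly", {
  sched <- frame_schedule()
  t <- frame_midpoints(sched)
  for (ttp_true in c(3.5, 7.5, 15.5, 22.5)) {
    les <- lesion_spec(c(1, 1, 1), c(5, 5, 5), 0L, 2.5, ttp_true, 1.2)
    v <- tac_model(les, sched)
    f <- fit_tac_kinetic(tac(t, v))
    expect_lt(max(abs(f$values - v)), 1e-9)
    expect_equal(ttp(f), ttp_true)
  }
})

test_that("TAC ratio and TTP follow their contracts", {
  t <- c(0.5, 1.5, 2.5, 3.5)
  b <- tac(t, rep(2, 4), fitted = TRUE)
  expect_equal(tac_ratio(b, b)$values, rep(1, 4))
  expect_equal(tac_ratio(tac(t, rep(4, 4), fitted = TRUE), b)$values,
               rep(2, 4))
  expect_error(tac_ratio(b, tac(t, c(1, 0, 1, 1), fitted = TRUE)), "positive")

  expect_equal(ttp(tac(t, c(1, 2, 5, 4), fitted = TRUE)), 2.5)
  mono <- tac(frame_midpoints(frame_schedule()), 1:30, fitted = TRUE)
  expect_equal(ttp(mono), 29.5)
  expect_equal(ttp(tac(t, c(1, 5, 5, 1), fitted = TRUE)), 1.5)
  expect_error(ttp(tac(t, 1:4)), "fitted")
})

test_that("voxel TTP maps are exact on noiseless phantoms and separate kinetic classes", {
  sub_a <- render_subject(test_phantom(ttp = 3.5, slope = 1.2, fwhm = 0,
                                       noise = list(type = "none")))
  sub_b <- render_subject(test_phantom(ttp = 19.5, slope = 0.1, fwhm = 0,
                                       noise = list(type = "none")))
  den_a <- hypr_denoise(sub_a$study)
  den_b <- hypr_denoise(sub_b$study)
  map_a <- ttp_map(den_a, sub_a$masks$brain, sub_a$masks$tumor_region)
  map_b <- ttp_map(den_b, sub_b$masks$brain, sub_b$masks$tumor_region)
  core <- sub_a$truth$lesions[[1]]$center
  expect_equal(map_a$values[core[1], core[2], core[3]], 3.5)
  expect_equal(map_b$values[core[1], core[2], core[3]], 19.5)
  les <- sub_a$masks$lesion_truth$mask
  expect_gt(mean(map_b$values[les]) - mean(map_a$values[les]), 10)
  ok <- map_a$values[!is.na(map_a$values)]
  expect_true(all(ok >= 0.5 & ok <= 29.5))
})

test_that("TTP is invariant to rescaling when the brain TAC is constant", {
  sub <- render_subject(test_phantom(ttp = 11.5, fwhm = 0,
                                     noise = list(type = "none")))
  den <- hypr_denoise(sub$study)
  m1 <- ttp_map(den, sub$masks$brain, sub$masks$tumor_region)
  den2 <- den; den2$data <- den$data * 3.7
  m2 <- ttp_map(den2, sub$masks$brain, sub$masks$tumor_region)
  expect_equal(m1$values, m2$values)
})

test_that("region features: 9 values, closed-form slope, uniform-field identities", {
  sub <- render_subject(test_phantom(fwhm = 0, noise = list(type = "none")))
  an <- analyze_subject(sub, psfd = FALSE)
  expect_length(an$region, 9L)
  expect_named(an$region, c("TBR_mean", "TBR_max", "TBR_peak", "TSR_mean",
                            "TSR_max", "TSR_peak", "MTV", "TTP_region",
                            "slope_region"))

  # hand-built study: tumour TAC_ratio = 2 + 0.01 t -> slope 0.6 per hour
  d <- c(12, 12, 6)
  t <- frame_midpoints(frame_schedule())
  dat <- array(1, c(d, 30))
  tum <- array(FALSE, d); tum[5:7, 5:7, 3:4] <- TRUE
  for (fr in 1:30) {
    frame <- array(1, d); frame[tum] <- 2 + 0.01 * t[fr]
    dat[, , , fr] <- frame
  }
  st <- structure(list(data = dat, spacing = c(1, 1, 1),
                       schedule = frame_schedule()),
                  class = "dynamic_study")
  brain <- array(FALSE, d); brain[1:3, 1:3, 1:2] <- TRUE
  stri <- array(FALSE, d); stri[10:11, 10:11, 5] <- TRUE
  static <- mk_static(apply(dat[, , , t >= 10], 1:3, mean))
  tbr <- tbr_map(static, 1)
  rf <- region_features(tbr, st, list(
    tumor = voi_mask(tum, c(1, 1, 1), "tumor"),
    striatum = voi_mask(stri, c(1, 1, 1), "striatum"),
    brain = voi_mask(brain, c(1, 1, 1), "brain")))
  expect_equal(rf[["slope_region"]], 0.6, tolerance = 1e-6)
  expect_equal(rf[["MTV"]], 18)               # 18 voxels at 1 mm^3
  expect_equal(rf[["TBR_mean"]], rf[["TBR_max"]])
  expect_equal(rf[["TTP_region"]], 29.5)       # monotone ratio peaks last
})
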