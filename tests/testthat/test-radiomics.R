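test_that("fixed-bin-width discretization follows the min-anchored formula", {
  d <- discretize_fbw(c(0.05, 0.14, 0.25), 0.1)
  expect_equal(d$levels, c(1L, 1L, 3L))
  expect_equal(d$n_levels, 3L)

  dc <- discretize_fbw(rep(2.2, 5), 0.1)
  expect_equal(dc$levels, rep(1L, 5))
  expect_equal(dc$n_levels, 1L)

  # TTP minutes with 1-min bins: levels index occupied frames from the min
  dt <- discretize_fbw(c(3.5, 3.5, 7.5, 12.5), 1)
  expect_equal(dt$levels, c(1L, 1L, 5L, 10L))
  expect_equal(dt$n_levels, 10L)
})

test_that("isotropic resampling: identity at target, shape doubling, constants preserved", {
  m <- parametric_map("TBR", array(runif(4 * 4 * 4), c(4, 4, 4)), c(1, 1, 1))
  v <- voi_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  out <- resample_isotropic(m, v, 1)
  expect_identical(out$map$values, m$values)

  m2 <- parametric_map("TBR", array(runif(5 * 5 * 5), c(5, 5, 5)), c(2, 2, 2))
  v2 <- voi_mask(array(TRUE, c(5, 5, 5)), c(2, 2, 2))
  out2 <- resample_isotropic(m2, v2, 1)
  expect_equal(dim(out2$map$values), c(9L, 9L, 9L))
  expect_true(all(out2$voi$mask))

  mc <- parametric_map("TBR", array(1.7, c(5, 5, 5)), c(2, 2, 2))
  out3 <- resample_isotropic(mc, v2, 1)
  expect_true(all(abs(out3$map$values - 1.7) < 1e-12))
})

test_that("morphology: cube volume, rod diameter, sphere vs slab sphericity", {
  cube <- voi_mask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  f <- extract_morphology(cube)
  expect_length(f, 11L)
  expect_equal(f[["morph_voxel_volume"]], 1000)
  expect_lt(abs(f[["morph_mesh_volume"]] - 1000) / 1000, 0.30)

  rodm <- array(FALSE, c(3, 3, 7)); rodm[2, 2, 2:6] <- TRUE
  rod <- extract_morphology(voi_mask(rodm, c(1, 1, 1)))
  expect_equal(rod[["morph_max_diameter"]], 4)
  expect_gt(rod[["morph_major_axis"]], rod[["morph_least_axis"]])

  grid <- c(13, 13, 13)
  ctr <- c(7, 7, 7)
  dist2 <- outer(outer(((1:13) - 7)^2, ((1:13) - 7)^2, `+`), ((1:13) - 7)^2, `+`)
  sphere <- voi_mask(dist2 <= 25, c(1, 1, 1))
  nvox <- sum(sphere$mask)
  slab_m <- array(FALSE, grid)
  slab_m[seq_len(ceiling(nvox / 13 / 4)), 1:13, 1:4] <- TRUE
  slab <- voi_mask(slab_m, c(1, 1, 1))
  fs <- extract_morphology(sphere); fl <- extract_morphology(slab)
  expect_gt(fs[["morph_sphericity"]], fl[["morph_sphericity"]])
  # the binary-mask tetrahedral surface is faceted, biasing area high, so
  # absolute sphericity sits below 1 even for a digital sphere
  expect_lt(abs(fs[["morph_sphericity"]] - 1), 0.35)
})

test_that("intensity features match hand computations and degenerate safely", {
  img <- array(0, c(3, 1, 1)); img[, 1, 1] <- c(1, 2, 3)
  m <- array(TRUE, c(3, 1, 1))
  f <- extract_intensity(img, m, discretize_fbw(c(1, 2, 3), 0.1), c(1, 1, 1))
  expect_length(f, 19L)
  expect_equal(f[["stat_mean"]], 2)
  expect_equal(f[["stat_variance"]], 2 / 3)
  expect_equal(f[["stat_range"]], 2)
  expect_equal(f[["stat_rms"]], sqrt(14 / 3))

  cimg <- array(5, c(3, 3, 3)); cm <- array(TRUE, c(3, 3, 3))
  fc <- extract_intensity(cimg, cm, discretize_fbw(rep(5, 27), 0.1), c(1, 1, 1))
  expect_equal(fc[["stat_variance"]], 0)
  expect_equal(fc[["stat_entropy"]], 0)
  expect_equal(fc[["stat_uniformity"]], 1)
  expect_equal(fc[["stat_skewness"]], 0)
  expect_equal(fc[["stat_local_peak"]], 5)
  expect_equal(fc[["stat_global_peak"]], 5)
})

test_that("GLCM counts match brute-force ordered-pair enumeration", {
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[1, 2, 1] <- 2L; lev[2, 1, 1] <- 1L; lev[2, 2, 1] <- 1L
  got <- fdopamics:::glcm_matrix(lev, 2L)
  expect_equal(got, glcm_brute(lev, 2L))
  expect_equal(max(got / sum(got)),
               fdopamics:::glcm_features(lev, 2L)[["glcm_max_probability"]])

  set.seed(8)
  lev2 <- array(sample(c(NA, 1:4), 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
  lev2 <- array(as.integer(lev2), dim(lev2))
  expect_equal(fdopamics:::glcm_matrix(lev2, 4L), glcm_brute(lev2, 4L))
})

test_that("GLSZM records one zone per connected component with its size", {
  lev <- array(NA_integer_, c(5, 5, 2))
  lev[1:3, 1, 1] <- 2L                   # zone of size 3 at level 2
  lev[5, 3:5, 1] <- 2L; lev[5, 3:4, 2] <- 2L  # 26-connected zone of size 5
  Z <- fdopamics:::glszm_matrix(lev, 2L)
  expect_equal(Z[2, 3], 1)
  expect_equal(Z[2, 5], 1)
  expect_equal(sum(Z), 2)
})

test_that("texture features are defined for degenerate single-level VOIs", {
  lev <- array(1L, c(3, 3, 3))
  f <- extract_texture(lev, 1L)
  expect_length(f, 75L)
  expect_true(all(is.finite(f)))
  expect_equal(f[["glcm_contrast"]], 0)
  # runs tile every voxel once per direction (13 directions, 27 voxels)
  R <- fdopamics:::glrlm_matrix(lev, 1L)
  expect_equal(sum(R %*% seq_len(ncol(R))), 27 * 13)
  expect_gt(f[["glrlm_large_run_emphasis"]], f[["glrlm_small_run_emphasis"]])
  single <- array(1L, c(1, 1, 1))
  f1 <- extract_texture(single, 1L)
  expect_true(all(is.finite(f1)))
})

test_that("texture on min-anchored bins is invariant to adding a constant", {
  set.seed(10)
  img <- array(runif(6 * 6 * 6, 1, 2), c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  lev_of <- function(a) {
    d <- discretize_fbw(a[m], 0.1)
    L <- array(NA_integer_, dim(a)); L[m] <- d$levels
    list(L = L, n = d$n_levels)
  }
  a1 <- lev_of(img); a2 <- lev_of(img + 3.3)
  expect_equal(a1$n, a2$n)
  expect_equal(extract_texture(a1$L, a1$n), extract_texture(a2$L, a2$n),
               tolerance = 1e-12)
})

test_that("extract_all emits exactly 105 finite features with the naming contract", {
  set.seed(11)
  img <- array(runif(10 * 10 * 8, 1, 3), c(10, 10, 8))
  msk <- array(FALSE, c(10, 10, 8)); msk[3:8, 3:8, 3:6] <- TRUE
  map <- parametric_map("TBR", img, c(1, 1, 1))
  voi <- voi_mask(msk, c(1, 1, 1))
  fv <- extract_all(map, voi, "tbr")
  expect_length(fv, 105L)
  expect_true(all(is.finite(fv)))
  expect_equal(sum(startsWith(names(fv), "morph_")), 11L)
  expect_equal(sum(!startsWith(names(fv), "morph_")), 94L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(fv, extract_all(map, voi, "tbr"))

  tmap <- parametric_map("TTP", array(sample(seq(0.5, 29.5, 1), 800,
                                             replace = TRUE), c(10, 10, 8)),
                         c(1, 1, 1))
  ft <- extract_all(tmap, voi, "ttp")
  expect_true(all(endsWith(names(ft), "_TTP")))
  expect_length(ft, 105L)

  man <- feature_manifest()
  expect_equal(nrow(man), 105L)
  expect_equal(as.integer(table(man$family)[c("glcm", "glrlm", "glszm",
                                              "gldm", "morph", "ngtdm",
                                              "stat")]),
               c(24L, 16L, 16L, 14L, 11L, 5L, 19L))
})
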