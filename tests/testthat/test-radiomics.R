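# small helper: wrap a (possibly 2D) grid as a tumor_volume with full mask
grid_volume <- function(vals, mask = NULL) {
  a <- if (is.matrix(vals)) array(vals, c(dim(vals), 1)) else as.array(vals)
  m <- if (is.null(mask)) array(TRUE, dim(a)) else
    array(as.logical(mask), dim(a))
  tumor_volume(a, m)
}

test_that("quantization uses right-closed equal-width bins over the mask", {
  v <- grid_volume(matrix(c(1, 5, 9), 1))
  expect_equal(quantize(v, 2)[1, , 1], c(1, 1, 2))
  # identity binning: 32 integer values onto 32 levels
  v32 <- grid_volume(matrix(0:31, 1))
  expect_equal(quantize(v32, 32)[1, , 1], 1:32)
  # constant region maps entirely to level 1
  vc <- grid_volume(matrix(7, 3, 3))
  expect_true(all(quantize(vc, 16)[, , 1] == 1))
  # outside-mask voxels get level 0
  vm <- grid_volume(matrix(1:4, 2), mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
  expect_identical(quantize(vm, 2)[2, 2, 1], 0L)
})

test_that("GLSZM counts connected zones of equal level by size", {
  g <- rbind(c(1, 2, 2),
             c(1, 1, 2),
             c(3, 3, 3))
  m <- glszm(g, connectivity = 8)
  expect_identical(sum(m$counts), 3L)
  expect_identical(m$counts["1", "3"], 1L)
  expect_identical(m$counts["2", "3"], 1L)
  expect_identical(m$counts["3", "3"], 1L)

  # constant region of V voxels: one zone of size V
  mc <- glszm(matrix(1L, 4, 5), connectivity = 8)
  expect_identical(mc$counts[1, 20], 1L)

  # checkerboard: diagonal adjacency merges each colour into one zone
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L)
  expect_identical(sum(glszm(cb, connectivity = 8)$counts), 2L)
})

test_that("GLSZM zone totals agree with an independent igraph oracle", {
  set.seed(101)
  for (rep in 1:100) {
    q <- array(sample(1:3, 6^3, replace = TRUE), c(6, 6, 6))
    m <- glszm(q)
    oracle_total <- sum(vapply(1:3, function(g)
      length(igraph_zone_sizes(q == g)), integer(1)))
    expect_identical(sum(m$counts), as.integer(oracle_total))
    # size spectra agree level by level
    for (g in 1:3) {
      expect_identical(
        sort(rep(seq_len(ncol(m$counts)), m$counts[g, ])),
        as.integer(igraph_zone_sizes(q == g)))
    }
  }
})

test_that("GLSZM features match the hand-evaluated worked example", {
  m <- glszm(rbind(c(1, 2, 2), c(1, 1, 2), c(3, 3, 3)), connectivity = 8)
  f <- glszm_features(m)
  expect_equal(unname(f["grey_level_variance"]), 2 / 3)
  expect_equal(unname(f["grey_level_non_uniformity"]), 1)
  expect_equal(unname(f["small_zone_low_grey_level_emphasis"]),
               (1 / 9 + 1 / 36 + 1 / 81) / 3)

  # single zone counts(1,1)=1
  single <- structure(list(counts = matrix(1L, 1, 1), n_levels = 1L,
                           kind = "GLSZM"), class = "texture_matrix")
  fs <- glszm_features(single)
  expect_equal(unname(fs), c(0, 1, 1), ignore_attr = TRUE)
})

test_that("GLSZM features satisfy their bounds on random matrices", {
  set.seed(11)
  for (rep in 1:20) {
    q <- array(sample(1:4, 125, replace = TRUE), c(5, 5, 5))
    f <- glszm_features(glszm(q))
    expect_gte(f[["grey_level_variance"]], 0)
    expect_gt(f[["small_zone_low_grey_level_emphasis"]], 0)
    expect_lte(f[["small_zone_low_grey_level_emphasis"]], 1)
  }
})

test_that("run-length GLN enumerates runs per direction and averages", {
  # constant 1x4 row: horizontal 1 run (GLN 1), the other three 2D
  # directions see 4 single-voxel runs of one level (GLN 4 each)
  expect_equal(unname(glrlm_gln(matrix(1L, 1, 4))), (1 + 3 * 4) / 4)
  # [1,1,2,2]: horizontal {(1,2),(2,2)} -> GLN 1; others 4 runs over 2
  # levels -> GLN 2
  expect_equal(unname(glrlm_gln(matrix(c(1, 1, 2, 2), 1))), (1 + 3 * 2) / 4)
  # [1,2,1,2]: every direction gives 4 runs, two per level -> GLN 2
  expect_equal(unname(glrlm_gln(matrix(c(1, 2, 1, 2), 1))), 2)
  expect_error(glrlm_gln(matrix(1L, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("Laws energies annihilate constants, scale linearly, and pass an impulse", {
  msk <- array(FALSE, c(11, 11, 11))
  msk[4:8, 4:8, 4:8] <- TRUE
  vc <- tumor_volume(array(3, c(11, 11, 11)), msk)
  e <- laws_energy_3d(vc)
  expect_length(e, 125)
  expect_true(all(e[names(e) != "laws_L5L5L5"] < 1e-10))
  expect_gt(e[["laws_L5L5L5"]], 0)

  v1 <- simulate_tumor_volume(shape = c(16, 16, 16), axes = c(5, 5, 5),
                              texture_sd = 8, seed = 6)
  v3 <- tumor_volume(v1$img * 3, v1$mask)
  expect_equal(laws_energy_3d(v3), 3 * laws_energy_3d(v1))

  # single-voxel impulse at an interior voxel, mask = that voxel:
  # the response there is the product of the kernels' central coefficients
  img <- array(0, c(9, 9, 9))
  img[5, 5, 5] <- 1
  m1 <- array(FALSE, c(9, 9, 9))
  m1[5, 5, 5] <- TRUE
  ei <- laws_energy_3d(tumor_volume(img, m1))
  centre <- c(L5 = 6, E5 = 0, S5 = 2, R5 = 6, W5 = 0)
  for (nm in c("L5L5L5", "S5S5S5", "L5S5R5", "E5L5L5")) {
    ks <- substring(nm, c(1, 3, 5), c(2, 4, 6))
    expect_equal(unname(ei[paste0("laws_", nm)]),
                 abs(prod(centre[ks])))
  }
})

test_that("wavelet energies: constants, quadratic scaling, 2x2x2 impulse", {
  msk <- array(FALSE, c(8, 8, 8))
  msk[3:6, 3:6, 3:6] <- TRUE
  w <- wavelet_energy_3d(tumor_volume(array(5, c(8, 8, 8)), msk))
  expect_length(w, 8)
  expect_true(all(w[names(w) != "wavelet_LLL"] == 0))

  v1 <- simulate_tumor_volume(shape = c(16, 16, 16), axes = c(5, 5, 5),
                              texture_sd = 8, seed = 6)
  v2 <- tumor_volume(v1$img * 2, v1$mask)
  expect_equal(wavelet_energy_3d(v2), 4 * wavelet_energy_3d(v1))

  wi <- wavelet_energy_3d(grid_volume(array(c(1, rep(0, 7)), c(2, 2, 2))))
  expect_equal(unname(wi), rep(1 / 8, 8))
})

test_that("shape features recover sphere and ellipsoid geometry", {
  sph <- simulate_tumor_volume(shape = c(31, 31, 31), axes = c(10, 10, 10),
                               texture_sd = 0, seed = 1)
  f <- shape_features(sph)
  expect_lt(abs(f[["flatness"]] - 1), 0.05)
  expect_lt(abs(f[["asymmetry"]]), 0.05)
  expect_lt(abs(f[["surface_to_volume"]] - 3 / 10) / (3 / 10), 0.15)

  ell <- simulate_tumor_volume(shape = c(45, 25, 15), axes = c(20, 10, 5),
                               texture_sd = 0, seed = 1)
  fe <- shape_features(ell)
  expect_lt(abs(fe[["flatness"]] - 0.25) / 0.25, 0.10)
  expect_equal(fe[["orientation_deg"]], 90)   # major axis along x

  ellz <- simulate_tumor_volume(shape = c(15, 15, 45), axes = c(5, 5, 20),
                                texture_sd = 0, seed = 1)
  expect_equal(shape_features(ellz)[["orientation_deg"]], 0)
})

test_that("rotating a grid-aligned ellipsoid 90 degrees preserves flatness and S/V", {
  a <- simulate_tumor_volume(shape = c(45, 25, 15), axes = c(20, 10, 5),
                             texture_sd = 0, seed = 1)
  b <- simulate_tumor_volume(shape = c(15, 25, 45), axes = c(5, 10, 20),
                             texture_sd = 0, seed = 1)
  fa <- shape_features(a)
  fb <- shape_features(b)
  expect_lt(abs(fa[["flatness"]] - fb[["flatness"]]) / fa[["flatness"]], 0.05)
  expect_lt(abs(fa[["surface_to_volume"]] - fb[["surface_to_volume"]]) /
              fa[["surface_to_volume"]], 0.05)
})

test_that("histogram features follow the linear-interpolation convention", {
  v <- grid_volume(array(1:10, c(10, 1, 1)))
  h <- histogram_features(v)
  expect_equal(h[["p90"]], 9.1)
  expect_equal(h[["p50"]], 5.5)
  expect_equal(h[["mean"]], 5.5)

  hc <- histogram_features(grid_volume(array(4, c(3, 3, 1))))
  expect_equal(unname(hc[c("mean", "sd", "p90")]), c(4, 0, 4))

  set.seed(2)
  hr <- histogram_features(grid_volume(array(rnorm(60), c(5, 4, 3))))
  expect_true(hr[["p10"]] <= hr[["p50"]] && hr[["p50"]] <= hr[["p90"]])
})

test_that("extract_features assembles all families, finite and deterministic", {
  v <- simulate_tumor_volume(shape = c(20, 20, 20), axes = c(7, 6, 5),
                             texture_sd = 12, seed = 8)
  fv <- extract_features(v, n_levels = 8)
  expect_true(all(is.finite(fv)))
  expect_true(all(c("hist_mean", "glszm_grey_level_variance",
                    "glrlm_avg_gln", "laws_L5L5L5", "wavelet_LLL",
                    "shape_flatness") %in% names(fv)))
  expect_identical(fv, extract_features(v, n_levels = 8))

  # intensity shift leaves shape features untouched
  v2 <- tumor_volume(v$img + 50, v$mask, v$spacing)
  shp <- grep("^shape_", names(fv))
  expect_equal(extract_features(v2, n_levels = 8)[shp], fv[shp])
})

test_that("texture features are invariant to intensity shifts after requantization", {
  v <- simulate_tumor_volume(shape = c(16, 16, 16), axes = c(5, 5, 5),
                             texture_sd = 10, seed = 13)
  v2 <- tumor_volume(v$img + 200, v$mask, v$spacing)
  q1 <- quantize(v, 16)
  q2 <- quantize(v2, 16)
  expect_identical(q1, q2)
  expect_identical(glszm_features(glszm(q1, v$mask)),
                   glszm_features(glszm(q2, v2$mask)))
  expect_identical(glrlm_gln(q1, v$mask), glrlm_gln(q2, v2$mask))
})
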