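test_that("the default catalog reproduces the per-family feature counts", {
  cat_def <- build_catalog()
  expect_equal(nrow(cat_def$table), 1004)
  fam <- table(cat_def$table$family)
  expect_equal(unname(fam["first_order"]), 187)
  expect_equal(unname(fam["shape"]), 14)
  expect_equal(unname(fam["glcm"]), 253)
  expect_equal(unname(fam["glrlm"]), 176)
  expect_equal(unname(fam["glszm"]), 165)
  expect_equal(unname(fam["ngtdm"]), 55)
  expect_equal(unname(fam["gldm"]), 154)
  expect_false(anyDuplicated(cat_def$table$id) > 0)
  # id format matches the <imageType>_<family>_<FeatureName> convention
  expect_true("log-sigma-1-0-mm-3D_glszm_SizeZoneNonUniformity" %in% cat_def$table$id)

  expect_equal(nrow(build_catalog(image_types = "original")$table), 104)
  expect_error(build_catalog(families = "glxm"), "unknown family")
  expect_error(build_catalog(image_types = "sobel"), "unknown image type")
})

test_that("the filter bank emits 11 congruent image types with sane limits", {
  v <- fg_volume(array(rnorm(16^3, -800, 30), c(16, 16, 16)))
  f <- apply_filters(v)
  expect_length(f, 11)
  expect_true(all(vapply(f, function(a) identical(dim(a), dim(v$data)), logical(1))))
  # constant input: LoG response vanishes, LLL band preserves the constant
  vc <- fg_volume(array(-700, c(16, 16, 16)))
  fc <- apply_filters(vc, c("log-sigma-1-0-mm-3D", "wavelet-LLL", "wavelet-HHH"))
  expect_lt(max(abs(fc[["log-sigma-1-0-mm-3D"]])), 1e-6 * 700)
  expect_equal(as.numeric(fc[["wavelet-LLL"]]), rep(-700, 16^3), tolerance = 1e-8)
  expect_lt(max(abs(fc[["wavelet-HHH"]])), 1e-8 * 700)
})

test_that("discretisation is min-referenced fixed binning", {
  expect_equal(discretize(c(0, 24.9, 25, 50), bin_width = 25), c(1L, 1L, 2L, 3L))
  expect_equal(discretize(rep(3.5, 10), bin_width = 25), rep(1L, 10))
  x <- rnorm(50)
  expect_identical(discretize(x, bin_width = 0.5), discretize(x + 1000, bin_width = 0.5))
  expect_equal(max(discretize(x, n_bins = 16)), 16L)
  expect_error(discretize(x, bin_width = 0), "positive")
})

test_that("texture matrices match hand-enumerated micro-cases", {
  # 2x1x1 region, levels 1 and 2: one symmetric pair in the x-direction
  lv <- array(c(1L, 2L), c(2, 1, 1))
  m <- region_texture_matrices(lv, 2)
  gl <- m$glcm
  expect_equal(gl[1, 2, 1], 1); expect_equal(gl[2, 1, 1], 1)
  expect_equal(sum(gl), 2)          # all other directions empty
  # single-level region: one GLSZM zone covering the region
  lv2 <- array(1L, c(3, 2, 1))
  z <- region_texture_matrices(lv2, 1)$glszm_zones
  expect_equal(nrow(z), 1)
  expect_equal(z[1, ], c(1L, 6L), ignore_attr = TRUE)
  # constant region: NGTDM coarseness hits the max-coarseness sentinel
  ng <- compute_family_features(region_texture_matrices(lv2, 1), "ngtdm", 6)
  expect_equal(unname(ng["Coarseness"]), 1e6)
  # homogeneous region: joint entropy of the single-cell GLCM is zero
  gf <- compute_family_features(region_texture_matrices(lv2, 1), "glcm", 6)
  expect_equal(unname(gf["JointEntropy"]), 0)
  expect_equal(unname(gf["MaximumProbability"]), 1)
})

test_that("first-order and shape features follow their definitions", {
  vals <- c(-800, -600)
  fo <- compute_family_features(list(vals = vals, levels = discretize(vals, bin_width = 25)),
                                "first_order")
  expect_equal(unname(fo["Mean"]), -700)
  expect_equal(unname(fo["Range"]), 200)
  expect_equal(unname(fo["Minimum"]), -800)
  # 2x2x2 cube at 1 mm: volume 8 mm^3, fully exposed surface 24 mm^2
  co <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  colnames(co) <- NULL
  sh <- compute_family_features(list(coords = co, crop_mask = array(TRUE, c(2, 2, 2)),
                                     spacing = c(1, 1, 1)), "shape")
  expect_equal(unname(sh["VoxelVolume"]), 8)
  expect_equal(unname(sh["SurfaceArea"]), 24)
  expect_equal(unname(sh["Maximum3DDiameter"]), sqrt(3))
})

test_that("region features cover every present region without gaps", {
  catal <- build_catalog(image_types = "original")
  ft <- extract_region_features(small_phantom$ph$volume, small_phantom$atlas, catal)
  expect_equal(dim(ft), c(36, 104))
  expect_equal(sum(is.na(ft)), 0)
  expect_identical(colnames(ft), catal$table$id)
})

test_that("texture features are shift-invariant, first-order means shift", {
  v <- small_phantom$ph$volume
  vshift <- fg_volume(v$data + 100, v$spacing, v$origin)
  catal <- build_catalog(image_types = "original",
                         families = c("first_order", "glcm", "glrlm"))
  f0 <- extract_region_features(v, small_phantom$atlas, catal)
  f1 <- extract_region_features(vshift, small_phantom$atlas, catal)
  tex <- grepl("_glcm_|_glrlm_", colnames(f0))
  expect_equal(f0[, tex], f1[, tex], tolerance = 1e-12)
  expect_equal(f1[, "original_first_order_Mean"],
               f0[, "original_first_order_Mean"] + 100, tolerance = 1e-9)
})

test_that("permuting region labels permutes feature rows identically", {
  at <- small_phantom$atlas
  perm <- c(2:36, 1L)                      # relabel region r -> perm[r]
  lab2 <- at$labels
  lab2[at$labels > 0] <- perm[at$labels[at$labels > 0]]
  at2 <- at; at2$labels <- lab2; at2$table <- fibrograph:::region_table(lab2)
  catal <- build_catalog(image_types = "original", families = "first_order")
  f1 <- extract_region_features(small_phantom$ph$volume, at, catal)
  f2 <- extract_region_features(small_phantom$ph$volume, at2, catal)
  expect_equal(unname(f2[perm, ]), unname(f1), tolerance = 1e-12,
               ignore_attr = TRUE)
})
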