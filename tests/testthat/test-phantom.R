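test_that("identical config and seed give bit-identical phantoms", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), seed = 9)
  a <- generate_phantom(cfg); b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
})

test_that("zero-amplitude classes are statistically indistinguishable", {
  fib <- generate_phantom(phantom_config(grid_shape = c(32, 32, 32), seed = 4,
                                         class_label = "fibrotic",
                                         reticular_amplitude_hu = 0, cyst_density = 0))
  non <- generate_phantom(phantom_config(grid_shape = c(32, 32, 32), seed = 4,
                                         class_label = "non_fibrotic",
                                         ggo_amplitude_hu = 0))
  x <- fib$volume$data[fib$mask$data]
  y <- non$volume$data[non$mask$data]
  p <- if (isTRUE(all.equal(x, y))) 1 else t.test(x, y)$p.value
  expect_gt(p, 0.01)
})

test_that("fibrotic texture variance concentrates basally and peripherally", {
  ph <- generate_phantom(phantom_config(seed = 11))
  at <- build_atlas(ph$mask)
  tab <- atlas_summary(at)
  var_of <- function(rids) {
    v <- ph$volume$data[at$labels %in% rids]
    mean((v - mean(v))^2)
  }
  bp <- tab$region_id[tab$axial_third == "basal" & tab$shell == "peripheral"]
  ac <- tab$region_id[tab$axial_third == "apical" & tab$shell == "central"]
  expect_gt(var_of(bp), var_of(ac))
})

test_that("ground-glass intensity shift scales exactly with its amplitude", {
  mk <- function(A) generate_phantom(phantom_config(
    grid_shape = c(32, 32, 32), seed = 13, class_label = "non_fibrotic",
    ggo_amplitude_hu = A))$volume$data
  v0 <- mk(0); v1 <- mk(120); v2 <- mk(240)
  expect_equal(v2 - v0, 2 * (v1 - v0), tolerance = 1e-10)
})

test_that("degenerate grids are rejected", {
  expect_error(phantom_config(grid_shape = c(16, 96, 96)), "at least 32")
  expect_error(phantom_config(basal_gradient = 1.2), "gradients")
  expect_error(phantom_config(noise_sd_hu = -1), "non-negative")
})

test_that("cohort generation is balanced, deterministic and within scan range", {
  d1 <- file.path(tempdir(), "fg-coh-a")
  man <- generate_cohort(4, 0.5, c(1, 1), out_dir = d1, seed = 2,
                         grid_shape = c(32, 32, 32))
  expect_equal(nrow(man), 4)
  expect_equal(sum(man$label == "fibrotic"), 2)
  expect_true(all(file.exists(man$path)), all(file.exists(man$mask_path)))

  d2 <- file.path(tempdir(), "fg-coh-b"); d3 <- file.path(tempdir(), "fg-coh-c")
  m2 <- generate_cohort(10, 0.5, c(1, 5), out_dir = d2, seed = 3, grid_shape = c(32, 32, 32))
  m3 <- generate_cohort(10, 0.5, c(1, 5), out_dir = d3, seed = 3, grid_shape = c(32, 32, 32))
  expect_equal(nrow(m2), nrow(m3))
  expect_identical(m2$scan_id, m3$scan_id)
  expect_true(all(table(m2$patient_id) >= 1 & table(m2$patient_id) <= 5))
  # every patient's scans share one class
  expect_true(all(tapply(m2$label, m2$patient_id, function(l) length(unique(l))) == 1))
})

test_that("total scan count concentrates around its closed-form expectation", {
  # scans per patient ~ uniform{1..5}: mean 3, variance 2
  d <- file.path(tempdir(), "fg-coh-d")
  man <- generate_cohort(40, 0.5, c(1, 5), out_dir = d, seed = 8,
                         grid_shape = c(32, 32, 32))
  expect_lt(abs(nrow(man) - 40 * 3), 3 * sqrt(40 * 2))
})
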