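test_that("the ten graph statistics match their closed-form values", {
  s <- graph_statistics(c(2, 4, 6, 8))
  expect_length(s, 10)
  expect_equal(unname(s["max"]), 8)
  expect_equal(unname(s["min"]), 2)
  expect_equal(unname(s["median"]), 5)
  expect_equal(unname(s["mean"]), 5)
  expect_equal(unname(s["p10"]), 2.6)
  expect_equal(unname(s["p90"]), 7.4)
  expect_equal(unname(s["iqr"]), 6.5 - 2.9)       # p75 - p15
  expect_equal(unname(s["sd"]), sqrt(5))
  expect_equal(unname(s["skewness"]), 0)
  expect_equal(unname(s["kurtosis"]), 41 / 25 - 3)
  # conventional IQR variant
  s2 <- graph_statistics(c(2, 4, 6, 8), iqr_variant = "p75-p25")
  expect_equal(unname(s2["iqr"]), 6.5 - 3.5)
})

test_that("constant graphs degrade gracefully", {
  s <- graph_statistics(rep(3.2, 7))
  expect_equal(unname(s), c(3.2, 3.2, 3.2, 3.2, 3.2, 3.2, 0, 0, 0, 0))
  expect_error(graph_statistics(c(1, 2, 3)), "at least 4")
  expect_error(graph_statistics(c(1, 2, NA, Inf, 3)), "non-finite")
})

test_that("statistics agree with the sort/moment oracle on random graphs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:36, 1)
    v <- rnorm(n, sd = 10^sample(-2:2, 1))
    expect_equal(graph_statistics(v), oracle_graph_stats(v), tolerance = 1e-10)
  }
})

test_that("adding a constant shifts location statistics only", {
  set.seed(7)
  v <- rnorm(20)
  s0 <- graph_statistics(v); s1 <- graph_statistics(v + 13.5)
  expect_equal(s1[1:6], s0[1:6] + 13.5, tolerance = 1e-9)
  expect_equal(s1[7:10], s0[7:10], tolerance = 1e-9)
})

test_that("graphs assemble per feature with absent-node propagation", {
  set.seed(3)
  tab <- matrix(rnorm(36 * 50), 36, 50,
                dimnames = list(sprintf("r%02d", 1:36), sprintf("f%02d", 1:50)))
  g <- build_graphs(tab)
  expect_length(g, 50)
  expect_length(g[[5]]$nodes, 36)
  # absent regions propagate
  tab2 <- tab; tab2[1:18, ] <- NA
  g2 <- build_graphs(tab2)
  expect_length(g2[[5]]$nodes, 18)
  # permuting table rows leaves each graph's node multiset unchanged
  g3 <- build_graphs(tab[sample(36), ])
  expect_equal(sort(g3[[7]]$nodes), sort(g[[7]]$nodes))
  tab3 <- tab; tab3[4:36, ] <- NA
  expect_error(build_graphs(tab3), "insufficient nodes")
})

test_that("descriptor dimension is 10 x catalog with deterministic naming", {
  set.seed(5)
  ids <- build_catalog(image_types = "original")$table$id
  tab <- matrix(rnorm(36 * 104), 36, 104,
                dimnames = list(sprintf("r%02d", 1:36), ids))
  d <- build_descriptor(build_graphs(tab))
  expect_length(d, 1040)
  expect_equal(names(d)[1:2], paste0(ids[1], "__s", 1:2))
  expect_identical(d, build_descriptor(build_graphs(tab)))
  # full catalog: 10 x 1004
  ids_full <- build_catalog()$table$id
  tabf <- matrix(rnorm(36 * 1004), 36, 1004,
                 dimnames = list(sprintf("r%02d", 1:36), ids_full))
  expect_length(build_descriptor(build_graphs(tabf)), 10040)
})
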