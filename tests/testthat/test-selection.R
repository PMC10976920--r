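test_that("Mann-Whitney p-values behave as specified", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  vals <- c(x, y); lab <- rep(0:1, each = 3)
  expect_equal(mannwhitney_p(vals, lab), 0.1, tolerance = 1e-12)
  # identical samples: p = 1 within tolerance
  same <- c(rnorm(5), rnorm(5)); same[6:10] <- same[1:5]
  expect_gt(mannwhitney_p(same, rep(0:1, each = 5)), 0.95)
  # label swap leaves the two-sided p unchanged
  set.seed(2); v <- rnorm(30); l <- rep(0:1, 15)
  expect_equal(mannwhitney_p(v, l), mannwhitney_p(v, 1 - l), tolerance = 1e-12)
  expect_error(mannwhitney_p(v, rep(1, 30)), "two classes")
})

test_that("top-fraction retention is stable and floor-rounded", {
  p <- runif(10040)
  expect_length(select_top_fraction(p, 0.01), 100)
  # all-equal p: first k indices kept in order
  expect_equal(select_top_fraction(rep(0.5, 500), 0.01), 1:5)
  expect_equal(select_top_fraction(p, 1), order(p, seq_along(p)))
  expect_error(select_top_fraction(p, 0), "fraction")
  expect_error(select_top_fraction(runif(50), 0.01), "too few")
})

test_that("correlation pruning removes the larger-p member", {
  set.seed(4)
  base <- rnorm(40)
  x <- cbind(base, base * 2 + 1e-8, rnorm(40))   # cols 1,2 have r = 1
  keep <- prune_correlated(x, c(0.01, 0.02, 0.5), cutoff = 0.85)
  expect_true(1 %in% keep); expect_false(2 %in% keep); expect_true(3 %in% keep)
  # survivors verified pairwise by brute force
  X <- matrix(rnorm(60 * 40), 60, 40)
  X[, 1:10] <- X[, 1] + matrix(rnorm(60 * 10, sd = 0.1), 60, 10)
  pv <- runif(40)
  surv <- prune_correlated(X, pv, cutoff = 0.85)
  cm <- abs(cor(X[, surv, drop = FALSE]))
  expect_lte(max(cm[upper.tri(cm)]), 0.85)
  # cutoff 1 with no exact collinearity removes nothing
  expect_length(prune_correlated(X, pv, cutoff = 1), 40)
  # zero-variance columns are never pruned by the rule
  Xz <- cbind(rep(1, 30), rnorm(30))
  expect_equal(prune_correlated(Xz, c(0.1, 0.2), 0.85), c(1, 2))
})

test_that("the fitted selector recovers planted elements and nests", {
  set.seed(11)
  n <- 50; D <- 1000
  hits <- 0
  for (rep in 1:20) {
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * D), n, D)
    planted <- 1:5
    X[y == 1, planted] <- X[y == 1, planted] + 2      # 2 SD shift
    sel <- fit_selector(X, y)
    if (all(planted %in% sel$step1)) hits <- hits + 1
    expect_true(all(sel$final %in% sel$step1))
    expect_true(all(sel$step1 %in% seq_len(D)))
    expect_lte(length(sel$final), floor(0.01 * D))
  }
  expect_gte(hits, 19)
  # apply on the training matrix returns the fitted columns
  sel <- fit_selector(X, y)
  expect_identical(apply_selector(sel, X), X[, sel$final, drop = FALSE])
  expect_error(apply_selector(sel, X[, 1:10]), "dimension")
})

test_that("permuted labels retain planted elements at the chance rate", {
  set.seed(21)
  n <- 50; D <- 500; planted <- 1:5
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * D), n, D)
  X[y == 1, planted] <- X[y == 1, planted] + 2
  n_kept <- 0; n_perm <- 200
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    p <- apply(X[, , drop = FALSE], 2, mannwhitney_p, labels = yp)
    kept <- select_top_fraction(p, 0.01)
    n_kept <- n_kept + sum(planted %in% kept)
  }
  # 5 planted x 200 permutations, each kept with prob ~ 1%
  expect_gte(n_kept, qbinom(0.0005, 5 * n_perm, 0.01))
  expect_lte(n_kept, qbinom(0.9995, 5 * n_perm, 0.01))
})
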