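make_planted <- function(n_patients = 20, scans_each = 2, d = 5, shift = 3, seed = 1) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", 1:n_patients), each = scans_each)
  y <- rep(rep(0:1, each = n_patients / 2), each = scans_each)
  X <- matrix(rnorm(length(y) * d), ncol = d)
  X[y == 1, ] <- X[y == 1, ] + shift
  list(X = X, y = y, groups = pid)
}

test_that("grouped folds never split a patient and find separable signal", {
  pl <- make_planted()
  cv <- cross_validate_zoo(pl$X, pl$y, pl$groups, k = 5, seed = 3)
  # grouping contract
  for (p in unique(pl$groups))
    expect_length(unique(cv$folds[pl$groups == p]), 1)
  expect_equal(unname(max(cv$mean_auc)), 1)
  expect_true(all(cv$weights >= 0))
  expect_equal(sum(cv$weights), 1)
})

test_that("permutation-null cross-validation stays near chance", {
  set.seed(17)
  aucs <- numeric(10)
  for (r in 1:10) {
    n <- 80
    pid <- sprintf("P%02d", 1:n)
    y <- sample(rep(0:1, n / 2))
    X <- matrix(rnorm(n * 5), n, 5)
    cv <- cross_validate_zoo(X, y, pid, k = 5, seed = r)
    aucs[r] <- max(cv$mean_auc)
  }
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("greedy ensembling favours a dominant model", {
  set.seed(5)
  n <- 100; y <- rep(0:1, each = n / 2)
  oof <- cbind(A = y * 0.8 + 0.1 + rnorm(n, sd = 0.01),
               B = runif(n), C = runif(n))
  w <- greedy_weighted_ensemble(oof, y)
  expect_gte(unname(w["A"]), 0.8)
  expect_equal(sum(w), 1)
  # ensemble out-of-fold AUC never falls below the best single model
  ens <- as.numeric(oof %*% w)
  expect_gte(fg_auc(ens, y), max(apply(oof, 2, fg_auc, labels = y)) - 1e-9)
})

test_that("duplicated models leave the ensemble AUC unchanged", {
  set.seed(6)
  n <- 60; y <- rep(0:1, each = n / 2)
  p <- plogis(rnorm(n) + 2 * y)
  oof <- cbind(M1 = p, M2 = p)
  w <- greedy_weighted_ensemble(oof, y)
  expect_equal(sum(w), 1)
  expect_equal(fg_auc(as.numeric(oof %*% w), y), fg_auc(p, y))
  # constant probabilities: uniform weights with a warning
  expect_warning(wc <- greedy_weighted_ensemble(cbind(a = rep(0.5, n), b = rep(0.2, n)), y),
                 "constant")
  expect_equal(unname(wc), c(0.5, 0.5))
})

test_that("the final refit model is deterministic and separates training data", {
  pl <- make_planted(seed = 9)
  zoo <- zoo_default(9)
  cv <- cross_validate_zoo(pl$X, pl$y, pl$groups, k = 5, zoo = zoo, seed = 9)
  fit <- train_final(pl$X, pl$y, cv, zoo = zoo, seed = 9)
  pr <- predict(fit, pl$X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(mean((pr >= 0.5) == (pl$y == 1)), 1)  # 100% training accuracy
  # identical rows give identical probabilities
  X2 <- pl$X[c(1, 1, 2), ]
  p2 <- predict(fit, X2)
  expect_equal(p2[1], p2[2])
  expect_error(predict(fit, pl$X[, 1:2]), "dimension mismatch")
})
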