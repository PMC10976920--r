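test_that("grouped random splits allocate patients 80/20 per class", {
  man <- data.frame(scan_id = sprintf("s%02d", 1:40),
                    patient_id = rep(sprintf("P%02d", 1:20), each = 2),
                    label = rep(c("fibrotic", "non_fibrotic"), each = 20),
                    stringsAsFactors = FALSE)
  sp <- make_random_splits(man, n_splits = 5, seed = 1)
  for (s in sp$splits) {
    te_p <- unique(man$patient_id[man$scan_id %in% s$test])
    tr_p <- unique(man$patient_id[man$scan_id %in% s$train])
    expect_length(te_p, 4)          # 2 per class out of 10
    expect_length(intersect(te_p, tr_p), 0)
    te_lab <- man$label[match(te_p, man$patient_id)]
    expect_setequal(unique(te_lab), c("fibrotic", "non_fibrotic"))
  }
  expect_identical(make_random_splits(man, 5, seed = 1), sp)
  # a multi-scan patient never straddles the partition
  man5 <- rbind(man, data.frame(scan_id = sprintf("x%d", 1:3), patient_id = "P01",
                                label = "fibrotic", stringsAsFactors = FALSE))
  sp5 <- make_random_splits(man5, n_splits = 5, seed = 2)
  for (s in sp5$splits) {
    sc <- c(s$train[man5$patient_id[match(s$train, man5$scan_id)] == "P01"],
            s$test[man5$patient_id[match(s$test, man5$scan_id)] == "P01"])
    expect_length(sc, 5)
    on_test <- sum(sc %in% s$test)
    expect_true(on_test == 0 || on_test == 5)
  }
})

test_that("patient aggregation is the arithmetic scan mean", {
  expect_equal(unname(patient_aggregate(c(0.2, 0.4), c("a", "a"))), 0.3)
  expect_equal(unname(patient_aggregate(0.7, "a")), 0.7)
  # straddling scans can flip the patient past the threshold
  agg <- patient_aggregate(c(0.45, 0.65), c("p", "p"))
  expect_equal(unname(agg), 0.55)
  expect_true(agg >= 0.5)
  expect_error(patient_aggregate(c(0.1, 0.2), c("a", NA)), "mapped")
})

test_that("confusion-matrix metrics match hand arithmetic", {
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(0.9, 9), 0.1, rep(0.1, 8), 0.9, 0.9)   # TP 9, FN 1, TN 8, FP 2
  m <- binary_metrics(p, y)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["ppv"]), 9 / 11)
  expect_equal(unname(m["npv"]), 8 / 9)
  expect_equal(unname(binary_metrics(y, y)), rep(1, 5))
  ap <- binary_metrics(rep(1, 20), y)
  expect_equal(unname(ap["sensitivity"]), 1)
  expect_equal(unname(ap["specificity"]), 0)
  # a probability exactly at the threshold counts positive
  expect_equal(unname(binary_metrics(0.5, 1)["sensitivity"]), 1)
})

test_that("structural-component AUC equals all-pairs concordance", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)            # induce ties
    expect_equal(auc_and_delong(p, labels = y)$auc_A, oracle_auc(p, y),
                 tolerance = 1e-12)
  }
})

test_that("DeLong comparison is symmetric with sane degenerate cases", {
  set.seed(32)
  y <- rep(0:1, each = 20)
  pa <- plogis(rnorm(40) + y); pb <- plogis(rnorm(40) + 0.5 * y)
  expect_equal(auc_and_delong(y, labels = y)$auc_A, 1)
  self <- auc_and_delong(pa, pa, y)
  expect_equal(self$z, 0); expect_equal(self$p, 1)
  ab <- auc_and_delong(pa, pb, y); ba <- auc_and_delong(pb, pa, y)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  # independent implementation cross-check
  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(y, pa, quiet = TRUE),
                       pROC::roc(y, pb, quiet = TRUE), method = "delong")
  expect_equal(ab$p, pr$p.value, tolerance = 1e-9)
})

test_that("bootstrap CIs behave like the binomial closed form", {
  set.seed(33)
  n <- 200
  y <- rep(0:1, each = n / 2)
  acc_target <- 0.9
  correct <- rbinom(n, 1, acc_target)
  p <- ifelse(correct == 1, y, 1 - y) * 0.8 + 0.1
  groups <- sprintf("P%03d", seq_len(n))    # one scan per patient
  ci <- bootstrap_ci(function(pp, yy) binary_metrics(pp, yy)["accuracy"],
                     p, y, groups, reps = 1000, seed = 5)
  width <- ci[2] - ci[1]
  acc_hat <- mean((p >= 0.5) == (y == 1))
  bin_width <- 2 * 1.96 * sqrt(acc_hat * (1 - acc_hat) / n)
  expect_gt(width, 0.7 * bin_width)
  expect_lt(width, 1.3 * bin_width)
  # determinism and the perfectly-separable degenerate case
  ci2 <- bootstrap_ci(function(pp, yy) binary_metrics(pp, yy)["accuracy"],
                      p, y, groups, reps = 1000, seed = 5)
  expect_identical(ci, ci2)
  ci3 <- bootstrap_ci(fg_auc, y, y, groups, reps = 200, seed = 1)
  expect_equal(as.numeric(ci3), c(1, 1))
})

test_that("patient-level AUC ignores duplicated identical scans", {
  y <- rep(0:1, each = 6)
  p <- plogis(rnorm(12) + y)
  pid <- sprintf("P%02d", 1:12)
  base <- fg_auc(as.numeric(patient_aggregate(p, pid)),
                 as.numeric(patient_aggregate(y, pid)))
  p2 <- c(p, p[3]); y2 <- c(y, y[3]); pid2 <- c(pid, pid[3])
  dup <- fg_auc(as.numeric(patient_aggregate(p2, pid2)),
                as.numeric(patient_aggregate(y2, pid2)))
  expect_equal(dup, base)
})
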