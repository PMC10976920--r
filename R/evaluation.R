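#' AUC by rank concordance
#'
#' Probability that a positive scan outranks a negative one, ties counting
#' one half (the Mann-Whitney concordance estimator).
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1 or two-level factor).
#' @return AUC in `[0, 1]`, or NA if a class is absent.
#' @export
fg_auc <- function(probs, labels) {
  y <- as.integer(labels == 1)
  if (length(unique(y)) < 2) return(NA_real_)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grouped 80/20 random split plans
#'
#' Generates `n_splits` independent train/test partitions at the patient
#' level: per class, patients are shuffled and allocated 80/20 by patient
#' count (rounded to nearest, at least one test patient per class), and all
#' scans of a patient follow the patient.
#'
#' @param manifest cohort manifest data.frame with columns `scan_id`,
#'   `patient_id`, `label`.
#' @param n_splits number of random splits (default 5).
#' @param train_fraction fraction of patients per class in training
#'   (default 0.8).
#' @param seed RNG seed; split s uses `seed + s - 1`.
#' @return an `fg_splits`: list of `(train, test)` scan-id vectors.
#' @export
make_random_splits <- function(manifest, n_splits = 5, train_fraction = 0.8,
                               seed = 1L) {
  stopifnot(all(c("scan_id", "patient_id", "label") %in% names(manifest)))
  pts <- unique(manifest[, c("patient_id", "label")])
  if (any(table(pts$label) < 5)) stop("need at least 5 patients per class")
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(seed + s - 1L)
    test_p <- character(0)
    for (cl in sort(unique(pts$label))) {
      p <- sample(pts$patient_id[pts$label == cl])
      n_test <- max(1L, round((1 - train_fraction) * length(p)))
      if (n_test >= length(p)) stop("class emptied on the training side")
      test_p <- c(test_p, p[seq_len(n_test)])
    }
    te <- manifest$patient_id %in% test_p
    splits[[s]] <- list(train = manifest$scan_id[!te], test = manifest$scan_id[te])
  }
  structure(list(splits = splits, n_splits = n_splits,
                 train_fraction = train_fraction, seed = seed),
            class = "fg_splits")
}

#' @exportS3Method base::print
print.fg_splits <- function(x, ...) {
  cat(sprintf("<fg_splits> %d grouped splits, train fraction %.2f\n",
              x$n_splits, x$train_fraction))
  for (s in seq_len(x$n_splits))
    cat(sprintf("  split %d: %d train / %d test scans\n", s,
                length(x$splits[[s]]$train), length(x$splits[[s]]$test)))
  invisible(x)
}

#' Average scan probabilities per patient
#'
#' @param scan_probs per-scan probabilities.
#' @param patients patient id per scan.
#' @return named vector of patient-level probabilities (arithmetic mean of
#'   the patient's scans).
#' @export
patient_aggregate <- function(scan_probs, patients) {
  if (length(scan_probs) != length(patients)) stop("every scan must be mapped to a patient")
  if (anyNA(patients)) stop("every scan must be mapped to a patient")
  out <- tapply(scan_probs, patients, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Confusion-matrix metrics at a decision threshold
#'
#' A probability exactly at the threshold is classified positive. Metrics
#' whose denominator is empty are returned as NA.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold (default 0.5).
#' @return named vector: accuracy, sensitivity, specificity, ppv, npv.
#' @export
binary_metrics <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stop("empty input")
  y <- as.integer(labels == 1)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(accuracy = (tp + tn) / length(y),
    sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

# DeLong structural components: V10 (per positive), V01 (per negative)
delong_components <- function(probs, y) {
  xs <- probs[y == 1]; ys <- probs[y == 0]
  m <- length(xs); n <- length(ys)
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' AUC and paired DeLong comparison
#'
#' Computes the AUC of one probability vector via the structural-component
#' construction, and, when a second vector on the same scans is supplied,
#' the two-sided DeLong test of equal AUCs for paired correlated ROC
#' curves. Zero variance of the AUC difference (e.g. identical
#' predictions) gives z = 0, p = 1.
#'
#' @param probs_A probabilities of model A.
#' @param probs_B optional probabilities of model B on the same scans.
#' @param labels binary labels (0/1).
#' @return list with `auc_A` and, when B is given, `auc_B`, `z`, `p`.
#' @export
auc_and_delong <- function(probs_A, probs_B = NULL, labels) {
  y <- as.integer(labels == 1)
  if (length(unique(y)) < 2) stop("both classes required")
  ca <- delong_components(probs_A, y)
  if (is.null(probs_B)) return(list(auc_A = ca$auc))
  stopifnot(length(probs_B) == length(probs_A))
  cb <- delong_components(probs_B, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v) || v <= 1e-16) {
    z <- 0; p <- 1
  } else {
    z <- (ca$auc - cb$auc) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_A = ca$auc, auc_B = cb$auc, z = z, p = p)
}

#' Patient-resampled bootstrap confidence interval
#'
#' Resamples patients with replacement (each drawn patient contributes all
#' its scans), recomputes the metric on the resampled scan set, and returns
#' the percentile interval. Degenerate resamples containing a single class
#' are redrawn and counted.
#'
#' @param metric_fn function(probs, labels) -> scalar.
#' @param probs per-scan probabilities.
#' @param labels per-scan binary labels.
#' @param groups per-scan patient ids.
#' @param reps bootstrap replicates (>= 100; default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return numeric `(lo, hi)` with attributes `n_degenerate` and `point`.
#' @export
bootstrap_ci <- function(metric_fn, probs, labels, groups, reps = 1000,
                         level = 0.95, seed = 1L) {
  if (reps < 100) stop("reps must be at least 100")
  pts <- unique(groups)
  scans_of <- split(seq_along(groups), groups)
  set.seed(seed)
  stat <- rep(NA_real_, reps)
  n_degen <- 0L
  for (b in seq_len(reps)) {
    for (try in 1:100) {
      draw <- sample(pts, length(pts), replace = TRUE)
      idx <- unlist(scans_of[draw], use.names = FALSE)
      if (length(unique(labels[idx])) == 2) break
      n_degen <- n_degen + 1L
    }
    stat[b] <- metric_fn(probs[idx], labels[idx])
  }
  if (mean(is.na(stat)) > 0.5) stop("metric undefined on more than half of the resamples")
  alpha <- (1 - level) / 2
  ci <- quantile(stat, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE, type = 7)
  attr(ci, "n_degenerate") <- n_degen
  attr(ci, "point") <- metric_fn(probs, labels)
  ci
}
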