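#' Two-sided Mann-Whitney U p-value
#'
#' Exact distribution when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values numeric vector of observations.
#' @param labels binary vector (two groups), same length.
#' @return two-sided p-value in (0, 1].
#' @export
mannwhitney_p <- function(values, labels) {
  g <- unique(labels)
  if (length(g) != 2) stop("exactly two classes required")
  x <- values[labels == g[1]]; y <- values[labels == g[2]]
  if (length(x) < 2 || length(y) < 2) stop("both classes need at least 2 observations")
  ex <- (length(x) + length(y) <= 20) && !anyDuplicated(values)
  p <- suppressWarnings(
    wilcox.test(x, y, exact = ex, correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Retain the smallest-p fraction of descriptor elements
#'
#' @param pvalues per-element p-values.
#' @param fraction fraction to retain, in (0, 1]; `k = floor(fraction * D)`
#'   elements are kept, ties broken by ascending element index.
#' @return integer vector of retained indices, in ascending-p order.
#' @export
select_top_fraction <- function(pvalues, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  D <- length(pvalues)
  k <- floor(fraction * D)
  if (k < 1) stop("too few elements for the requested fraction")
  order(pvalues, seq_len(D))[seq_len(k)]
}

#' Prune correlated elements, keeping the more significant member
#'
#' Candidates are visited in ascending-p order (ties by index); a candidate
#' is dropped when its absolute Pearson correlation with any surviving
#' element exceeds the cutoff, so the larger-p member of each offending pair
#' is removed. Zero-variance elements have correlation defined as 0 and are
#' never pruned by this rule.
#'
#' @param x matrix scans x candidate elements.
#' @param pvalues p-values of the candidate columns.
#' @param cutoff absolute Pearson r threshold (default 0.85).
#' @return indices (into the columns of `x`) of the survivors.
#' @export
prune_correlated <- function(x, pvalues, cutoff = 0.85) {
  stopifnot(ncol(x) == length(pvalues), ncol(x) >= 1)
  ord <- order(pvalues, seq_along(pvalues))
  sds <- apply(x, 2, sd)
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      r <- if (sds[i] == 0 || sds[j] == 0) 0 else cor(x[, i], x[, j])
      if (is.na(r)) r <- 0
      if (abs(r) > cutoff) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  sort(keep)
}

#' Fit the two-step descriptor selector on training scans
#'
#' Step 1 ranks all descriptor elements by the two-sided Mann-Whitney U
#' p-value between the classes (scan-level observations) and keeps the top
#' fraction; step 2 prunes the retained set so that no surviving pair has
#' absolute Pearson correlation above the cutoff, always discarding the
#' larger-p member.
#'
#' @param descriptors matrix scans x elements (training scans only).
#' @param labels binary class labels per scan.
#' @param fraction step-1 retention fraction (default 0.01).
#' @param cutoff step-2 correlation cutoff (default 0.85).
#' @return an `fg_selector` with p-values, the step-1 and final index sets.
#' @export
fit_selector <- function(descriptors, labels, fraction = 0.01, cutoff = 0.85) {
  stopifnot(is.matrix(descriptors), nrow(descriptors) == length(labels))
  p <- apply(descriptors, 2, mannwhitney_p, labels = labels)
  step1 <- select_top_fraction(p, fraction)
  surv <- prune_correlated(descriptors[, step1, drop = FALSE], p[step1], cutoff)
  final <- sort(step1[surv])
  structure(list(pvalues = p, step1 = sort(step1), final = final,
                 element_ids = colnames(descriptors),
                 fraction = fraction, cutoff = cutoff),
            class = "fg_selector")
}

#' Project descriptors onto a fitted selector's final element set
#'
#' @param selector an `fg_selector`.
#' @param descriptors matrix scans x elements with the fitted dimension.
#' @return reduced matrix scans x |final|.
#' @export
apply_selector <- function(selector, descriptors) {
  stopifnot(inherits(selector, "fg_selector"))
  if (ncol(descriptors) != length(selector$pvalues))
    stop("descriptor dimension does not match the fitted selector")
  descriptors[, selector$final, drop = FALSE]
}

#' @exportS3Method base::print
print.fg_selector <- function(x, ...) {
  cat(sprintf("<fg_selector> %d elements -> top %d (fraction %.3g) -> %d after |r| <= %.2f pruning\n",
              length(x$pvalues), length(x$step1), x$fraction,
              length(x$final), x$cutoff))
  invisible(x)
}
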