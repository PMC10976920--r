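#' Assemble per-feature lung graphs from a region feature table
#'
#' One lung graph per catalog feature: the feature's value on every atlas
#' region forms the graph's node set (at most 36 nodes); absent regions
#' propagate as absent nodes.
#'
#' @param table region feature matrix from [extract_region_features()].
#' @return an `fg_graphs` object (features x regions value matrix with the
#'   catalog attached).
#' @export
build_graphs <- function(table) {
  stopifnot(is.matrix(table))
  present <- rowSums(!is.na(table)) > 0
  if (sum(present) < 4) stop("insufficient nodes: fewer than 4 present regions")
  structure(list(values = t(table), region_present = present,
                 catalog = attr(table, "catalog")),
            class = "fg_graphs")
}

#' @exportS3Method base::print
print.fg_graphs <- function(x, ...) {
  cat(sprintf("<fg_graphs> %d graphs, %d/%d present nodes\n",
              nrow(x$values), sum(x$region_present), ncol(x$values)))
  invisible(x)
}

#' @export
length.fg_graphs <- function(x) nrow(x$values)

#' @export
`[[.fg_graphs` <- function(x, i) {
  v <- x$values[i, ]
  list(feature_id = rownames(x$values)[i], nodes = v[!is.na(v)])
}

STAT_NAMES <- c("max", "min", "median", "p10", "p90", "mean", "sd", "iqr",
                "skewness", "kurtosis")

#' Ten summary statistics of a lung graph
#'
#' Over the present nodes: maximum, minimum, median, 10th and 90th
#' percentile, mean, population standard deviation, interquartile range
#' (p75 - p15 by default, with a conventional p75 - p25 switch),
#' Fisher-Pearson skewness g1 and excess kurtosis g2. Percentiles use
#' linear interpolation between closest ranks (index `q * (n - 1)`).
#' Constant graphs have sd = iqr = 0 and skewness/kurtosis defined as 0.
#'
#' @param graph numeric vector of node values (NAs = absent nodes), or a
#'   graph from [build_graphs()].
#' @param iqr_variant `"p75-p15"` (default) or `"p75-p25"`.
#' @return named numeric vector of length 10.
#' @export
graph_statistics <- function(graph, iqr_variant = c("p75-p15", "p75-p25")) {
  iqr_variant <- match.arg(iqr_variant)
  v <- if (is.list(graph)) graph$nodes else graph
  v <- v[!is.na(v)]
  if (length(v) < 4) stop("insufficient nodes: at least 4 required")
  if (any(!is.finite(v))) stop("non-finite node values")
  lo_q <- if (iqr_variant == "p75-p15") 0.15 else 0.25
  qs <- quantile(v, c(0.1, lo_q, 0.5, 0.75, 0.9), type = 7, names = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  s <- sqrt(m2)
  sk <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0
  stats::setNames(c(max(v), min(v), qs[3], qs[1], qs[5], m, s, qs[4] - qs[2], sk, ku),
                  STAT_NAMES)
}

#' Concatenate graph statistics into the lung descriptor
#'
#' Computes the 10 statistics for every graph, in catalog order, and
#' concatenates them into a single vector of dimension 10 x |catalog|
#' (10040 under the default catalog). Element names follow
#' `<feature_id>__s<k>`.
#'
#' @param graphs an `fg_graphs` object.
#' @param iqr_variant passed to [graph_statistics()].
#' @return named numeric vector.
#' @export
build_descriptor <- function(graphs, iqr_variant = "p75-p15") {
  stopifnot(inherits(graphs, "fg_graphs"))
  if (!is.null(graphs$catalog) && nrow(graphs$values) != nrow(graphs$catalog$table))
    stop("graph count inconsistent with catalog")
  V <- graphs$values
  nf <- nrow(V)
  out <- matrix(NA_real_, nf, 10)
  for (i in seq_len(nf)) out[i, ] <- graph_statistics(V[i, ], iqr_variant)
  ids <- rownames(V)
  vec <- as.numeric(t(out))
  names(vec) <- paste0(rep(ids, each = 10), "__s", rep(1:10, nf))
  vec
}
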