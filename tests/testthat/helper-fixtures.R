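# Shared fixtures, built once per test run.

# small fibrotic phantom with its segmentation-derived atlas
small_phantom <- local({
  ph <- generate_phantom(phantom_config(grid_shape = c(48, 48, 48), seed = 7))
  mask <- extract_lung_mask(ph$volume)
  list(ph = ph, mask = mask, atlas = build_atlas(mask))
})

# a tiny cohort on disk, reused by pipeline-level tests
tiny_cohort <- local({
  dir <- file.path(tempdir(), "fg-tiny-cohort")
  if (!file.exists(file.path(dir, "manifest.csv"))) {
    generate_cohort(12, 0.5, c(1, 3), out_dir = dir, seed = 42,
                    grid_shape = c(48, 48, 48))
  }
  read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
})

tiny_config <- function(n_splits = 3, ...) {
  pipeline_config(catalog = build_catalog(image_types = "original"),
                  bootstrap_reps = 100, n_splits = n_splits, seed = 42, ...)
}

# Independent oracle for the ten graph statistics: closest-rank linear
# interpolation percentiles from an explicit sort, and direct moment sums.
oracle_percentile <- function(v, q) {
  v <- sort(v); n <- length(v)
  h <- q * (n - 1)
  lo <- floor(h) + 1; hi <- ceiling(h) + 1
  v[lo] + (h - floor(h)) * (v[hi] - v[lo])
}

oracle_graph_stats <- function(v, lo_q = 0.15) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  c(max = max(v), min = min(v),
    median = oracle_percentile(v, 0.5),
    p10 = oracle_percentile(v, 0.1), p90 = oracle_percentile(v, 0.9),
    mean = m, sd = sqrt(m2),
    iqr = oracle_percentile(v, 0.75) - oracle_percentile(v, lo_q),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# brute-force AUC: mean concordance over all positive x negative pairs
oracle_auc <- function(probs, y) {
  pos <- probs[y == 1]; neg <- probs[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); pooled <- c(x, y); n <- length(pooled)
  idx <- utils::combn(n, nx)
  ustat <- function(first) {
    r <- rank(pooled)
    sum(r[first]) - nx * (nx + 1) / 2
  }
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  us <- apply(idx, 2, function(f) sum(rank(pooled)[f]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}
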