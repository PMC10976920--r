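#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end pipeline. The defaults
#' are the published operating point: top 1\% Mann-Whitney retention,
#' |r| > 0.85 pruning, fivefold grouped cross-validation, five 80/20
#' patient-grouped random splits, decision threshold 0.5 and 1000 bootstrap
#' replicates.
#'
#' @param catalog an [build_catalog()] result (defaults to the full
#'   1004-feature catalog).
#' @param fraction,cutoff selection thresholds.
#' @param cv_folds,n_splits,train_fraction resampling design.
#' @param bootstrap_reps bootstrap replicates for the 95\% CIs.
#' @param threshold decision threshold for the confusion-matrix metrics.
#' @param iqr_variant graph-statistic IQR convention (see
#'   [graph_statistics()]).
#' @param ensemble_iterations greedy ensemble bag size.
#' @param seed master seed; every stage derives its stream from it.
#' @param workdir optional cache directory: the descriptor matrix is stored
#'   there and reused on rerun.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(catalog = build_catalog(), fraction = 0.01,
                            cutoff = 0.85, cv_folds = 5, n_splits = 5,
                            train_fraction = 0.8, bootstrap_reps = 1000,
                            threshold = 0.5, iqr_variant = "p75-p15",
                            ensemble_iterations = 25L, seed = 1L,
                            workdir = NULL) {
  stopifnot(fraction > 0, fraction <= 1, cutoff > 0, cutoff <= 1,
            cv_folds >= 2, n_splits >= 1,
            train_fraction > 0, train_fraction < 1, bootstrap_reps >= 100)
  structure(list(catalog = catalog, fraction = fraction, cutoff = cutoff,
                 cv_folds = cv_folds, n_splits = n_splits,
                 train_fraction = train_fraction,
                 bootstrap_reps = bootstrap_reps, threshold = threshold,
                 iqr_variant = iqr_variant,
                 ensemble_iterations = as.integer(ensemble_iterations),
                 seed = as.integer(seed), workdir = workdir),
            class = "pipeline_config")
}

#' Compute per-scan lung descriptors for a cohort
#'
#' For each manifest row: read the volume (and mask, or segment one),
#' resample to 1 mm isotropic voxels, build the 36-region atlas, extract
#' the region feature table and condense it into the graph descriptor.
#'
#' @param manifest manifest data.frame (or path to a manifest CSV) with
#'   columns `scan_id`, `patient_id`, `path`, `label` and optionally
#'   `mask_path`.
#' @param config a [pipeline_config()].
#' @param verbose print per-scan progress.
#' @return matrix scans x descriptor elements, rownames = scan ids.
#' @export
compute_descriptors <- function(manifest, config = pipeline_config(),
                                verbose = FALSE) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  cache <- if (!is.null(config$workdir))
    file.path(config$workdir, "descriptors.rds") else NULL
  if (!is.null(cache) && file.exists(cache)) {
    D <- readRDS(cache)
    if (identical(rownames(D), manifest$scan_id)) return(D)
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    vol <- resample_isotropic(read_volume(manifest$path[i]), 1)
    mask <- if (!is.null(manifest$mask_path) && nzchar(manifest$mask_path[i]) &&
                file.exists(manifest$mask_path[i])) {
      m <- resample_isotropic(read_volume(manifest$mask_path[i], mask = TRUE), 1)
      if (is.null(m$lung)) label_lungs(m) else m
    } else extract_lung_mask(vol)
    atlas <- build_atlas(mask)
    ft <- extract_region_features(vol, atlas, config$catalog)
    rows[[i]] <- build_descriptor(build_graphs(ft), config$iqr_variant)
    if (verbose) message(sprintf("[%d/%d] %s", i, nrow(manifest), manifest$scan_id[i]))
  }
  D <- do.call(rbind, rows)
  rownames(D) <- manifest$scan_id
  if (!is.null(cache)) {
    dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
    saveRDS(D, cache)
  }
  D
}

# assign left/right labels to an unlabelled mask by connected components
label_lungs <- function(mask) {
  d <- dim(mask$data)
  lab <- array(cpp_cc_label(as.logical(mask$data), d, 6L), d)
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[1:min(2, length(sizes))]
  if (length(keep) < 2) stop("lungs not separable in provided mask")
  lung <- array(0L, d)
  cx <- numeric(2)
  for (k in 1:2) {
    lung[lab == keep[k]] <- k
    cx[k] <- mean(arrayInd(which(lab == keep[k]), d)[, 1])
  }
  if (cx[1] > cx[2]) lung <- array(c(0L, 2L, 1L)[lung + 1L], d)
  fg_mask(lung > 0, mask$spacing, mask$origin, lung = lung)
}

#' Run the full lung-graph pipeline on a cohort
#'
#' Executes descriptor computation, then per random split: two-step feature
#' selection on the training scans, grouped cross-validation of the zoo,
#' greedy weighted ensembling, final refit and test-set evaluation at scan
#' and patient level with bootstrap CIs and a DeLong comparison of the
#' ensemble against the best single model.
#'
#' @param manifest cohort manifest (data.frame or CSV path).
#' @param config a [pipeline_config()].
#' @param verbose progress messages.
#' @param splits optional precomputed [make_random_splits()] plan that
#'   overrides the seeded default (e.g. to evaluate a fixed partition).
#' @return a `fibro_report`: per-split metric tables, per-scan
#'   probabilities, training artifacts and the config.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), verbose = FALSE,
                         splits = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  y_all <- as.integer(manifest$label == "fibrotic")
  D <- compute_descriptors(manifest, config, verbose = verbose)
  if (is.null(splits))
    splits <- make_random_splits(manifest, config$n_splits, config$train_fraction,
                                 seed = config$seed)
  stopifnot(inherits(splits, "fg_splits"), length(splits$splits) >= config$n_splits)
  metric_rows <- list(); prob_rows <- list(); artifacts <- list()
  for (s in seq_len(config$n_splits)) {
    sp <- splits$splits[[s]]
    tr <- manifest$scan_id %in% sp$train
    te <- !tr
    sel <- fit_selector(D[tr, , drop = FALSE], y_all[tr],
                        fraction = config$fraction, cutoff = config$cutoff)
    Xtr <- apply_selector(sel, D[tr, , drop = FALSE])
    Xte <- apply_selector(sel, D[te, , drop = FALSE])
    zoo <- zoo_default(config$seed + s)
    cv <- cross_validate_zoo(Xtr, y_all[tr], manifest$patient_id[tr],
                             k = config$cv_folds, zoo = zoo,
                             seed = config$seed + s,
                             ensemble_iterations = config$ensemble_iterations)
    fit <- train_final(Xtr, y_all[tr], cv, zoo = zoo, seed = config$seed + s)
    p_te <- predict(fit, Xte)
    # best single model, refit alone, for the DeLong comparison
    single_cv <- cv; single_cv$weights[] <- 0; single_cv$weights[cv$chosen] <- 1
    fit1 <- train_final(Xtr, y_all[tr], single_cv, zoo = zoo, seed = config$seed + s)
    p1_te <- predict(fit1, Xte)
    dl <- auc_and_delong(p_te, p1_te, y_all[te])

    pts_te <- manifest$patient_id[te]
    p_pat <- patient_aggregate(p_te, pts_te)
    y_pat <- patient_aggregate(y_all[te], pts_te)
    lvl <- list(scan = list(p = p_te, y = y_all[te], g = pts_te),
                patient = list(p = as.numeric(p_pat), y = as.integer(y_pat),
                               g = names(p_pat)))
    for (lv in names(lvl)) {
      z <- lvl[[lv]]
      bm <- binary_metrics(z$p, z$y, config$threshold)
      met <- c(auc = fg_auc(z$p, z$y), bm)
      cis <- lapply(stats::setNames(names(met), names(met)), function(mn) {
        fn <- if (mn == "auc") function(p, y) fg_auc(p, y) else
          function(p, y) binary_metrics(p, y, config$threshold)[[mn]]
        tryCatch(
          bootstrap_ci(fn, z$p, z$y, z$g, reps = config$bootstrap_reps,
                       seed = config$seed + 1000L * s),
          error = function(e) c(NA_real_, NA_real_))   # metric undefined
      })
      metric_rows[[length(metric_rows) + 1]] <- data.frame(
        split = s, level = lv, metric = names(met), value = unname(met),
        ci_lo = vapply(cis, `[`, numeric(1), 1),
        ci_hi = vapply(cis, `[`, numeric(1), 2),
        row.names = NULL)
    }
    prob_rows[[length(prob_rows) + 1]] <- data.frame(
      split = s, scan_id = manifest$scan_id[te], patient_id = pts_te,
      label = y_all[te], prob = p_te, row.names = NULL)
    artifacts[[s]] <- list(selector = sel, cv = cv, model = fit,
                           delong_vs_best_single = dl)
  }
  metrics <- do.call(rbind, metric_rows)
  structure(list(metrics = metrics, scan_probs = do.call(rbind, prob_rows),
                 artifacts = artifacts, splits = splits, config = config,
                 manifest = manifest),
            class = "fibro_report")
}

#' Mean and SD of a report metric over splits
#'
#' @param report a `fibro_report`.
#' @param level `"scan"` or `"patient"`.
#' @return data.frame with one row per metric.
#' @export
report_summary <- function(report, level = c("scan", "patient")) {
  level <- match.arg(level)
  m <- report$metrics[report$metrics$level == level, ]
  ag <- aggregate(value ~ metric, m, function(v) c(mean = mean(v), sd = sd(v)))
  data.frame(metric = ag$metric, mean = ag$value[, "mean"], sd = ag$value[, "sd"])
}

#' @exportS3Method base::print
print.fibro_report <- function(x, ...) {
  cat(sprintf("<fibro_report> %d splits, %d scans, %d patients\n",
              x$config$n_splits, nrow(x$manifest),
              length(unique(x$manifest$patient_id))))
  for (lv in c("scan", "patient")) {
    cat(sprintf("\n%s-level (mean +/- SD over splits):\n", lv))
    s <- report_summary(x, lv)
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
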