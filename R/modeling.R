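# ---------------------------------------------------------------------------
# Model zoo: each spec is list(id, grid = list of hyper settings,
# fit(X, y, pars, seed) -> model, prob(model, X) -> P(positive)).
# X is standardised with training statistics inside fit for the
# scale-sensitive learners.

zscale <- function(X, center, scale) sweep(sweep(X, 2, center), 2, scale, "/")

fix_names <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

fit_scaler <- function(X) {
  ctr <- colMeans(X); sc <- apply(X, 2, sd); sc[sc == 0] <- 1
  list(center = ctr, scale = sc)
}

#' Default classifier zoo
#'
#' Eight representative learners covering boosting, bagging, randomized
#' trees, nearest-neighbour (uniform and distance weights), neural, kernel
#' and linear families, each with a small fixed hyper-parameter grid
#' searched inside cross-validation.
#'
#' @param seed common seed for the stochastic learners.
#' @return list of model specifications (class `fg_zoo`).
#' @export
zoo_default <- function(seed = 1L) {
  specs <- list(
    list(id = "GradientBoosting",
         grid = list(list(max_depth = 2), list(max_depth = 3)),
         fit = function(X, y, pars, seed) {
           xgboost::xgb.train(
             params = list(objective = "binary:logistic", eta = 0.3,
                           max_depth = pars$max_depth, nthread = 1,
                           seed = seed),
             data = xgboost::xgb.DMatrix(X, label = y), nrounds = 50, verbose = 0)
         },
         prob = function(m, X) predict(m, xgboost::xgb.DMatrix(X))),
    list(id = "RandomForest",
         grid = list(list(mtry_frac = 0.5)),
         fit = function(X, y, pars, seed) {
           ranger::ranger(x = fix_names(X), y = factor(y, levels = c(0, 1)),
                          probability = TRUE, num.trees = 300,
                          mtry = max(1, floor(pars$mtry_frac * ncol(X))),
                          seed = seed, num.threads = 1)
         },
         prob = function(m, X) predict(m, data = fix_names(X), num.threads = 1)$predictions[, "1"]),
    list(id = "ExtraTrees",
         grid = list(list(dummy = 1)),
         fit = function(X, y, pars, seed) {
           ranger::ranger(x = fix_names(X), y = factor(y, levels = c(0, 1)),
                          probability = TRUE, num.trees = 300,
                          splitrule = "extratrees", num.random.splits = 1,
                          seed = seed, num.threads = 1)
         },
         prob = function(m, X) predict(m, data = fix_names(X), num.threads = 1)$predictions[, "1"]),
    list(id = "KNeighborsUnif",
         grid = list(list(k = 3), list(k = 7)),
         fit = function(X, y, pars, seed) {
           sc <- fit_scaler(X)
           list(X = zscale(X, sc$center, sc$scale), y = y, k = pars$k, sc = sc)
         },
         prob = function(m, X) {
           Xs <- zscale(X, m$sc$center, m$sc$scale)
           knn_prob(m$X, m$y, Xs, m$k, weighted = FALSE)
         }),
    list(id = "KNeighborsDist",
         grid = list(list(k = 3), list(k = 7)),
         fit = function(X, y, pars, seed) {
           sc <- fit_scaler(X)
           list(X = zscale(X, sc$center, sc$scale), y = y, k = pars$k, sc = sc)
         },
         prob = function(m, X) {
           Xs <- zscale(X, m$sc$center, m$sc$scale)
           knn_prob(m$X, m$y, Xs, m$k, weighted = TRUE)
         }),
    list(id = "MLP",
         grid = list(list(size = 3), list(size = 6)),
         fit = function(X, y, pars, seed) {
           sc <- fit_scaler(X)
           set.seed(seed)
           m <- nnet::nnet(zscale(X, sc$center, sc$scale), y, size = pars$size,
                           decay = 0.1, maxit = 300, trace = FALSE)
           list(net = m, sc = sc)
         },
         prob = function(m, X) as.numeric(predict(m$net, zscale(X, m$sc$center, m$sc$scale)))),
    list(id = "LogisticRegression",
         grid = list(list(lambda = 0.01), list(lambda = 0.1)),
         fit = function(X, y, pars, seed) {
           pad <- ncol(X) < 2            # glmnet needs >= 2 columns
           if (pad) X <- cbind(X, `.pad` = 0)
           m <- suppressWarnings(
             glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                            alpha = 0, lambda = pars$lambda))
           list(fit = m, lambda = pars$lambda, pad = pad)
         },
         prob = function(m, X) {
           if (m$pad) X <- cbind(X, `.pad` = 0)
           as.numeric(predict(m$fit, X, s = m$lambda, type = "response"))
         }),
    list(id = "SVM_RBF",
         grid = list(list(cost = 1)),
         fit = function(X, y, pars, seed) {
           set.seed(seed)
           e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                      cost = pars$cost, probability = TRUE, scale = TRUE)
         },
         prob = function(m, X) {
           pr <- attr(predict(m, X, probability = TRUE), "probabilities")
           as.numeric(pr[, "1"])
         }))
  structure(specs, class = "fg_zoo", seed = as.integer(seed))
}

knn_prob <- function(Xtr, ytr, Xte, k, weighted) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1, function(dr) {
    nb <- order(dr)[seq_len(k)]
    if (weighted) {
      w <- 1 / (sqrt(pmax(dr[nb], 0)) + 1e-8)
      sum(w * (ytr[nb] == 1)) / sum(w)
    } else mean(ytr[nb] == 1)
  })
}

# grouped, label-stratified fold assignment at the patient level
make_grouped_folds <- function(y, groups, k, seed) {
  pt <- unique(groups)
  pl <- vapply(pt, function(p) y[match(p, groups)], numeric(1))
  fold_of <- stats::setNames(integer(length(pt)), pt)
  set.seed(seed)
  for (cl in unique(pl)) {
    ps <- sample(pt[pl == cl])
    fold_of[ps] <- rep_len(seq_len(k), length(ps))
  }
  unname(fold_of[as.character(groups)])
}

#' Cross-validate the classifier zoo with patient grouping
#'
#' Five-fold (by default) cross-validation in which folds are stratified by
#' class and grouped by patient: no patient's scans span folds. Per model,
#' each hyper-parameter setting is scored by the mean of fold AUCs, the
#' best setting is kept, and out-of-fold probabilities are recorded. Model
#' ranking uses mean fold AUC; the greedy weighted ensemble is built on the
#' pooled out-of-fold probabilities.
#'
#' @param X reduced feature matrix (training scans x elements).
#' @param y binary labels (0/1).
#' @param groups patient id per scan.
#' @param k number of folds (default 5).
#' @param zoo a [zoo_default()] list.
#' @param seed fold-assignment and learner seed.
#' @param ensemble_iterations greedy ensemble steps (default 25).
#' @return an `fg_cv` with per-model fold AUCs, mean AUCs, the out-of-fold
#'   probability matrix, the chosen model and ensemble weights.
#' @export
cross_validate_zoo <- function(X, y, groups, k = 5, zoo = zoo_default(seed),
                               seed = 1L, ensemble_iterations = 25L) {
  stopifnot(nrow(X) == length(y), length(y) == length(groups))
  for (cl in unique(y))
    if (length(unique(groups[y == cl])) < k)
      stop("need at least k patients per class")
  folds <- make_grouped_folds(y, groups, k, seed)
  for (tries in 1:10) {
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds != f])) == 2 && length(unique(y[folds == f])) == 2,
      logical(1)))
    if (ok) break
    message("refolding: a fold lost a class")
    folds <- make_grouped_folds(y, groups, k, seed + tries)
  }
  nm <- vapply(zoo, `[[`, character(1), "id")
  oof <- matrix(NA_real_, nrow(X), length(zoo), dimnames = list(NULL, nm))
  fold_auc <- matrix(NA_real_, length(zoo), k, dimnames = list(nm, NULL))
  best_pars <- vector("list", length(zoo))
  for (mi in seq_along(zoo)) {
    spec <- zoo[[mi]]
    best_mean <- -Inf
    for (pars in spec$grid) {
      po <- rep(NA_real_, nrow(X)); fa <- rep(NA_real_, k)
      for (f in seq_len(k)) {
        tr <- folds != f; te <- !tr
        m <- spec$fit(X[tr, , drop = FALSE], y[tr], pars, seed + f)
        po[te] <- spec$prob(m, X[te, , drop = FALSE])
        fa[f] <- fg_auc(po[te], y[te])
      }
      mfa <- mean(fa, na.rm = TRUE)
      if (mfa > best_mean) {
        best_mean <- mfa; best_pars[[mi]] <- pars
        oof[, mi] <- po; fold_auc[mi, ] <- fa
      }
    }
  }
  mean_auc <- rowMeans(fold_auc, na.rm = TRUE)
  chosen <- nm[which.max(mean_auc)]
  w <- greedy_weighted_ensemble(oof, y, iterations = ensemble_iterations)
  structure(list(fold_auc = fold_auc, mean_auc = mean_auc, oof = oof,
                 folds = folds, chosen = chosen, weights = w,
                 best_pars = stats::setNames(best_pars, nm), seed = seed),
            class = "fg_cv")
}

#' @exportS3Method base::print
print.fg_cv <- function(x, ...) {
  cat("<fg_cv> mean fold AUC per model:\n")
  print(round(sort(x$mean_auc, decreasing = TRUE), 4))
  cat("chosen:", x$chosen, "\nensemble weights:\n")
  print(round(x$weights[x$weights > 0], 3))
  invisible(x)
}

#' Greedy weighted ensemble from out-of-fold probabilities
#'
#' Forward selection with replacement: the bag starts with the single model
#' of highest pooled out-of-fold AUC, and each step adds the model that
#' maximises the bagged-average AUC (ties to the lower model index).
#' Weights are the bag counts normalised to sum 1.
#'
#' @param oof_probs matrix scans x models of out-of-fold probabilities.
#' @param y binary labels.
#' @param iterations total bag size (default 25).
#' @return named non-negative weights summing to 1.
#' @export
greedy_weighted_ensemble <- function(oof_probs, y, iterations = 25L) {
  stopifnot(ncol(oof_probs) >= 2)
  nm <- colnames(oof_probs)
  aucs <- apply(oof_probs, 2, fg_auc, labels = y)
  if (all(apply(oof_probs, 2, function(p) max(p) - min(p)) < 1e-12)) {
    warning("all models produced constant probabilities; uniform weights")
    return(stats::setNames(rep(1 / ncol(oof_probs), ncol(oof_probs)), nm))
  }
  bag <- which.max(aucs)          # ties: which.max takes the lower index
  ens <- oof_probs[, bag]
  for (it in seq_len(iterations - 1)) {
    cand_auc <- vapply(seq_len(ncol(oof_probs)), function(j)
      fg_auc((ens * length(bag) + oof_probs[, j]) / (length(bag) + 1), y),
      numeric(1))
    j <- which.max(cand_auc)
    ens <- (ens * length(bag) + oof_probs[, j]) / (length(bag) + 1)
    bag <- c(bag, j)
  }
  w <- tabulate(bag, nbins = ncol(oof_probs)) / length(bag)
  stats::setNames(w, nm)
}

#' Train the final weighted-ensemble model
#'
#' Refits every positively-weighted zoo member on the full training set and
#' returns a classed model whose prediction is the weighted average of the
#' component probabilities.
#'
#' @param X training feature matrix (after selection).
#' @param y binary labels.
#' @param cv an `fg_cv` from [cross_validate_zoo()] (provides weights and
#'   best hyper-parameters).
#' @param zoo the zoo used for cross-validation.
#' @param seed refit seed.
#' @return an object of class `fibro_model`.
#' @export
train_final <- function(X, y, cv, zoo = zoo_default(seed), seed = 1L) {
  stopifnot(inherits(cv, "fg_cv"))
  nm <- vapply(zoo, `[[`, character(1), "id")
  comps <- list()
  for (mi in seq_along(zoo)) {
    if (cv$weights[nm[mi]] <= 0) next
    spec <- zoo[[mi]]
    comps[[nm[mi]]] <- list(model = spec$fit(X, y, cv$best_pars[[nm[mi]]], seed),
                            prob = spec$prob, weight = cv$weights[nm[mi]])
  }
  structure(list(components = comps, weights = cv$weights, cv = cv,
                 n_features = ncol(X), feature_names = colnames(X), seed = seed),
            class = "fibro_model")
}

#' Predict fibrotic-class probabilities for scans
#'
#' @param object a `fibro_model`.
#' @param newdata feature matrix with the model's feature dimension.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.fibro_model <- function(object, newdata, ...) {
  if (length(object$components) == 0) stop("unfitted model bundle")
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch: model expects ", object$n_features)
  p <- numeric(nrow(newdata)); wsum <- 0
  for (cmp in object$components) {
    p <- p + cmp$weight * cmp$prob(cmp$model, newdata)
    wsum <- wsum + cmp$weight
  }
  pmin(pmax(p / wsum, 0), 1)
}

#' @exportS3Method base::print
print.fibro_model <- function(x, ...) {
  cat(sprintf("<fibro_model> weighted ensemble of %d learner(s), %d features\n",
              length(x$components), x$n_features))
  w <- x$weights[x$weights > 0]
  for (nm in names(w)) cat(sprintf("  %-20s w = %.3f\n", nm, w[nm]))
  invisible(x)
}

#' @exportS3Method base::summary
summary.fibro_model <- function(object, ...) {
  cat("Weighted-ensemble fibrosis classifier\n")
  cat(sprintf("Features used (%d): %s\n", object$n_features,
              paste(head(object$feature_names, 5), collapse = ", ")))
  cat("Cross-validated mean fold AUC per zoo member:\n")
  print(round(sort(object$cv$mean_auc, decreasing = TRUE), 4))
  invisible(object)
}
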