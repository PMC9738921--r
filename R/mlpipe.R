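# Classification harness: per-fold preprocessing (zero-variance removal,
# z-scoring, Spearman complete-linkage feature agglomeration), Borderline-
# SMOTE oversampling, L1-penalized logistic regression with a randomized
# log-uniform penalty search, stratified repeated cross-validation,
# bootstrap performance summaries, permutation tests and exact linear SHAP
# importances. Every fitted transform uses training-fold data only.

#' Feature table
#' @param X numeric matrix (subjects x features) with column names.
#' @param y 0/1 label vector.
#' @param ids optional subject identifiers.
#' @param set feature-set tag.
#' @param psfd logical PSF-deconvolution arm tag.
#' @export
feature_table <- function(X, y, ids = NULL, set = NA_character_, psfd = NA) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), !anyNA(X), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("labels must cover both classes")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  structure(list(X = X, y = y, ids = ids, set = set, psfd = psfd),
            class = "feature_table")
}

#' Cross-validation specification
#' @param k folds (default 5).
#' @param repeats CV repetitions (default 20).
#' @param seed integer seed; all pipeline randomness derives from it.
#' @param search_iterations penalty-search budget (default 300).
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @param agg_threshold Spearman agglomeration threshold (default 0.9).
#' @export
cv_spec <- function(k = 5L, repeats = 20L, seed = 1L,
                    search_iterations = 300L, smote_k = 5L,
                    agg_threshold = 0.9) {
  stopifnot(k >= 2, repeats >= 1, search_iterations >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 search_iterations = as.integer(search_iterations),
                 smote_k = as.integer(smote_k),
                 agg_threshold = agg_threshold),
            class = "cv_spec")
}

#' Remove zero-variance features
#' @param X numeric matrix.
#' @return X without its constant columns.
#' @export
remove_zero_variance <- function(X) {
  keep <- apply(X, 2, function(col) max(col) > min(col))
  if (!any(keep)) stop("no informative features")
  X[, keep, drop = FALSE]
}

#' Fit z-score parameters on training data
#' @param X training matrix (no constant columns).
#' @return list(mean, sd) with population standard deviations.
#' @export
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  list(mean = mu, sd = sd_pop)
}

#' Apply fitted z-score parameters
#' @param X matrix to transform (train or test).
#' @param fit a [zscore_fit()] result.
#' @export
zscore_apply <- function(X, fit) {
  sweep(sweep(X[, names(fit$mean), drop = FALSE], 2, fit$mean), 2, fit$sd, `/`)
}

#' Complete-linkage Spearman feature agglomeration
#'
#' Hierarchical clustering with distance 1 - |Spearman rho|, complete
#' linkage, cut so that within every cluster all pairwise |rho| >= the
#' threshold; one representative per cluster, the medoid (highest mean
#' |rho| to its cluster co-members, ties broken by column order).
#'
#' @param X numeric matrix, >= 2 columns.
#' @param threshold correlation threshold (default 0.9).
#' @return list(selected = representative column names,
#'   clusters = integer cluster id per feature).
#' @export
agglomerate <- function(X, threshold = 0.9) {
  p <- ncol(X)
  stopifnot(p >= 2)
  rho <- abs(stats::cor(X, method = "spearman"))
  d <- stats::as.dist(1 - rho)
  cl <- stats::cutree(stats::hclust(d, method = "complete"),
                      h = 1 - threshold)
  selected <- character(0)
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    if (length(members) == 1L) rep_ix <- members
    else {
      score <- vapply(members, function(m)
        mean(rho[m, setdiff(members, m)]), numeric(1))
      rep_ix <- members[which.max(score)]
    }
    selected <- c(selected, colnames(X)[rep_ix])
  }
  list(selected = selected, clusters = cl)
}

# k nearest neighbours of each row of A among rows of B (Euclidean),
# excluding exact self-matches by index when self_ix is given
knn_index <- function(A, B, k, self_ix = NULL) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  if (!is.null(self_ix))
    d2[cbind(seq_len(nrow(A)), self_ix)] <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(min(k, sum(is.finite(r))))]))
}

#' Borderline-SMOTE oversampling of the minority class
#'
#' Borderline-SMOTE-1: only minority samples in the "danger" set (at least
#' half, but not all, of their k nearest neighbours among all samples
#' belong to the majority class) seed synthetic points, interpolated
#' towards random minority neighbours. Falls back to plain SMOTE over all
#' minority samples when the danger set is empty. Output classes are
#' balanced.
#'
#' @param X training matrix.
#' @param y training labels.
#' @param seed integer seed.
#' @param k neighbourhood size (default 5).
#' @return list(X, y) with equal class counts.
#' @export
oversample <- function(X, y, seed = 1L, k = 5L) {
  tab <- table(factor(y, levels = 0:1))
  n_need <- abs(diff(as.integer(tab)))
  if (n_need == 0) return(list(X = X, y = y))
  minority <- as.integer(names(tab)[which.min(tab)])
  min_ix <- which(y == minority)
  Xm <- X[min_ix, , drop = FALSE]
  if (length(min_ix) == 1L) {
    Xs <- Xm[rep(1, n_need), , drop = FALSE]
    return(list(X = rbind(X, Xs), y = c(y, rep(minority, n_need))))
  }
  kk <- min(k, nrow(X) - 1L)
  nb_all <- knn_index(Xm, X, kk, self_ix = min_ix)
  n_maj_nb <- apply(nb_all, 1, function(r) sum(y[r] != minority))
  danger <- which(n_maj_nb >= kk / 2 & n_maj_nb < kk)
  base_set <- if (length(danger)) danger else seq_along(min_ix)
  km <- min(k, nrow(Xm) - 1L)
  nb_min <- knn_index(Xm[base_set, , drop = FALSE], Xm, km,
                      self_ix = base_set)
  with_seed(seed, {
    bi <- sample(length(base_set), n_need, replace = TRUE)
    nj <- vapply(bi, function(b) nb_min[b, sample(km, 1)], numeric(1))
    u <- stats::runif(n_need)
    Xs <- Xm[base_set[bi], , drop = FALSE] +
      u * (Xm[nj, , drop = FALSE] - Xm[base_set[bi], , drop = FALSE])
    list(X = rbind(X, Xs), y = c(y, rep(minority, n_need)))
  })
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Search the L1 penalty strength
#'
#' Probes `n_iter` inverse-penalty values C drawn log-uniformly from
#' [1e-3, 1e3] and scores each by the mean binomial cross-entropy over an
#' internal stratified 3-fold split of the training set, using the glmnet
#' Lasso path (lambda = 1 / (C n)). Returns the C with minimal loss.
#'
#' @param X standardized training matrix.
#' @param y training labels (both classes present).
#' @param n_iter number of probed values (default 300).
#' @param seed integer seed.
#' @return list(C, loss) for the best probe.
#' @export
search_penalty <- function(X, y, n_iter = 300L, seed = 1L) {
  stopifnot(length(unique(y)) == 2)
  with_seed(seed, {
    Cs <- sort(10^stats::runif(n_iter, -3, 3))
    kint <- 3L
    fold <- stratified_folds(y, kint)
    ce <- matrix(NA_real_, kint, n_iter)
    for (f in seq_len(kint)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
      lam <- 1 / (Cs * sum(tr))
      # glmnet warns about small per-class counts on desk-scale folds;
      # expected here, not actionable
      fit <- suppressWarnings(glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                                             family = "binomial", alpha = 1,
                                             standardize = FALSE))
      pr <- stats::predict(fit, X[!tr, , drop = FALSE], s = lam,
                           type = "response")
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      yt <- y[!tr]
      ce[f, ] <- -colMeans(yt * log(pr) + (1 - yt) * log(1 - pr))
    }
    loss <- colMeans(ce, na.rm = TRUE)
    best <- which.min(loss)
    list(C = Cs[best], loss = loss[best])
  })
}

# Fit the full per-fold pipeline on a training split and predict the test
# split. Returns predictions plus the fitted linear model in the reduced
# standardized space (for SHAP).
fit_fold <- function(X_tr, y_tr, X_te, spec, seed) {
  X_tr <- remove_zero_variance(X_tr)
  zfit <- zscore_fit(X_tr)
  Z_tr <- zscore_apply(X_tr, zfit)
  Z_te <- zscore_apply(X_te, zfit)
  if (ncol(Z_tr) >= 2) {
    agg <- agglomerate(Z_tr, spec$agg_threshold)
    Z_tr <- Z_tr[, agg$selected, drop = FALSE]
    Z_te <- Z_te[, agg$selected, drop = FALSE]
  }
  os <- oversample(Z_tr, y_tr, seed = seed, k = spec$smote_k)
  sp <- search_penalty(os$X, os$y, spec$search_iterations, seed = seed + 1L)
  lam <- 1 / (sp$C * nrow(os$X))
  fit <- suppressWarnings(glmnet::glmnet(os$X, os$y, family = "binomial",
                                         alpha = 1, standardize = FALSE))
  beta <- drop(as.matrix(stats::coef(fit, s = lam)))
  eta <- beta[1] + drop(Z_te %*% beta[-1])
  model <- list(beta0 = unname(beta[1]), beta = beta[-1],
                center = colMeans(os$X), C = sp$C,
                features = colnames(Z_tr))
  list(prob = 1 / (1 + exp(-eta)), model = model, Z_te = Z_te)
}

#' Exact SHAP values of a fitted linear fold model
#'
#' For a linear model the Shapley attribution of feature j at input z is
#' `beta_j * (z_j - center_j)`; attributions plus the base value
#' reconstruct the model logit exactly.
#'
#' @param model fold model from [run_cv()] (`report$folds[[i]]$model`).
#' @param Z standardized feature matrix in the model's feature space.
#' @return list(phi = matrix of attributions, base = base logit).
#' @export
shap_linear <- function(model, Z) {
  phi <- sweep(Z[, model$features, drop = FALSE], 2, model$center) *
    rep(model$beta, each = nrow(Z))
  base <- model$beta0 + sum(model$beta * model$center)
  list(phi = phi, base = base)
}

#' Repeated stratified cross-validation of the Lasso pipeline
#'
#' For every repetition and stratified fold, the pipeline
#' (zero-variance removal, z-scoring, agglomeration, Borderline-SMOTE,
#' penalty search, L1 logistic regression) is fitted on the training split
#' only, and class probabilities are predicted for the held-out split.
#'
#' @param table a [feature_table()], n >= 10.
#' @param spec a [cv_spec()].
#' @return object of class `eval_report` with pooled out-of-fold
#'   predictions, per-fold models and SHAP accumulators.
#' @export
run_cv <- function(table, spec = cv_spec()) {
  stopifnot(inherits(table, "feature_table"), nrow(table$X) >= 10)
  X <- table$X; y <- table$y
  preds <- list(); folds <- list()
  with_seed(spec$seed, {
    for (r in seq_len(spec$repeats)) {
      fold <- stratified_folds(y, spec$k)
      for (f in seq_len(spec$k)) {
        te <- fold == f
        res <- fit_fold(X[!te, , drop = FALSE], y[!te],
                        X[te, , drop = FALSE], spec,
                        seed = spec$seed + 7919L * r + 104729L * f)
        shp <- shap_linear(res$model, res$Z_te)
        preds[[length(preds) + 1L]] <- data.frame(
          subject = which(te), rep = r, fold = f,
          prob = res$prob, label = y[te])
        folds[[length(folds) + 1L]] <- list(
          rep = r, fold = f, model = res$model,
          auc = tryCatch(auc_rank(res$prob, y[te]), error = function(e) NA_real_),
          shap_abs_sum = colSums(abs(shp$phi)), n_test = sum(te))
      }
    }
  })
  pred <- do.call(rbind, preds)
  structure(list(predictions = pred, folds = folds, n = nrow(X),
                 labels = y, spec = spec, set = table$set,
                 psfd = table$psfd),
            class = "eval_report")
}

pooled_metrics <- function(pred) {
  auc <- auc_rank(pred$prob, pred$label)
  hard <- as.integer(pred$prob >= 0.5)
  sens <- sum(hard == 1 & pred$label == 1) / max(1, sum(pred$label == 1))
  spcf <- sum(hard == 0 & pred$label == 0) / max(1, sum(pred$label == 0))
  c(auc = auc, sensitivity = sens, specificity = spcf,
    balanced_accuracy = (sens + spcf) / 2)
}

#' Bootstrap summary of CV performance
#'
#' Subjects are resampled with replacement (stratified by class so both
#' classes are always present) from the pooled out-of-fold predictions;
#' each metric is reported as the bootstrap mean with a percentile 95%
#' confidence interval.
#'
#' @param report an `eval_report`.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return data.frame with metric, estimate, mean, lower, upper.
#' @export
bootstrap_summary <- function(report, n_boot = 1000L, seed = 1L) {
  pred <- report$predictions
  subjects <- sort(unique(pred$subject))
  lab <- report$labels[subjects]
  by_subj <- split(seq_len(nrow(pred)), pred$subject)
  est <- pooled_metrics(pred)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      samp <- c(sample(subjects[lab == 0], sum(lab == 0), replace = TRUE),
                sample(subjects[lab == 1], sum(lab == 1), replace = TRUE))
      rows <- unlist(by_subj[as.character(samp)], use.names = FALSE)
      pooled_metrics(pred[rows, ])
    }, numeric(4))
  })
  data.frame(metric = names(est), estimate = unname(est),
             mean = rowMeans(draws),
             lower = apply(draws, 1, stats::quantile, 0.025),
             upper = apply(draws, 1, stats::quantile, 0.975),
             row.names = NULL)
}

#' Label-permutation test of the CV AUC
#'
#' The observed pooled AUC (from `report`, or recomputed) is compared with
#' the null distribution obtained by permuting labels and re-running a
#' reduced cross-validation (same k, 1 repetition) per permutation;
#' p = (1 + #{null >= observed}) / (1 + n_perm).
#'
#' @param table a [feature_table()].
#' @param spec a [cv_spec()] used for the observed run.
#' @param n_perm number of permutations (default 200).
#' @param observed optionally, a precomputed observed pooled AUC.
#' @return list(p, observed, null) with the null AUC draws.
#' @export
permutation_test <- function(table, spec = cv_spec(), n_perm = 200L,
                             observed = NULL) {
  if (is.null(observed)) {
    rep0 <- run_cv(table, spec)
    observed <- pooled_metrics(rep0$predictions)[["auc"]]
  }
  null_spec <- cv_spec(spec$k, 1L, spec$seed, spec$search_iterations,
                       spec$smote_k, spec$agg_threshold)
  null_auc <- numeric(n_perm)
  perms <- with_seed(spec$seed + 33L,
                     lapply(seq_len(n_perm), function(i) sample(table$y)))
  for (i in seq_len(n_perm)) {
    tab_i <- table
    tab_i$y <- perms[[i]]
    null_spec$seed <- spec$seed + 101L * i
    rep_i <- run_cv(tab_i, null_spec)
    null_auc[i] <- pooled_metrics(rep_i$predictions)[["auc"]]
  }
  list(p = (1 + sum(null_auc >= observed)) / (1 + n_perm),
       observed = observed, null = null_auc)
}

#' SHAP feature importance and the minimal 50%-contribution set
#'
#' Importance of a feature is its mean absolute linear-SHAP attribution
#' over all out-of-fold predictions, aggregated over fold models and
#' normalized to sum 1. The minimal set is the shortest prefix of the
#' descending importance ranking whose cumulative share reaches 0.5 (ties
#' broken by feature name).
#'
#' @param report an `eval_report`.
#' @return list(importance = named sorted vector, minimal_set).
#' @export
shap_importance <- function(report) {
  acc <- new.env()
  total_pred <- 0
  for (fr in report$folds) {
    total_pred <- total_pred + fr$n_test
    s <- fr$shap_abs_sum
    for (nm in names(s))
      assign(nm, s[[nm]] + mget(nm, acc, ifnotfound = 0)[[1]], acc)
  }
  imp <- unlist(as.list(acc)) / total_pred
  if (sum(imp) == 0) imp[] <- 1 / length(imp) else imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  mset <- names(imp)[seq_len(which(cumsum(imp) >= 0.5)[1])]
  list(importance = imp, minimal_set = mset)
}

#' @export
print.eval_report <- function(x, ...) {
  m <- pooled_metrics(x$predictions)
  cat(sprintf("<eval_report> n=%d, %dx%d CV | AUC %.3f, sens %.3f, spec %.3f, bACC %.3f\n",
              x$n, x$spec$k, x$spec$repeats, m["auc"], m["sensitivity"],
              m["specificity"], m["balanced_accuracy"]))
  invisible(x)
}

#' @export
summary.eval_report <- function(object, n_boot = 1000L, seed = 1L, ...) {
  bootstrap_summary(object, n_boot = n_boot, seed = seed)
}
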