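noise_table <- function(n = 20, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  feature_table(X, rep_len(0:1, n))
}

test_that("z-scoring uses train statistics with population sd", {
  tr <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "a"))
  fit <- zscore_fit(tr)
  expect_equal(drop(zscore_apply(tr, fit)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  te <- matrix(2, ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(drop(zscore_apply(te, fit)), 0, ignore_attr = TRUE)
})

test_that("zero-variance removal drops exactly the constant columns", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  expect_equal(colnames(remove_zero_variance(X)), c("a", "c"))
  expect_equal(remove_zero_variance(X[, c("a", "c")]), X[, c("a", "c")])
  expect_error(remove_zero_variance(X[, "b", drop = FALSE]), "informative")
})

test_that("Spearman agglomeration clusters perfect correlates and keeps independents", {
  set.seed(2)
  f1 <- rnorm(30); f3 <- rnorm(30)
  X <- cbind(f1 = f1, f2 = 2 * f1, f3 = f3)
  ag <- agglomerate(X, 0.9)
  expect_equal(length(unique(ag$clusters)), 2L)
  expect_equal(ag$clusters[["f1"]], ag$clusters[["f2"]])
  expect_true("f3" %in% ag$selected)
  expect_length(ag$selected, 2L)

  Xw <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  agw <- agglomerate(Xw, 0.9)
  expect_equal(sort(agw$selected), c("a", "b", "c"))
})

test_that("agglomeration matches a naive complete-linkage oracle", {
  set.seed(7)
  for (trial in 1:5) {
    base <- rnorm(6)
    X <- cbind(a = base + rnorm(6, sd = 0.05),
               b = base + rnorm(6, sd = 0.05),
               c = rnorm(6), d = rnorm(6))
    rho <- abs(cor(X, method = "spearman"))
    oracle <- complete_linkage_naive(1 - rho, h = 0.1)
    got <- agglomerate(X, 0.9)$clusters
    # same partition up to label renaming
    expect_equal(outer(got, got, `==`), outer(oracle, oracle, `==`),
                 ignore_attr = TRUE)
  }
})

test_that("Borderline-SMOTE balances classes with interpolated synthetic rows", {
  set.seed(3)
  X <- rbind(matrix(rnorm(8 * 3, mean = 0), ncol = 3),
             matrix(rnorm(4 * 3, mean = 1.5), ncol = 3))
  colnames(X) <- c("x", "y", "z")
  y <- c(rep(0, 8), rep(1, 4))
  os <- oversample(X, y, seed = 5)
  expect_equal(as.vector(table(os$y)), c(8, 8))
  syn <- os$X[13:16, , drop = FALSE]
  mino <- X[y == 1, , drop = FALSE]
  for (r in seq_len(nrow(syn))) {
    expect_true(all(syn[r, ] >= apply(mino, 2, min) - 1e-9))
    expect_true(all(syn[r, ] <= apply(mino, 2, max) + 1e-9))
  }
  os2 <- oversample(X, y, seed = 5)
  expect_identical(os$X, os2$X)
  bal <- oversample(X[1:8, ], rep_len(0:1, 8), seed = 1)
  expect_equal(dim(bal$X), c(8L, 3L))
})

test_that("penalty search keeps separating features and silences noise", {
  set.seed(4)
  n <- 40
  sig <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  X <- cbind(sig = sig, matrix(rnorm(n * 4), n))
  colnames(X) <- c("sig", paste0("n", 1:4))
  y <- rep(0:1, each = n / 2)
  sp <- search_penalty(X, y, n_iter = 100, seed = 1)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        standardize = FALSE)
  beta <- drop(as.matrix(coef(fit, s = 1 / (sp$C * n))))
  expect_true(beta["sig"] != 0)

  Xn <- matrix(rnorm(30 * 20), 30); colnames(Xn) <- paste0("p", 1:20)
  yn <- rep_len(0:1, 30)
  spn <- search_penalty(Xn, yn, n_iter = 100, seed = 2)
  betan <- drop(as.matrix(coef(glmnet::glmnet(Xn, yn, family = "binomial",
                                              alpha = 1, standardize = FALSE),
                               s = 1 / (spn$C * 30))))[-1]
  expect_gte(mean(betan == 0), 0.9)

  one <- search_penalty(X, y, n_iter = 1, seed = 9)
  again <- search_penalty(X, y, n_iter = 1, seed = 9)
  expect_identical(one$C, again$C)
  expect_true(one$C >= 1e-3 && one$C <= 1e3)
})

test_that("repeated stratified CV visits each subject exactly once per repetition", {
  tb <- noise_table(20, 8, seed = 5)
  rep <- run_cv(tb, cv_spec(k = 5, repeats = 3, seed = 2,
                            search_iterations = 30))
  expect_length(rep$folds, 15L)
  counts <- table(rep$predictions$subject)
  expect_true(all(counts == 3))
  per_rep <- table(rep$predictions$rep)
  expect_true(all(per_rep == 20))
  # stratification: fold class counts within 1 of proportional
  for (r in unique(rep$predictions$rep)) {
    pr <- rep$predictions[rep$predictions$rep == r, ]
    tab <- table(pr$fold, pr$label)
    expect_true(all(abs(tab[, "1"] - 2) <= 1))
  }
  rep2 <- run_cv(tb, cv_spec(k = 5, repeats = 3, seed = 2,
                             search_iterations = 30))
  expect_identical(rep$predictions, rep2$predictions)
})

test_that("null features give chance-level AUC; a label-copy feature is learnable", {
  tb <- noise_table(30, 12, seed = 6)
  repn <- run_cv(tb, cv_spec(k = 5, repeats = 2, seed = 3,
                             search_iterations = 50))
  auc_null <- auc_rank(repn$predictions$prob, repn$predictions$label)
  expect_gt(auc_null, 0.35); expect_lt(auc_null, 0.65)

  # canary: the same pipeline finds a legitimately included perfect feature
  Xc <- cbind(tb$X, leak = tb$y + rnorm(30, sd = 0.01))
  repc <- run_cv(feature_table(Xc, tb$y), cv_spec(k = 5, repeats = 2,
                                                  seed = 3,
                                                  search_iterations = 50))
  expect_gt(auc_rank(repc$predictions$prob, repc$predictions$label), 0.95)
})

test_that("bootstrap summaries honour degenerate and hand-computed cases", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  tb <- noise_table(12, 4, seed = 7)
  rep <- run_cv(tb, cv_spec(k = 3, repeats = 1, seed = 1,
                            search_iterations = 20))
  rep$predictions$prob <- ifelse(rep$predictions$label == 1, 0.9, 0.1)
  bs <- bootstrap_summary(rep, n_boot = 200, seed = 2)
  expect_equal(bs$mean[bs$metric == "auc"], 1.0)
  expect_equal(bs$lower[bs$metric == "auc"], 1.0)
  expect_equal(bs$upper[bs$metric == "auc"], 1.0)
  expect_true(all(bs$lower <= bs$mean + 1e-12 & bs$mean <= bs$upper + 1e-12))
})

test_that("AUC equals brute-force pair counting on random score sets", {
  set.seed(8)
  for (trial in 1:25) {
    n <- sample(6:20, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)            # rounding forces ties
    expect_equal(auc_rank(s, y), auc_pairs(s, y))
  }
})

test_that("linear SHAP is exactly additive and allocates shares sensibly", {
  set.seed(9)
  Z <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("a", "b", "c")))
  model <- list(beta0 = 0.3, beta = c(a = 1.2, b = -0.7, c = 0),
                center = colMeans(Z), features = colnames(Z))
  sh <- shap_linear(model, Z)
  logit <- model$beta0 + drop(Z %*% model$beta)
  expect_lt(max(abs(rowSums(sh$phi) + sh$base - logit)), 1e-10)

  # single-feature model dominates the importance ranking
  tb <- noise_table(24, 5, seed = 10)
  Xs <- cbind(tb$X, strong = ifelse(tb$y == 1, 3, -3) + rnorm(24, sd = 0.1))
  rep <- run_cv(feature_table(Xs, tb$y),
                cv_spec(k = 4, repeats = 2, seed = 4, search_iterations = 40))
  si <- shap_importance(rep)
  expect_equal(names(si$importance)[1], "strong")
  expect_equal(sum(si$importance), 1)
  expect_true("strong" %in% si$minimal_set)
  expect_lte(length(si$minimal_set), 3L)
})

test_that("permutation test separates signal from noise and bounds p correctly", {
  set.seed(12)
  n <- 24
  X <- cbind(s = ifelse(rep(0:1, each = n / 2) == 1, 2, -2) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 3), n))
  colnames(X) <- c("s", "n1", "n2", "n3")
  tb <- feature_table(X, rep(0:1, each = n / 2))
  spec <- cv_spec(k = 4, repeats = 1, seed = 5, search_iterations = 25)
  pt <- permutation_test(tb, spec, n_perm = 99)
  expect_lte(pt$p, 0.02)
  expect_gt(pt$p, 0)
  expect_lte(pt$p, 1)
  expect_equal(pt$observed, 1.0)
})
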