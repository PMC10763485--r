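# Compendium prefilter, feature selection, model fit/prediction,
# concordance index, cross-validation and external validation.

test_that("compendium prefilter intersects and reports counts", {
  expr <- matrix(rnorm(12), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  suppressMessages(out <- prefilter_genes(expr, c("b", "c", "d")))
  expect_setequal(rownames(out), c("b", "c"))
  expect_equal(attr(out, "counts"),
               c(in_list = 3L, present = 2L, retained = 2L))
  expect_error(suppressMessages(prefilter_genes(expr, c("x", "y"))),
               "no genes in common")

  sc <- make_small_cohort()
  compendium <- c(sc$signal, paste0("decoy", 1:5), sc$genes[50:80])
  suppressMessages(kept <- prefilter_genes(sc$expr, compendium))
  expect_setequal(rownames(kept), intersect(compendium, sc$genes))
})

test_that("feature selection ranks by absolute correlation with AUC", {
  sc <- make_small_cohort()
  expr <- rbind(sc$expr, exact = sc$response)
  expect_identical(select_features(expr, sc$response, k = 1), "exact")
  all_feats <- select_features(expr, sc$response, k = nrow(expr))
  expect_length(all_feats, nrow(expr))
  rho <- apply(expr, 1, function(x) cor(x, sc$response, method = "spearman"))
  expect_identical(all_feats[1:5],
                   names(sort(abs(rho), decreasing = TRUE))[1:5])
  expect_error(select_features(expr, sc$response, k = nrow(expr) + 1), "between 1")

  # planted-signal recovery: most selected genes are the planted ones
  sel <- select_features(sc$expr, sc$response, k = length(sc$signal))
  expect_gte(mean(sel %in% sc$signal), 0.7)
})

test_that("signature fitting is exact for perfect predictors and minimum-norm for duplicates", {
  withr::with_seed(3, {
    n <- 30
    auc <- rnorm(n, 3, 1)
    expr <- rbind(perf = auc, noise = rnorm(n))
    colnames(expr) <- sprintf("s%02d", 1:n)
  })
  m <- fit_signature(expr, auc, "perf")
  expect_equal(unname(m$coefficients["perf"]), sd(auc), tolerance = 1e-10)
  pred <- predict_score(m, expr)
  expect_equal(unname(pred), unname(auc), tolerance = 1e-10)
  expect_equal(concordance_index(pred, auc), 1.0)

  # duplicated feature column predicts identically to the single copy
  expr_dup <- rbind(expr, perf2 = expr["perf", ])
  m_dup <- fit_signature(expr_dup, auc, c("perf", "perf2"))
  expect_equal(unname(predict_score(m_dup, expr_dup)), unname(pred),
               tolerance = 1e-8)

  # constant features are dropped before fitting
  expr_c <- rbind(expr, flat = rep(1, ncol(expr)))
  expect_warning(m_c <- fit_signature(expr_c, auc, c("perf", "flat")), "constant")
  expect_identical(m_c$features, "perf")

  # zero-coefficient model predicts the intercept everywhere
  m0 <- m
  m0$coefficients[] <- 0
  expect_true(all(predict_score(m0, expr) == m0$intercept))
  expect_error(predict_score(m, expr["noise", , drop = FALSE]), "perf")
})

test_that("concordance index matches brute force and is rank-invariant", {
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3)), 0.0)
  expect_equal(concordance_index(c(1, 2, 2, 3), c(1, 3, 2, 4)), 5.5 / 6)
  expect_error(concordance_index(c(1, 2), c(2, 2)), "tied")

  set.seed(19)
  for (rep in 1:100) {
    n <- sample(4:25, 1)
    pred <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01 * (rep %% 2))
    obs <- sample(1:5, n, replace = TRUE)
    if (length(unique(obs)) < 2) next
    expect_equal(concordance_index(pred, obs), oracle_cindex(pred, obs))
    # invariant under strictly increasing transforms of the prediction
    expect_equal(concordance_index(exp(pred / 3), obs),
                 concordance_index(pred, obs))
  }
})

test_that("concordance index agrees with the survival package on untied data", {
  skip_if_not_installed("survival")
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    pred <- rnorm(n)
    obs <- rnorm(n)
    ref <- survival::concordance(obs ~ pred)$concordance
    expect_equal(concordance_index(pred, obs), ref, tolerance = 1e-12)
  }
})

test_that("cross-validation is deterministic and leakage-free", {
  sc <- make_small_cohort(n_samples = 50, n_genes = 120, n_signal = 10)
  cv1 <- cross_validate(sc$expr, sc$response, k_grid = c(2, 5, 10),
                        n_folds = 5, n_repeats = 2, seed = 6)
  cv2 <- cross_validate(sc$expr, sc$response, k_grid = c(2, 5, 10),
                        n_folds = 5, n_repeats = 2, seed = 6)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$best_k, cv2$best_k)
  expect_true(all(cv1$per_fold$cindex >= 0 & cv1$per_fold$cindex <= 1))
  expect_true(cv1$ci95["lower"] <= cv1$mean_cindex &&
                cv1$mean_cindex <= cv1$ci95["upper"])

  # the features recorded for each fold equal an independent re-selection on
  # that fold's training samples only: test samples never inform selection
  idx <- 0
  for (r in 1:2) {
    fold_id <- cv1$fold_assignments[, r]
    for (f in 1:5) {
      idx <- idx + 1
      train <- which(fold_id != f)
      ref <- select_features(sc$expr[, train], sc$response[train], k = 10)
      expect_identical(cv1$fold_features[[idx]], ref)
    }
  }

  # oversized k values are skipped with a warning
  expect_warning(
    cv3 <- cross_validate(sc$expr[1:8, ], sc$response, k_grid = c(2, 50),
                          n_folds = 5, n_repeats = 1, seed = 2),
    "skipped")
  expect_identical(cv3$k_grid, 2L)
})

test_that("pure-noise expression yields chance-level cross-validated concordance", {
  withr::with_seed(29, {
    n <- 200
    expr <- matrix(rnorm(100 * n), nrow = 100,
                   dimnames = list(sprintf("z%03d", 1:100),
                                   sprintf("s%03d", 1:n)))
    auc <- rnorm(n)
  })
  cv <- cross_validate(expr, auc, k_grid = c(5, 10), n_folds = 10,
                       n_repeats = 3, seed = 8)
  expect_gte(cv$mean_cindex, 0.45)
  expect_lte(cv$mean_cindex, 0.55)
})

test_that("external validation is self-consistent and collapses under permuted outcomes", {
  sc <- make_small_cohort(n_samples = 80, n_genes = 150, n_signal = 12, seed = 71)
  model <- build_signature(sc$expr, sc$response, k = 12)
  # validating on the training cohort reproduces the training concordance
  c_train <- concordance_index(predict_score(model, sc$expr), sc$response)
  expect_equal(external_validate(model, sc$expr, sc$response), c_train)

  # permuted validation outcomes give chance-level concordance on average
  null_c <- withr::with_seed(5, vapply(1:50, function(i)
    external_validate(model, sc$expr, sample(sc$response)), numeric(1)))
  expect_lt(abs(mean(null_c) - 0.5), 0.05)

  # a transferable planted signal keeps validation concordance above the null
  cfg <- simulation_config(seed = 12, n_discovery = 120, n_validation = 50,
                           n_genes = 300, n_signal_genes = 25)
  disc <- generate_cohort(cfg, "discovery")
  val <- generate_cohort(cfg, "validation")
  fd <- fit_cohort(disc$dose_response)
  fv <- fit_cohort(val$dose_response)
  m <- build_signature(disc$expression, fd$auc, k = 20)
  c_ext <- external_validate(m, val$expression, fv$auc)
  expect_gt(c_ext, quantile(withr::with_seed(6, vapply(1:100, function(i)
    external_validate(m, val$expression, sample(fv$auc)), numeric(1))), 0.95))
})
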