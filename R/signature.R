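# Gene-expression signature of radiosensitivity: compendium prefilter,
# correlation-ranked feature selection, multivariate linear regression on
# z-scored expression, concordance index, repeated k-fold cross-validation
# (feature selection re-run inside every training fold) and one-shot
# external validation.

#' Restrict an expression matrix to a radioresponse gene compendium
#'
#' Dimensionality reduction step: keeps only genes present in a curated list
#' of radioresponse-associated genes.
#'
#' @param expr genes x samples matrix with unique rownames.
#' @param compendium character vector of gene ids (e.g. from a plain-text
#'   gene-list file, one id per line).
#' @return The row-subset matrix, with attribute `counts` =
#'   `c(in_list, present, retained)`.
#' @export
prefilter_genes <- function(expr, compendium) {
  compendium <- unique(as.character(compendium))
  if (length(compendium) == 0) .stop_invalid("compendium gene list is empty")
  present <- intersect(rownames(expr), compendium)
  if (length(present) == 0)
    .stop_invalid("compendium has no genes in common with the expression matrix")
  out <- expr[present, , drop = FALSE]
  attr(out, "counts") <- c(in_list = length(compendium),
                           present = length(present),
                           retained = nrow(out))
  message(sprintf("compendium prefilter: %d genes in list, %d measured, %d retained",
                  length(compendium), length(present), nrow(out)))
  out
}

#' Select top-k features by absolute correlation with AUC
#'
#' Ranks genes by `|Spearman rho|` between training expression and the
#' training AUC values and returns the top k gene ids. Both resistance- and
#' sensitivity-associated genes are admissible (absolute value); ties are
#' broken lexicographically by gene id.
#'
#' @param expr_train genes x samples training expression.
#' @param auc_train per-sample AUC values for the training samples.
#' @param k number of features, `1 <= k <= nrow(expr_train)`.
#' @param method correlation type, `"spearman"` (default) or `"pearson"`.
#' @return Character vector of k gene ids, ordered by decreasing `|rho|`.
#' @export
select_features <- function(expr_train, auc_train, k,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (k < 1 || k > nrow(expr_train))
    .stop_invalid("k must be between 1 and the number of genes")
  rho <- if (method == "spearman") {
    .spearman_rows(as.matrix(expr_train), auc_train)
  } else {
    .pearson_rows(as.matrix(expr_train), auc_train)
  }
  rho[is.na(rho)] <- 0
  ord <- order(-abs(rho), rownames(expr_train))
  rownames(expr_train)[ord][seq_len(k)]
}

.pearson_rows <- function(expr, response) {
  xc <- expr - rowMeans(expr)
  rc <- response - mean(response)
  den <- sqrt(rowSums(xc^2)) * sqrt(sum(rc^2))
  rho <- ifelse(den > 0, as.vector(xc %*% rc) / den, NA_real_)
  names(rho) <- rownames(expr)
  rho
}

#' Fit a multivariate linear signature model
#'
#' Least-squares regression of AUC on per-gene z-scored expression of the
#' selected features. Features constant in training are dropped with a
#' warning; rank-deficient designs are resolved by the minimum-norm solution
#' (SVD pseudoinverse), so duplicated feature columns share the coefficient
#' mass and predictions are unaffected. The per-gene centre/scale used at
#' training is stored so the model can be applied to new samples.
#'
#' @param expr_train genes x samples training expression, containing all
#'   `features` rows.
#' @param auc_train per-sample AUC values (> 1 sample).
#' @param features character vector of feature gene ids.
#' @param cohort_id optional label for the training cohort.
#' @return Object of class `signature_model`: list with `features`,
#'   `coefficients` (one per feature, z-scored scale), `intercept`, `center`,
#'   `scale`, `k`, `cohort_id`.
#' @export
fit_signature <- function(expr_train, auc_train, features,
                          cohort_id = "discovery") {
  if (length(auc_train) < 2) .stop_invalid("need more than 1 training sample")
  missing <- setdiff(features, rownames(expr_train))
  if (length(missing) > 0)
    .stop_invalid("features absent from training matrix: ",
                  paste(missing, collapse = ", "))
  x <- t(as.matrix(expr_train)[features, , drop = FALSE])  # samples x k
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  const <- !is.finite(scl) | scl == 0
  if (any(const)) {
    warning(sprintf("%d feature(s) constant in training dropped: %s",
                    sum(const), paste(features[const], collapse = ", ")))
    features <- features[!const]
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
    if (length(features) == 0) .stop_invalid("all features constant in training")
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  yc <- auc_train - mean(auc_train)
  sv <- svd(z)
  tol <- max(dim(z)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% yc) / sv$d[pos])
  structure(
    list(features = features, coefficients = setNames(as.vector(coef), features),
         intercept = mean(auc_train), center = setNames(ctr, features),
         scale = setNames(scl, features), k = length(features),
         cohort_id = cohort_id),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("radiosensitivity signature: %d genes (trained on %s)\n",
              x$k, x$cohort_id))
  print(head(sort(abs(x$coefficients), decreasing = TRUE), 10))
  invisible(x)
}

#' Predicted radioresistance score
#'
#' Applies the signature's stored per-gene normalization and linear form to
#' new expression data. A higher score predicts a higher AUC, i.e. a more
#' radioresistant line. With `renormalize = TRUE` the expression is z-scored
#' per gene within the supplied cohort instead of with the training
#' centre/scale — the cross-platform harmonization used for external
#' validation.
#'
#' @param model a `signature_model`.
#' @param expr genes x samples matrix containing all model features.
#' @param renormalize z-score within `expr` rather than using training
#'   normalization metadata (default FALSE).
#' @return Named numeric vector of per-sample scores (predicted AUC scale).
#' @export
predict_score <- function(model, expr, renormalize = FALSE) {
  missing <- setdiff(model$features, rownames(expr))
  if (length(missing) > 0)
    .stop_invalid("features missing from expression matrix: ",
                  paste(missing, collapse = ", "))
  x <- t(as.matrix(expr)[model$features, , drop = FALSE])
  if (renormalize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- model$center; scl <- model$scale
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  setNames(as.vector(z %*% model$coefficients) + model$intercept, rownames(x))
}

#' Concordance index between predicted and observed values
#'
#' Probability that, for a random pair of samples with distinct observed
#' values, the sample with the higher predicted score also has the higher
#' observed value. Pairs tied on the observation are excluded; pairs tied on
#' the prediction count 0.5. 0.5 is a random predictor, 1 a perfect one.
#'
#' @param pred per-sample predicted scores.
#' @param obs per-sample observed values (e.g. AUC), same length.
#' @return Concordance index in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 2, 3))  # 1
#' concordance_index(c(3, 2, 1), c(1, 2, 3))  # 0
#' @export
concordance_index <- function(pred, obs) {
  if (length(pred) != length(obs))
    .stop_invalid("pred and obs must have the same length")
  if (length(obs) < 2) .stop_invalid("need at least 2 samples")
  d_obs <- sign(outer(obs, obs, "-"))
  d_pred <- sign(outer(pred, pred, "-"))
  up <- upper.tri(d_obs)
  comparable <- d_obs != 0 & up
  n_comp <- sum(comparable)
  if (n_comp == 0) .stop_invalid("all observed values are tied; concordance undefined")
  agree <- d_pred[comparable] * d_obs[comparable]
  (sum(agree > 0) + 0.5 * sum(agree == 0)) / n_comp
}

#' Repeated k-fold cross-validation of the signature pipeline
#'
#' Pre-validation on the discovery cohort: for each repetition a seeded
#' shuffle assigns samples to folds; within every training fold the feature
#' ranking AND the model fit are recomputed from scratch (test-fold samples
#' never touch selection or fitting), the model is applied to the held-out
#' fold, and the concordance index is recorded per candidate signature size
#' k. The best k maximises the mean concordance over all folds and
#' repetitions, ties going to the smallest k. Repetition r uses seed
#' `seed + r`, so the whole report is reproducible.
#'
#' @param expr genes x samples expression (typically compendium-prefiltered).
#' @param auc per-sample AUC values.
#' @param k_grid candidate signature sizes (default
#'   `c(2, 5, 10, 15, 20, 22, 25, 30, 40, 50)`); values exceeding the gene
#'   count are skipped with a warning.
#' @param n_folds folds per repetition (default 10).
#' @param n_repeats repetitions (default 10).
#' @param seed base integer seed.
#' @param method correlation type for feature ranking.
#' @param features optional fixed feature set; when supplied, per-fold
#'   selection is skipped and only the model fit is cross-validated
#'   (the "fixed-feature" protocol; the default per-fold protocol is the
#'   leakage-free primary analysis).
#' @return Object of class `cv_report`: list with `per_fold` (rep, fold, k,
#'   cindex), `best_k`, `rep_means` (per-repetition mean concordance at
#'   `best_k`), `mean_cindex`, `ci95` (mean +/- 1.96 * SD of repetition
#'   means), `k_means`, `fold_features` (per rep x fold, the ranked candidate
#'   genes used), `fold_assignments`, and `seed`.
#' @export
cross_validate <- function(expr, auc, k_grid = c(2, 5, 10, 15, 20, 22, 25, 30, 40, 50),
                           n_folds = 10, n_repeats = 10, seed = 1,
                           method = c("spearman", "pearson"),
                           features = NULL) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  n <- length(auc)
  if (n_folds < 2) .stop_invalid("n_folds must be >= 2")
  if (n < n_folds) .stop_invalid("cohort smaller than the number of folds")
  bad_k <- k_grid > nrow(expr)
  if (any(bad_k)) {
    warning(sprintf("k values exceeding the gene count skipped: %s",
                    paste(k_grid[bad_k], collapse = ", ")))
    k_grid <- k_grid[!bad_k]
  }
  if (length(k_grid) == 0) .stop_invalid("empty k grid")
  k_grid <- sort(unique(as.integer(k_grid)))
  kmax <- max(k_grid)
  per_fold <- vector("list", n_repeats * n_folds)
  fold_features <- vector("list", n_repeats * n_folds)
  fold_assignments <- matrix(NA_integer_, nrow = n, ncol = n_repeats)
  idx <- 0L
  for (r in seq_len(n_repeats)) {
    perm <- withr::with_seed(seed + r, sample.int(n))
    fold_id <- integer(n)
    fold_id[perm] <- rep_len(seq_len(n_folds), n)
    fold_assignments[, r] <- fold_id
    for (f in seq_len(n_folds)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      feats <- if (is.null(features)) {
        select_features(expr[, train, drop = FALSE], auc[train],
                        k = min(kmax, nrow(expr)), method = method)
      } else features
      idx <- idx + 1L
      fold_features[[idx]] <- feats
      ci_k <- vapply(k_grid, function(k) {
        fk <- feats[seq_len(min(k, length(feats)))]
        mod <- suppressWarnings(
          fit_signature(expr[, train, drop = FALSE], auc[train], fk))
        pr <- predict_score(mod, expr[, test, drop = FALSE])
        concordance_index(pr, auc[test])
      }, numeric(1))
      per_fold[[idx]] <- data.frame(rep = r, fold = f, k = k_grid,
                                    cindex = ci_k)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  k_means <- tapply(per_fold$cindex, per_fold$k, mean)
  best_k <- as.integer(names(k_means)[which.max(k_means)])  # ties: smallest k (sorted grid)
  at_best <- per_fold[per_fold$k == best_k, , drop = FALSE]
  rep_means <- tapply(at_best$cindex, at_best$rep, mean)
  m <- mean(rep_means)
  s <- sd(rep_means)
  structure(
    list(per_fold = per_fold, best_k = best_k,
         rep_means = as.numeric(rep_means), mean_cindex = m,
         ci95 = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
         k_means = setNames(as.numeric(k_means), names(k_means)),
         fold_features = fold_features, fold_assignments = fold_assignments,
         n_folds = n_folds, n_repeats = n_repeats, k_grid = k_grid,
         seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d x %d-fold CV: best k = %d, mean concordance = %.3f (95%% CI %.3f-%.3f)\n",
    x$n_repeats, x$n_folds, x$best_k, x$mean_cindex,
    x$ci95["lower"], x$ci95["upper"]))
  invisible(x)
}

#' External validation of a trained signature
#'
#' Applies a trained model once to a fully independent cohort. The
#' validation expression is z-scored per gene within the validation cohort
#' (cross-platform harmonization), then the linear form is applied and the
#' concordance index against the observed validation AUC returned.
#'
#' @param model a `signature_model` trained on the discovery cohort.
#' @param expr_val genes x samples validation expression.
#' @param auc_val observed validation AUC values.
#' @return Concordance index in `[0, 1]`.
#' @export
external_validate <- function(model, expr_val, auc_val) {
  pr <- predict_score(model, expr_val, renormalize = TRUE)
  concordance_index(pr, auc_val)
}

#' Train the final signature on the full discovery cohort
#'
#' Convenience wrapper for the deliverable model: selects the top-k features
#' on the full cohort and fits the signature at that k (typically the best k
#' from [cross_validate()]).
#'
#' @inheritParams cross_validate
#' @param k signature size.
#' @return A `signature_model`.
#' @export
build_signature <- function(expr, auc, k, method = c("spearman", "pearson"),
                            cohort_id = "discovery") {
  method <- match.arg(method)
  feats <- select_features(expr, auc, k, method = method)
  fit_signature(expr, auc, feats, cohort_id = cohort_id)
}
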