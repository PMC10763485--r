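# Whole-pipeline benchmark on the default synthetic cohort pair.

#' Run the planted-signal benchmark on a synthetic cohort pair
#'
#' Generates the default discovery/validation pair (511 and 60 lines, 6- and
#' 3-dose grids, 2000 genes with 50 planted signal genes), fits the LQ model
#' to every line, cross-validates the signature on the discovery cohort,
#' refits the final model at the best k and validates it externally against
#' a response-permutation null, and runs the enrichment analysis on a
#' planted/null gene-set collection. Returns the headline quantities of each
#' stage; this is the end-to-end recovery run the package's tests assert
#' against.
#'
#' @param seed integer seed driving the simulation, cross-validation,
#'   permutation nulls and gene-set draws.
#' @param n_perm permutations for the enrichment p-values and the external
#'   validation null (default 200).
#' @param n_repeats,n_folds cross-validation design (default 10 x 10-fold).
#' @param fdr_threshold enrichment significance threshold (default 0.10).
#' @return List with cohort summaries (`median_auc`, group medians,
#'   `auc_recovery_rho`), `cv` (the `cv_report`), `best_k`,
#'   `cv_concordance`, `external_concordance`, `external_null_q95`,
#'   `enrichment` (the AUC `enrichment_result`), `n_planted_significant`,
#'   `n_planted`, `null_fpr` (fraction of null sets with nominal p < 0.05),
#'   and `seed`.
#' @export
run_synthetic_benchmark <- function(seed = 1, n_perm = 200, n_repeats = 10,
                                    n_folds = 10, fdr_threshold = 0.10) {
  cfg <- simulation_config(seed = seed)
  disc <- generate_cohort(cfg, "discovery")
  val <- generate_cohort(cfg, "validation")
  fits_d <- fit_cohort(disc$dose_response)
  fits_v <- fit_cohort(val$dose_response)
  auc_d <- fits_d$auc
  auc_v <- fits_v$auc
  strat <- split(auc_d, fits_d$group)

  cv <- cross_validate(disc$expression, auc_d, n_folds = n_folds,
                       n_repeats = n_repeats, seed = seed)
  model <- build_signature(disc$expression, auc_d, cv$best_k)
  c_ext <- external_validate(model, val$expression, auc_v)
  pred_v <- predict_score(model, val$expression, renormalize = TRUE)
  null_c <- withr::with_seed(.derive_seed(seed, 4), vapply(seq_len(n_perm),
    function(i) concordance_index(pred_v, sample(auc_v)), numeric(1)))

  gs <- generate_genesets(disc)
  enr <- enrich_collection(disc$expression, auc_d, gs, n_perm = n_perm,
                           seed = .derive_seed(seed, 5),
                           fdr_threshold = fdr_threshold)
  planted <- attr(gs, "planted")
  is_null_set <- !(enr$pathway %in% planted)

  list(
    seed = seed,
    n_discovery = length(auc_d), n_validation = length(auc_v),
    median_auc = median(auc_d),
    resistant_median_auc = median(strat$resistant),
    sensitive_median_auc = median(strat$sensitive),
    auc_recovery_rho = cor(auc_d, disc$truth$cell_lines$auc_true,
                           method = "spearman"),
    cv = cv, best_k = cv$best_k, cv_concordance = cv$mean_cindex,
    external_concordance = c_ext,
    external_null_q95 = as.numeric(quantile(null_c, 0.95)),
    enrichment = enr,
    n_planted = length(planted),
    n_planted_significant = sum(enr$significant & enr$pathway %in% planted),
    null_fpr = mean(enr$p_nominal[is_null_set] < 0.05)
  )
}
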