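# End-to-end workflow: LQ fits -> indicators -> enrichment comparison ->
# cross-validated signature -> external validation, with all outputs and a
# provenance manifest written to one directory.

#' Assemble a pipeline configuration
#'
#' Bundles the input paths and analysis parameters for [run_pipeline()].
#' Validation-cohort paths may be omitted, in which case the pipeline runs
#' in discovery-only mode and skips external validation.
#'
#' @param discovery_dose_response,discovery_expression paths to the discovery
#'   cohort's dose-response CSV and expression TSV.
#' @param validation_dose_response,validation_expression optional paths for
#'   the validation cohort.
#' @param genesets named character vector of GMT paths (one per collection),
#'   or NULL to skip enrichment.
#' @param compendium optional path to a plain-text radioresponse gene list
#'   used to prefilter features before signature building.
#' @param out_dir output directory.
#' @param n_perm,fdr_threshold,weight_exponent enrichment parameters.
#' @param k_grid,n_folds,n_repeats cross-validation parameters.
#' @param method correlation type for ranking/selection.
#' @param seed integer seed used for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery_dose_response, discovery_expression,
                            validation_dose_response = NULL,
                            validation_expression = NULL,
                            genesets = NULL, compendium = NULL,
                            out_dir = "radiosig_out",
                            n_perm = 1000, fdr_threshold = 0.10,
                            weight_exponent = 1,
                            k_grid = c(2, 5, 10, 15, 20, 22, 25, 30, 40, 50),
                            n_folds = 10, n_repeats = 10,
                            method = "spearman", seed = 1) {
  cfg <- as.list(environment())
  paths <- c(discovery_dose_response, discovery_expression,
             validation_dose_response, validation_expression,
             genesets, compendium)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    .stop_invalid("input path(s) do not exist: ", paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full radiogenomics analysis pipeline
#'
#' Executes, in order: LQ fitting of the discovery cohort with AUC/SF2
#' derivation and mean-AUC stratification; per-collection enrichment of both
#' indicators with comparison and leading-edge overlap; compendium
#' prefiltering; repeated cross-validated signature building; a final model
#' refit on the full discovery cohort at the best k; and (when a validation
#' cohort is configured) one-shot external validation. All declared outputs
#' plus a provenance manifest (`manifest.json`) are written under
#' `config$out_dir`. Idempotent under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`fits`,
#'   `enrichment`, `comparisons`, `cv`, `model`, `external_cindex`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    .stop_invalid("config must come from pipeline_config()")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  fits <- stage("fit", function() {
    drs <- read_dose_response(config$discovery_dose_response)
    fit_cohort(drs)
  })
  write_fits(fits, file.path(out, "discovery_fits.tsv"))

  expr <- stage("expression", function() {
    m <- read_expression(config$discovery_expression)
    common <- intersect(colnames(m), fits$cell_line)
    if (length(common) < 3)
      .stop_invalid("fewer than 3 cell lines shared between dose-response and expression")
    m[, common, drop = FALSE]
  })
  fits_x <- fits[match(colnames(expr), fits$cell_line), , drop = FALSE]

  enrichment <- list(); comparisons <- list()
  if (!is.null(config$genesets)) {
    gmt_paths <- config$genesets
    if (is.null(names(gmt_paths)))
      names(gmt_paths) <- tools::file_path_sans_ext(basename(gmt_paths))
    for (nm in names(gmt_paths)) {
      res <- stage(paste0("enrich:", nm), function() {
        coll <- read_gmt(gmt_paths[[nm]])
        list(
          auc = enrich_collection(expr, fits_x$auc, coll,
                                  n_perm = config$n_perm, seed = config$seed,
                                  fdr_threshold = config$fdr_threshold,
                                  weight_exponent = config$weight_exponent),
          sf2 = enrich_collection(expr, fits_x$sf2, coll,
                                  n_perm = config$n_perm,
                                  seed = config$seed + 500000L,
                                  fdr_threshold = config$fdr_threshold,
                                  weight_exponent = config$weight_exponent)
        )
      })
      enrichment[[nm]] <- res
      comparisons[[nm]] <- compare_indicators(res$auc, res$sf2)
      write_enrichment(res$auc, file.path(out, sprintf("enrichment_%s_auc.tsv", nm)))
      write_enrichment(res$sf2, file.path(out, sprintf("enrichment_%s_sf2.tsv", nm)))
      jsonlite::write_json(
        comparisons[[nm]][c("common", "unique_to_auc", "unique_to_sf2")],
        file.path(out, sprintf("comparison_%s.json", nm)))
    }
  }

  expr_model <- if (!is.null(config$compendium)) {
    stage("prefilter", function()
      prefilter_genes(expr, read_gene_list(config$compendium)))
  } else expr

  cv <- stage("cross_validate", function()
    cross_validate(expr_model, fits_x$auc, k_grid = config$k_grid,
                   n_folds = config$n_folds, n_repeats = config$n_repeats,
                   seed = config$seed, method = config$method))
  write.table(cv$per_fold, file.path(out, "cv_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(best_k = cv$best_k, mean_cindex = cv$mean_cindex,
         ci95 = as.list(cv$ci95), rep_means = cv$rep_means, seed = cv$seed),
    file.path(out, "cv_summary.json"), auto_unbox = TRUE, digits = NA)

  model <- stage("train", function()
    build_signature(expr_model, fits_x$auc, cv$best_k, method = config$method))

  external_cindex <- NULL
  if (!is.null(config$validation_dose_response) &&
      !is.null(config$validation_expression)) {
    external_cindex <- stage("external_validate", function() {
      fits_v <- fit_cohort(read_dose_response(config$validation_dose_response))
      ev <- read_expression(config$validation_expression)
      common <- intersect(colnames(ev), fits_v$cell_line)
      ev <- ev[, common, drop = FALSE]
      auc_v <- fits_v$auc[match(common, fits_v$cell_line)]
      external_validate(model, ev, auc_v)
    })
  } else {
    message("no validation cohort configured; external validation skipped")
  }

  write_model(model, file.path(out, "signature_model.json"),
              provenance = list(seed = config$seed, best_k = cv$best_k))
  jsonlite::write_json(
    list(config = config[setdiff(names(config), "genesets")],
         genesets = as.list(config$genesets),
         seed = config$seed,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("radiosig")),
         external_cindex = external_cindex),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")

  invisible(list(fits = fits, enrichment = enrichment,
                 comparisons = comparisons, cv = cv, model = model,
                 external_cindex = external_cindex, out_dir = out))
}
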