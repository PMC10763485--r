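# Seeded synthetic radiogenomics cohorts with known ground truth.
#
# Emulates the geometry of a large discovery cohort (~511 lines, 6-dose
# grid) and a small validation cohort (~60 lines, 3-dose grid) sharing a
# gene universe: per-line LQ parameters drawn from plausible radiobiology
# ranges, multiplicative lognormal survival noise, signal genes linearly
# coupled to the true AUC (shared across cohorts), and a per-gene
# location/scale shift in the validation cohort mimicking the platform gap
# between RNA-seq and array expression.

#' Simulation configuration for synthetic cohort pairs
#'
#' Defaults mirror the study geometry the simulator emulates: 511 discovery /
#' 60 validation lines, dose grids of 1,2,3,4,6,8 Gy and 2,4,6 Gy, 2000
#' genes of which 50 carry AUC-coupled signal, alpha ~ N(0.3, 0.1) floored
#' at 0.01 /Gy, alpha/beta ~ U(5, 15) Gy, multiplicative lognormal survival
#' noise sigma_S = 0.1, signal effects |b| ~ U(0.5, 1.5) with random sign,
#' unit expression noise, and 8 tissues with tissue-level alpha shifts.
#'
#' @param n_discovery,n_validation cohort sizes.
#' @param doses_discovery,doses_validation dose grids in Gy (positive,
#'   sorted).
#' @param n_genes,n_signal_genes gene universe size and number of planted
#'   signal genes.
#' @param alpha_mean,alpha_sd,alpha_floor truncated-normal alpha parameters
#'   (1/Gy).
#' @param ab_ratio_range alpha/beta ratio range in Gy (uniform).
#' @param sigma_s multiplicative lognormal survival noise SD.
#' @param effect_range range of |b|, the signal-gene coupling to z-scored
#'   true AUC.
#' @param expr_noise_sd SD of additive expression noise on signal genes
#'   (background genes are iid N(0, 1)).
#' @param n_tissues number of tissue labels.
#' @param tissue_sd SD of tissue-level alpha shifts (1/Gy).
#' @param platform_loc_sd,platform_scale_range per-gene location/scale shift
#'   applied to validation expression (platform gap).
#' @param seed integer seed; all draws derive from it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_discovery = 511, n_validation = 60,
                              doses_discovery = c(1, 2, 3, 4, 6, 8),
                              doses_validation = c(2, 4, 6),
                              n_genes = 2000, n_signal_genes = 50,
                              alpha_mean = 0.3, alpha_sd = 0.1,
                              alpha_floor = 0.01,
                              ab_ratio_range = c(5, 15),
                              sigma_s = 0.1,
                              effect_range = c(0.5, 1.5),
                              expr_noise_sd = 1,
                              n_tissues = 8, tissue_sd = 0.05,
                              platform_loc_sd = 0.5,
                              platform_scale_range = c(0.8, 1.25),
                              seed = 1) {
  cfg <- as.list(environment())
  if (any(c(cfg$n_discovery, cfg$n_validation, cfg$n_genes, cfg$n_tissues) < 1))
    .stop_invalid("all counts must be positive")
  if (cfg$n_signal_genes > cfg$n_genes)
    .stop_invalid("n_signal_genes cannot exceed n_genes")
  for (d in list(cfg$doses_discovery, cfg$doses_validation)) {
    if (any(d <= 0) || is.unsorted(d, strictly = TRUE))
      .stop_invalid("dose grids must be positive and strictly increasing")
  }
  structure(cfg, class = "sim_config")
}

# derive stage seeds from the base seed, keeping within 32-bit integer range
.derive_seed <- function(seed, offset) {
  (as.numeric(seed) %% 2e8) * 10 + offset
}

# shared ground truth (signal genes, effects, tissue shifts) drawn from the
# base seed so both cohorts agree on it
.shared_truth <- function(config) {
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    signal <- sort(sample(gene_ids, config$n_signal_genes))
    b <- runif(config$n_signal_genes, config$effect_range[1],
               config$effect_range[2]) *
      sample(c(-1, 1), config$n_signal_genes, replace = TRUE)
    shifts <- rnorm(config$n_tissues, 0, config$tissue_sd)
    list(gene_ids = gene_ids, signal_genes = signal,
         effects = setNames(b, signal),
         tissue_shifts = setNames(shifts, paste0("tissue", seq_len(config$n_tissues))))
  })
}

#' Generate a synthetic radiogenomics cohort
#'
#' Draws per-line LQ parameters, computes true survival on the role's dose
#' grid, applies multiplicative lognormal noise, and builds a gene x sample
#' expression matrix in which each signal gene j equals
#' `b_j * zscore(trueAUC) + N(0, expr_noise_sd)` while background genes are
#' iid N(0, 1). The validation cohort reuses the discovery signal genes and
#' effect signs (drawn from the base seed) and additionally receives a
#' per-gene location/scale shift emulating a different expression platform.
#' Fully reproducible: the same config yields bitwise-identical cohorts.
#'
#' @param config a [simulation_config()].
#' @param role `"discovery"` or `"validation"`.
#' @return Object of class `synthetic_cohort`: list with `role`,
#'   `dose_response` (list of [dose_response()] objects), `dose_table`
#'   (long-format data frame `cell_line,tissue,dose_gy,survival`),
#'   `expression` (genes x samples matrix), `tissue`, and `truth` (per-line
#'   alpha/beta/true AUC/true SF2, signal gene ids, effects).
#' @export
generate_cohort <- function(config, role = c("discovery", "validation")) {
  role <- match.arg(role)
  if (!inherits(config, "sim_config")) .stop_invalid("config must be a sim_config")
  shared <- .shared_truth(config)
  n <- if (role == "discovery") config$n_discovery else config$n_validation
  doses <- if (role == "discovery") config$doses_discovery else config$doses_validation
  offset <- if (role == "discovery") 1L else 2L
  withr::with_seed(.derive_seed(config$seed, offset), {
    ids <- sprintf("%s_%03d", toupper(substr(role, 1, 3)), seq_len(n))
    tissue_idx <- sample.int(config$n_tissues, n, replace = TRUE)
    tissue <- names(shared$tissue_shifts)[tissue_idx]
    alpha <- pmax(config$alpha_floor,
                  rnorm(n, config$alpha_mean + shared$tissue_shifts[tissue_idx],
                        config$alpha_sd))
    ratio <- runif(n, config$ab_ratio_range[1], config$ab_ratio_range[2])
    beta <- alpha / ratio
    dmax <- max(doses)
    auc_true <- vapply(seq_len(n), function(i) compute_auc(alpha[i], beta[i], dmax),
                       numeric(1))
    sf2_true <- exp(-2 * alpha - 4 * beta)
    surv <- lapply(seq_len(n), function(i) {
      s <- exp(-alpha[i] * doses - beta[i] * doses^2)
      if (config$sigma_s > 0) s <- s * exp(rnorm(length(doses), 0, config$sigma_s))
      s
    })
    z_auc <- (auc_true - mean(auc_true)) / sd(auc_true)
    expr <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes,
                   dimnames = list(shared$gene_ids, ids))
    sig_idx <- match(shared$signal_genes, shared$gene_ids)
    expr[sig_idx, ] <- outer(shared$effects, z_auc) +
      matrix(rnorm(length(sig_idx) * n, 0, config$expr_noise_sd),
             nrow = length(sig_idx))
    if (role == "validation") {
      loc <- rnorm(config$n_genes, 0, config$platform_loc_sd)
      scl <- runif(config$n_genes, config$platform_scale_range[1],
                   config$platform_scale_range[2])
      expr <- expr * scl + loc
    }
    drs <- lapply(seq_len(n), function(i)
      dose_response(ids[i], doses, surv[[i]], tissue = tissue[i]))
    dose_table <- data.frame(
      cell_line = rep(ids, each = length(doses)),
      tissue = rep(tissue, each = length(doses)),
      dose_gy = rep(doses, n),
      survival = unlist(surv),
      stringsAsFactors = FALSE
    )
    structure(
      list(role = role, dose_response = drs, dose_table = dose_table,
           expression = expr, tissue = setNames(tissue, ids),
           truth = list(
             cell_lines = data.frame(cell_line = ids, tissue = tissue,
                                     alpha = alpha, beta = beta,
                                     auc_true = auc_true, sf2_true = sf2_true,
                                     stringsAsFactors = FALSE),
             signal_genes = shared$signal_genes, effects = shared$effects,
             doses = doses, dmax = dmax),
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' Generate a gene-set collection with planted enrichment
#'
#' Builds `n_planted` sets drawn mostly (`frac_signal`, default 80%) from the
#' cohort's signal genes — which are strongly correlated with true AUC and
#' therefore genuinely enriched — plus `n_null` sets sampled uniformly from
#' the gene universe. Each planted set draws its signal members from genes of
#' a coherent effect sign (alternating positive/negative across sets), the
#' way a real pathway is enriched in one direction; a sign-mixed set would
#' scatter its hits across both ends of the ranked list and carry no
#' running-sum signal. Set names encode the ground truth (`PLANTED_*`,
#' `NULL_*`) so tests can assert against them.
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_planted,n_null numbers of planted and null sets.
#' @param set_size_range inclusive range of set sizes.
#' @param frac_signal minimum fraction of planted-set members drawn from
#'   signal genes (default 0.8).
#' @param seed integer seed (default derives from the cohort's config seed).
#' @return Named list of character vectors, with attribute `planted` naming
#'   the planted sets.
#' @export
generate_genesets <- function(cohort, n_planted = 5, n_null = 45,
                              set_size_range = c(10, 30), frac_signal = 0.8,
                              seed = .derive_seed(cohort$config$seed, 3)) {
  universe <- rownames(cohort$expression)
  signal <- cohort$truth$signal_genes
  if (set_size_range[2] > length(universe))
    .stop_invalid("set sizes exceed the gene universe")
  if (n_planted > 0 && ceiling(frac_signal * set_size_range[2]) > length(signal))
    .stop_invalid("planted sets would need more signal genes than exist")
  background <- setdiff(universe, signal)
  pools <- list(signal[cohort$truth$effects > 0], signal[cohort$truth$effects < 0])
  withr::with_seed(seed, {
    sets <- list()
    for (i in seq_len(n_planted)) {
      s <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      n_sig <- ceiling(frac_signal * s)
      pool <- pools[[(i %% 2) + 1]]
      other <- pools[[2 - (i %% 2)]]
      take <- min(n_sig, length(pool))
      members <- sample(pool, take)
      if (take < n_sig) members <- c(members, sample(other, n_sig - take))
      sets[[sprintf("PLANTED_%02d", i)]] <-
        c(members, sample(background, s - n_sig))
    }
    for (i in seq_len(n_null)) {
      s <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      sets[[sprintf("NULL_%02d", i)]] <- sample(universe, s)
    }
    attr(sets, "planted") <- grep("^PLANTED_", names(sets), value = TRUE)
    sets
  })
}

#' Ground-truth export for a synthetic cohort
#'
#' Per-line true parameters and indicators with resistant/sensitive labels
#' re-derived from true AUC via the mean threshold, plus per-gene signal
#' flags and effects.
#'
#' @param cohort a `synthetic_cohort`.
#' @return List with `cell_lines` (cell_line, tissue, alpha, beta, auc_true,
#'   sf2_true, group) and `genes` (gene, signal, effect) data frames.
#' @export
truth_table <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort"))
    .stop_invalid("cohort must come from generate_cohort()")
  cl <- cohort$truth$cell_lines
  cl$group <- stratify_by_mean(cl$auc_true)$group
  genes <- data.frame(
    gene = rownames(cohort$expression),
    signal = rownames(cohort$expression) %in% cohort$truth$signal_genes,
    effect = 0, stringsAsFactors = FALSE
  )
  genes$effect[match(names(cohort$truth$effects), genes$gene)] <-
    as.numeric(cohort$truth$effects)
  list(cell_lines = cl, genes = genes)
}
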