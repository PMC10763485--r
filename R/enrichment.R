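# Permutation-based gene-set enrichment against a radioresponse indicator.
#
# Genes are ranked by Spearman correlation with the indicator (AUC or SF2);
# a weighted Kolmogorov-Smirnov running sum over the ranked list gives each
# pathway an enrichment score (ES, the signed maximum deviation from zero);
# significance comes from a gene-label permutation null with add-one
# correction; Benjamini-Hochberg controls the FDR within each collection.

#' Rank genes by Spearman correlation with a response
#'
#' Computes per-gene Spearman correlation between expression and a per-sample
#' response (e.g. AUC or SF2) and returns genes sorted by decreasing
#' correlation. Constant genes are retained with rho = 0 (with a warning);
#' ties in rho are broken lexicographically by gene id so the ordering is
#' deterministic.
#'
#' @param expr numeric matrix, genes x samples, with unique rownames
#'   (gene ids); columns aligned with `response`.
#' @param response numeric vector, one value per sample.
#' @return `data.frame` of class `ranked_list` with columns `gene` and `rho`,
#'   sorted by decreasing `rho`.
#' @export
rank_genes <- function(expr, response) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    .stop_invalid("expr must have unique rownames (gene ids)")
  if (ncol(expr) != length(response))
    .stop_invalid("expr columns and response must be aligned")
  if (length(response) < 3)
    .stop_invalid("at least 3 samples are required to rank genes")
  rho <- .spearman_rows(expr, response)
  n_const <- sum(is.na(rho))
  if (n_const > 0) {
    warning(sprintf("%d constant gene(s) assigned rho = 0", n_const))
    rho[is.na(rho)] <- 0
  }
  ord <- order(-rho, rownames(expr))
  structure(
    data.frame(gene = rownames(expr)[ord], rho = rho[ord],
               stringsAsFactors = FALSE),
    class = c("ranked_list", "data.frame")
  )
}

# vectorised Spearman: rank rows and the response, then Pearson algebra.
# Constant rows return NA.
.spearman_rows <- function(expr, response) {
  gr <- t(apply(expr, 1, rank))
  if (nrow(expr) == 1) gr <- matrix(gr, nrow = 1)  # apply drops dims
  rr <- rank(response)
  grc <- gr - rowMeans(gr)
  rc <- rr - mean(rr)
  den <- sqrt(rowSums(grc^2)) * sqrt(sum(rc^2))
  num <- as.vector(grc %*% rc)
  rho <- ifelse(den > 0, num / den, NA_real_)
  names(rho) <- rownames(expr)
  rho
}

# Core running-sum statistic evaluated only at hit positions.
# stat_sorted: per-gene statistics in ranked (descending) order.
# pos: sorted positions of the set's genes in that order. Returns es, the
# index of the extremum within pos, and its sign.
.es_at_positions <- function(stat_sorted, pos, p) {
  m <- length(pos)
  n <- length(stat_sorted)
  w <- abs(stat_sorted[pos])^p
  tot <- sum(w)
  if (tot == 0) { w <- rep(1, m); tot <- m }  # all-zero stats: unweighted
  miss_step <- if (n > m) 1 / (n - m) else 0
  cw <- cumsum(w)
  misses <- (pos - seq_len(m)) * miss_step
  at_hit <- cw / tot - misses          # running sum just after each hit
  before_hit <- (cw - w) / tot - misses  # just before each hit (local minima)
  es_pos <- max(at_hit)
  es_neg <- min(before_hit)
  # ties in |es| go to the positive side; the 1e-12 cushion keeps the choice
  # stable across algebraically equivalent evaluation orders
  if (es_pos >= -es_neg - 1e-12) {
    list(es = es_pos, hit_index = which.max(at_hit), positive = TRUE)
  } else {
    list(es = es_neg, hit_index = which.min(before_hit), positive = FALSE)
  }
}

#' GSEA enrichment score of a gene set on a ranked list
#'
#' Classic running-sum enrichment statistic: walking down the ranked list,
#' genes in the set increment the sum by their weight
#' `|statistic|^weight_exponent` (normalised by the total over set members)
#' and genes outside the set decrement it by `1/(N - Nh)`. The enrichment
#' score is the signed maximum deviation of this sum from zero. With
#' `weight_exponent = 0` the statistic reduces to the unweighted
#' Kolmogorov-Smirnov form.
#'
#' @param ranked a `ranked_list` from [rank_genes()], or a named numeric
#'   vector of per-gene statistics already sorted in decreasing order.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent weight on `|statistic|` (default 1, classic
#'   weighted GSEA; 0 gives the unweighted form).
#' @return List with `es` (in `[-1, 1]`), `running_sum` (length-N numeric),
#'   `hit_positions` (ranks of set members), `peak` (rank at which the
#'   extremum is attained) and `leading_edge` (gene ids driving the score);
#'   `NULL` (with a warning) if the set does not intersect the ranked genes.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  st <- .ranked_stats(ranked)
  pos <- sort(which(names(st) %in% gene_set))
  if (length(pos) == 0) {
    warning("gene set has empty intersection with the ranked list; skipped")
    return(NULL)
  }
  res <- .es_at_positions(st, pos, weight_exponent)
  n <- length(st); m <- length(pos)
  w <- abs(st[pos])^weight_exponent
  if (sum(w) == 0) w <- rep(1, m)
  step <- rep(if (n > m) -1 / (n - m) else 0, n)
  step[pos] <- w / sum(w)
  running <- cumsum(step)
  if (res$positive) {
    peak <- pos[res$hit_index]
    le <- names(st)[pos[pos <= peak]]
  } else {
    peak <- pos[res$hit_index] - 1L  # minimum sits just before the hit
    le <- names(st)[pos[pos > peak]]
  }
  list(es = unname(res$es), running_sum = unname(running),
       hit_positions = pos, peak = peak, leading_edge = le)
}

.ranked_stats <- function(ranked) {
  if (inherits(ranked, "ranked_list") ||
      (is.data.frame(ranked) && all(c("gene", "rho") %in% names(ranked)))) {
    setNames(ranked$rho, ranked$gene)
  } else if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked
  } else .stop_invalid("ranked must be a ranked_list or a named numeric vector")
}

#' Leading-edge genes of an enrichment result
#'
#' The set members that drive the enrichment score: for a positive ES, the
#' hits at ranks up to the running-sum maximum; for a negative ES, the hits
#' after the running-sum minimum.
#'
#' @inheritParams enrichment_score
#' @return Character vector of gene ids (a subset of `gene_set`).
#' @export
extract_leading_edge <- function(ranked, gene_set, weight_exponent = 1) {
  res <- enrichment_score(ranked, gene_set, weight_exponent)
  if (is.null(res)) character(0) else res$leading_edge
}

#' Permutation p-value for an enrichment score
#'
#' Gene-label permutation null: `n_perm` random gene sets of the same size
#' are drawn from the ranked universe and scored; the two-sided p-value is
#' `(1 + #\{|ES_perm| >= |ES_obs|\}) / (n_perm + 1)` (add-one correction, so
#' p >= 1/(n_perm+1)).
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return Nominal p-value in (0, 1].
#' @export
permutation_pvalue <- function(ranked, gene_set, n_perm = 1000, seed = NULL,
                               weight_exponent = 1) {
  if (n_perm < 100) .stop_invalid("n_perm must be >= 100")
  st <- .ranked_stats(ranked)
  pos <- sort(which(names(st) %in% gene_set))
  m <- length(pos)
  if (m == 0) .stop_invalid("gene set has empty intersection with the universe")
  if (m > length(st)) .stop_invalid("gene set larger than the ranked universe")
  es_obs <- .es_at_positions(st, pos, weight_exponent)$es
  draw <- function() {
    hits <- 0L
    n <- length(st)
    for (i in seq_len(n_perm)) {
      es_p <- .es_at_positions(st, sort(sample.int(n, m)), weight_exponent)$es
      if (abs(es_p) >= abs(es_obs)) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction of nominal p-values,
#' order-preserving with respect to the input indexing. Delegates to
#' [stats::p.adjust()] after validating the domain.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return FDR (q) values, same length and order as the input.
#' @export
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    .stop_invalid("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Enrichment analysis of a gene-set collection
#'
#' Ranks genes once against the response, filters sets by size after
#' intersection with the measured genes, computes the enrichment score and a
#' permutation p-value per set, corrects across the collection with
#' Benjamini-Hochberg, and flags sets significant at `fdr < fdr_threshold`.
#' FDR is controlled within the collection (i.e. per pathway database).
#'
#' @param expr genes x samples expression matrix (log scale).
#' @param response per-sample radioresponse indicator (AUC or SF2 values).
#' @param collection named list of character vectors (gene sets), e.g. from
#'   [read_gmt()] or [generate_genesets()].
#' @param n_perm permutations per set (default 1000).
#' @param seed optional integer seed for the permutation null.
#' @param fdr_threshold significance threshold on the FDR (default 0.10).
#' @param weight_exponent GSEA weight (default 1).
#' @param min_size,max_size set-size bounds after intersection with measured
#'   genes (defaults 10 and 500); degenerate sets outside the bounds are
#'   excluded with a message.
#' @param permutation null scheme: `"gene"` (default; random same-size gene
#'   sets) or `"sample"` (response permutation with re-ranking; slower).
#' @return `data.frame` of class `enrichment_result`: one row per analysed
#'   set with `pathway`, `es`, `p_nominal`, `fdr`, `direction`
#'   ("positive"/"negative" = sign of es), `set_size_used`, `significant`,
#'   and a `leading_edge` list-column.
#' @export
enrich_collection <- function(expr, response, collection, n_perm = 1000,
                              seed = NULL, fdr_threshold = 0.10,
                              weight_exponent = 1, min_size = 10,
                              max_size = 500,
                              permutation = c("gene", "sample")) {
  permutation <- match.arg(permutation)
  if (length(collection) == 0) .stop_invalid("collection is empty")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    .stop_invalid("collection must have unique set names")
  ranked <- rank_genes(expr, response)
  st <- .ranked_stats(ranked)
  sizes <- vapply(collection, function(g) sum(names(st) %in% g), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message(sprintf("%d set(s) excluded by size filter [%d, %d]",
                    sum(!keep), min_size, max_size))
  if (!any(keep)) {
    warning("all gene sets were filtered out")
    out <- data.frame(pathway = character(0), es = numeric(0),
                      p_nominal = numeric(0), fdr = numeric(0),
                      direction = character(0), set_size_used = integer(0),
                      significant = logical(0))
    out$leading_edge <- list()
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  collection <- collection[keep]
  set_seeds <- if (is.null(seed)) rep(list(NULL), length(collection)) else
    as.list(seed + seq_along(collection))
  if (permutation == "sample" && !is.null(seed)) {
    perm_rankings <- withr::with_seed(seed, lapply(seq_len(n_perm), function(i)
      .ranked_stats(rank_genes(expr, sample(response)))))
  } else if (permutation == "sample") {
    perm_rankings <- lapply(seq_len(n_perm), function(i)
      .ranked_stats(rank_genes(expr, sample(response))))
  }
  rows <- lapply(seq_along(collection), function(i) {
    gs <- collection[[i]]
    esr <- enrichment_score(ranked, gs, weight_exponent)
    if (permutation == "gene") {
      p <- permutation_pvalue(ranked, gs, n_perm = n_perm,
                              seed = set_seeds[[i]],
                              weight_exponent = weight_exponent)
    } else {
      es_null <- vapply(perm_rankings, function(stp) {
        pos <- sort(which(names(stp) %in% gs))
        .es_at_positions(stp, pos, weight_exponent)$es
      }, numeric(1))
      p <- (1 + sum(abs(es_null) >= abs(esr$es))) / (n_perm + 1)
    }
    list(pathway = names(collection)[i], es = esr$es, p_nominal = p,
         set_size_used = length(esr$hit_positions),
         leading_edge = esr$leading_edge)
  })
  out <- data.frame(
    pathway = vapply(rows, `[[`, character(1), "pathway"),
    es = vapply(rows, `[[`, numeric(1), "es"),
    p_nominal = vapply(rows, `[[`, numeric(1), "p_nominal"),
    set_size_used = vapply(rows, `[[`, integer(1), "set_size_used"),
    stringsAsFactors = FALSE
  )
  out$fdr <- adjust_bh(out$p_nominal)
  out$direction <- ifelse(out$es >= 0, "positive", "negative")
  out$significant <- out$fdr < fdr_threshold
  out$leading_edge <- lapply(rows, `[[`, "leading_edge")
  out <- out[, c("pathway", "es", "p_nominal", "fdr", "direction",
                 "set_size_used", "significant", "leading_edge")]
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Compare pathways enriched by two radioresponse indicators
#'
#' Set algebra on the significantly enriched pathway names of two enrichment
#' runs (typically AUC vs SF2 on the same collection): common pathways,
#' pathways unique to each indicator, and per-direction counts.
#'
#' @param results_auc,results_sf2 `enrichment_result` objects from
#'   [enrich_collection()] computed on the same collection.
#' @return List of class `indicator_comparison` with elements `auc_enriched`,
#'   `sf2_enriched`, `common`, `unique_to_auc`, `unique_to_sf2`, and `counts`
#'   (a data frame of enriched / positive / negative counts per indicator).
#' @export
compare_indicators <- function(results_auc, results_sf2) {
  if (!setequal(results_auc$pathway, results_sf2$pathway))
    .stop_invalid("the two result sets were not computed on the same collection")
  sig_a <- results_auc$pathway[results_auc$significant]
  sig_s <- results_sf2$pathway[results_sf2$significant]
  dir_counts <- function(res) {
    sig <- res[res$significant, , drop = FALSE]
    c(enriched = nrow(sig),
      positive = sum(sig$direction == "positive"),
      negative = sum(sig$direction == "negative"))
  }
  structure(
    list(auc_enriched = sig_a, sf2_enriched = sig_s,
         common = intersect(sig_a, sig_s),
         unique_to_auc = setdiff(sig_a, sig_s),
         unique_to_sf2 = setdiff(sig_s, sig_a),
         counts = data.frame(indicator = c("AUC", "SF2"),
                             rbind(dir_counts(results_auc),
                                   dir_counts(results_sf2)))),
    class = "indicator_comparison"
  )
}

#' @export
print.indicator_comparison <- function(x, ...) {
  cat(sprintf("Enriched pathways: AUC %d, SF2 %d; common %d; AUC-only %d; SF2-only %d\n",
              length(x$auc_enriched), length(x$sf2_enriched),
              length(x$common), length(x$unique_to_auc),
              length(x$unique_to_sf2)))
  invisible(x)
}

#' Leading-edge gene overlap across commonly enriched pathways
#'
#' For pathways significantly enriched by both indicators, takes the union of
#' leading-edge genes per indicator and reports the intersection and the
#' genes unique to each — i.e. whether the same genes drive the shared
#' pathway signal under AUC and under SF2.
#'
#' @param comparison an `indicator_comparison` from [compare_indicators()].
#' @param results_auc,results_sf2 the underlying `enrichment_result` objects.
#' @return List with `auc_genes`, `sf2_genes` (union leading edges), `common`,
#'   `unique_to_auc`, `unique_to_sf2`, and a `counts` summary vector.
#' @export
leading_edge_overlap <- function(comparison, results_auc, results_sf2) {
  common_pw <- comparison$common
  if (length(common_pw) == 0) {
    warning("no commonly enriched pathways; empty leading-edge summary")
    return(list(auc_genes = character(0), sf2_genes = character(0),
                common = character(0), unique_to_auc = character(0),
                unique_to_sf2 = character(0),
                counts = c(auc = 0L, sf2 = 0L, common = 0L,
                           unique_to_auc = 0L, unique_to_sf2 = 0L)))
  }
  le_union <- function(res) {
    idx <- match(common_pw, res$pathway)
    unique(unlist(res$leading_edge[idx]))
  }
  ga <- le_union(results_auc)
  gs <- le_union(results_sf2)
  list(auc_genes = ga, sf2_genes = gs,
       common = intersect(ga, gs),
       unique_to_auc = setdiff(ga, gs),
       unique_to_sf2 = setdiff(gs, ga),
       counts = c(auc = length(ga), sf2 = length(gs),
                  common = length(intersect(ga, gs)),
                  unique_to_auc = length(setdiff(ga, gs)),
                  unique_to_sf2 = length(setdiff(gs, ga))))
}
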