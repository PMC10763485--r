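# Gene ranking, running-sum enrichment score, permutation null, FDR and
# indicator comparison.

test_that("gene ranking reproduces Spearman correlation with deterministic ties", {
  expr <- rbind(
    ident = c(3, 1, 2, 5, 4),          # equals the response
    g1 = c(1, 2, 3, 4, 5),             # rank-difference closed form: rho 0.6
    flat = rep(2, 5)                   # constant
  )
  colnames(expr) <- paste0("s", 1:5)
  response <- c(3, 1, 2, 5, 4)
  expect_warning(rl <- rank_genes(expr, response), "constant")
  expect_identical(rl$gene[1], "ident")
  expect_equal(rl$rho[1], 1)
  expect_equal(rl$rho[rl$gene == "g1"], 1 - 6 * 8 / (5 * 24))
  expect_equal(rl$rho[rl$gene == "flat"], 0)

  # agrees with the reference implementation on random data
  set.seed(21)
  m <- matrix(rnorm(200), nrow = 20,
              dimnames = list(sprintf("r%02d", 1:20), NULL))
  y <- rnorm(10)
  rl2 <- rank_genes(m, y)
  ref <- apply(m, 1, function(x) cor(x, y, method = "spearman"))
  expect_equal(rl2$rho, unname(sort(ref, decreasing = TRUE)), tolerance = 1e-12)

  # equal-rho genes sort lexicographically
  tie <- rbind(b = c(1, 2, 3, 4), a = c(1, 2, 3, 4))
  rl3 <- rank_genes(tie, c(1, 2, 3, 4))
  expect_identical(rl3$gene, c("a", "b"))
  expect_error(rank_genes(m[, 1:2], y[1:2]), "3 samples")
})

test_that("enrichment score matches hand cases and the brute-force running sum", {
  st <- setNames(c(3, 2, 1, -1), paste0("g", 1:4))
  top <- enrichment_score(st, "g1", weight_exponent = 0)
  expect_equal(top$es, 1.0)
  expect_equal(top$running_sum[1], 1.0)
  expect_identical(top$leading_edge, "g1")

  sat <- enrichment_score(st, paste0("g", 1:4), weight_exponent = 0)
  expect_equal(sat$es, 1.0)

  st6 <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  mine <- enrichment_score(st6, c("g1", "g6"), weight_exponent = 1)
  orc <- oracle_es(st6, c("g1", "g6"), 1)
  expect_equal(mine$es, orc$es)
  expect_equal(mine$running_sum, orc$running)

  expect_warning(none <- enrichment_score(st6, c("zz")), "empty intersection")
  expect_null(none)

  # randomized equivalence on small universes, both exponents
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("x%02d", sample.int(n))
    gs <- sample(names(stats), sample.int(n - 1, 1))
    for (p in c(0, 1)) {
      got <- enrichment_score(stats, gs, p)
      want <- oracle_es(stats, gs, p)
      expect_equal(got$es, want$es, tolerance = 1e-12)
      expect_identical(got$leading_edge, want$leading_edge)
      expect_true(abs(got$es) <= 1 + 1e-12)
    }
  }
})

test_that("reversing the ranked list with negated statistics negates the score", {
  set.seed(11)
  n <- 15
  stats <- sort(rnorm(n), decreasing = TRUE)
  names(stats) <- sprintf("y%02d", 1:n)
  gs <- sample(names(stats), 5)
  fwd <- enrichment_score(stats, gs, weight_exponent = 1)
  rev_stats <- rev(-stats)
  bwd <- enrichment_score(rev_stats, gs, weight_exponent = 1)
  expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
})

test_that("permutation p-values respect the add-one floor and the exact null", {
  # observed score strictly above every achievable permuted score
  st <- setNames(seq(100, 1), sprintf("g%03d", 1:100))
  p <- permutation_pvalue(st, names(st)[1:5], n_perm = 999, seed = 4)
  expect_equal(p, 1 / 1000)
  expect_error(permutation_pvalue(st, names(st)[1:5], n_perm = 10), "n_perm")

  # universe of 6, set of 2: sampled p within binomial error of the
  # exhaustive 15-subset null
  st6 <- setNames(c(2.5, 1.2, 0.4, -0.3, -1.1, -2.2), paste0("h", 1:6))
  gs <- c("h1", "h2")
  es_obs <- abs(enrichment_score(st6, gs)$es)
  combos <- combn(names(st6), 2)
  es_all <- apply(combos, 2, function(g) abs(enrichment_score(st6, g)$es))
  p_exact <- mean(es_all >= es_obs - 1e-12)
  p_hat <- permutation_pvalue(st6, gs, n_perm = 2000, seed = 9)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p_hat - p_exact), 3 * se + 2 / 2000)

  # identical seed, identical p
  expect_identical(permutation_pvalue(st, names(st)[3:12], n_perm = 199, seed = 5),
                   permutation_pvalue(st, names(st)[3:12], n_perm = 199, seed = 5))
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.04), 0.04)
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  p <- runif(50)
  q <- adjust_bh(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("collection-level enrichment flags planted sets and filters degenerate ones", {
  sc <- make_small_cohort()
  coll <- list(
    PLANTED = sc$signal,
    NULLSET1 = sample(sc$genes[-seq_len(15)], 20),
    NULLSET2 = sample(sc$genes[-seq_len(15)], 25),
    TINY = sc$genes[1:3],                 # below min_size
    ALIEN = c("nope1", "nope2", "nope3")  # empty intersection
  )
  expect_message(
    res <- enrich_collection(sc$expr, sc$response, coll, n_perm = 200,
                             seed = 17, min_size = 10),
    "excluded by size filter")
  expect_setequal(res$pathway, c("PLANTED", "NULLSET1", "NULLSET2"))
  planted <- res[res$pathway == "PLANTED", ]
  expect_true(planted$significant)
  expect_identical(planted$direction, "positive")
  expect_true(all(res$leading_edge[[which(res$pathway == "PLANTED")]] %in% sc$signal))

  # reproducible under the same seed
  res2 <- suppressMessages(
    enrich_collection(sc$expr, sc$response, coll, n_perm = 200, seed = 17))
  expect_identical(res$p_nominal, res2$p_nominal)
})

test_that("null cohorts keep the nominal false-positive level", {
  set.seed(31)
  fps <- numeric(10)
  for (r in 1:10) {
    n_genes <- 150
    expr <- matrix(rnorm(n_genes * 30), nrow = n_genes,
                   dimnames = list(sprintf("n%03d", 1:n_genes), NULL))
    response <- rnorm(30)
    coll <- lapply(1:20, function(i) sample(rownames(expr), 15))
    names(coll) <- sprintf("S%02d", 1:20)
    res <- enrich_collection(expr, response, coll, n_perm = 100, seed = 100 + r)
    fps[r] <- mean(res$p_nominal < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / (10 * 20))
  expect_lt(mean(fps), 0.05 + 3 * se)
})

test_that("indicator comparison recovers planted shared and AUC-only structure", {
  a <- data.frame(pathway = c("a", "b", "c"), significant = c(TRUE, TRUE, FALSE),
                  direction = "positive")
  b <- data.frame(pathway = c("a", "b", "c"), significant = c(TRUE, TRUE, FALSE),
                  direction = "positive")
  cmp <- compare_indicators(a, b)
  expect_length(cmp$unique_to_auc, 0)
  expect_length(cmp$unique_to_sf2, 0)

  b2 <- data.frame(pathway = c("a", "b", "c"), significant = c(FALSE, FALSE, TRUE),
                   direction = "negative")
  cmp2 <- compare_indicators(a, b2)
  expect_setequal(cmp2$unique_to_auc, c("a", "b"))
  expect_setequal(cmp2$unique_to_sf2, "c")
  expect_length(cmp2$common, 0)
  # partition invariant
  expect_equal(length(cmp2$auc_enriched),
               length(cmp2$common) + length(cmp2$unique_to_auc))
  expect_error(compare_indicators(a, b2[1:2, ]), "same collection")

  # construction: AUC = f + g, SF2 = f; shared set tracks f, AUC-only set
  # tracks g, so SF2 enriches only the shared set
  withr::with_seed(55, {
    n <- 100
    f <- rnorm(n); g <- rnorm(n)
    auc <- f + g
    sf2 <- f
    genes <- sprintf("q%03d", 1:120)
    expr <- matrix(rnorm(120 * n), nrow = 120, dimnames = list(genes, NULL))
    shared_set <- genes[1:12]
    auconly_set <- genes[13:24]
    expr[shared_set, ] <- outer(runif(12, 1, 1.6), scale(f)[, 1]) +
      matrix(rnorm(12 * n, 0, 0.6), nrow = 12)
    expr[auconly_set, ] <- outer(runif(12, 1, 1.6), scale(g)[, 1]) +
      matrix(rnorm(12 * n, 0, 0.6), nrow = 12)
    coll <- c(list(SHARED = shared_set, AUCONLY = auconly_set),
              setNames(lapply(1:10, function(i) sample(genes[25:120], 12)),
                       sprintf("N%02d", 1:10)))
    res_auc <- enrich_collection(expr, auc, coll, n_perm = 200, seed = 61)
    res_sf2 <- enrich_collection(expr, sf2, coll, n_perm = 200, seed = 62)
    cmp3 <- compare_indicators(res_auc, res_sf2)
    expect_true("SHARED" %in% cmp3$common)
    expect_true("AUCONLY" %in% cmp3$unique_to_auc)
  })
})

test_that("leading-edge extraction and overlap follow the running-sum extremum", {
  st <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.2, 0.1), paste0("g", 1:8))
  # hits at ranks 1, 2 and 8; peak after rank 2
  le <- extract_leading_edge(st, c("g1", "g2", "g8"))
  expect_identical(le, c("g1", "g2"))
  # negated mirror: the tail hits drive a negative score
  st_neg <- rev(-st)
  le_neg <- extract_leading_edge(st_neg, c("g1", "g2", "g8"))
  expect_setequal(le_neg, c("g1", "g2"))

  mk <- function(pathways, ledges) {
    r <- data.frame(pathway = pathways, significant = TRUE, direction = "positive")
    r$leading_edge <- ledges
    r
  }
  ra <- mk(c("p1", "p2"), list(c("a", "b"), c("c")))
  rb <- mk(c("p1", "p2"), list(c("b"), c("c", "d")))
  cmp <- compare_indicators(ra, rb)
  ov <- leading_edge_overlap(cmp, ra, rb)
  expect_setequal(ov$common, c("b", "c"))
  expect_setequal(ov$unique_to_auc, "a")
  expect_setequal(ov$unique_to_sf2, "d")
  ov_same <- leading_edge_overlap(cmp, ra, ra)
  expect_length(ov_same$unique_to_auc, 0)
  cmp_none <- compare_indicators(mk("p1", list("a"))[0, ], mk("p1", list("a"))[0, ])
  expect_warning(ov0 <- leading_edge_overlap(cmp_none, ra, rb), "no commonly")
  expect_identical(unname(ov0$counts["common"]), 0L)
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("f%03d", 1:n)
    gs <- sample(names(stats), sample(5:12, 1))
    mine <- enrichment_score(stats, gs, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% gs),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})
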