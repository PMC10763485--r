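# Independent oracles used across the suite. Each reimplements the checked
# quantity by direct enumeration, kept deliberately naive and separate from
# the package's code paths.

# position-by-position GSEA running sum
oracle_es <- function(stats_sorted, set_genes, p) {
  n <- length(stats_sorted)
  hits <- names(stats_sorted) %in% set_genes
  m <- sum(hits)
  w <- abs(stats_sorted)^p
  tot <- sum(w[hits])
  if (tot == 0) {
    w[hits] <- 1
    tot <- m
  }
  step <- ifelse(hits, w / tot, if (n > m) -1 / (n - m) else 0)
  run <- unname(cumsum(step))
  if (max(run) >= -min(run) - 1e-12) {  # tie to positive, as in the package
    es <- max(run)
    peak <- which.max(run)
    le <- names(stats_sorted)[hits & seq_len(n) <= peak]
  } else {
    es <- min(run)
    peak <- which.min(run)
    le <- names(stats_sorted)[hits & seq_len(n) > peak]
  }
  list(es = es, running = run, leading_edge = le)
}

# O(n^2) pairwise concordance with the usual tie conventions
oracle_cindex <- function(pred, obs) {
  num <- 0
  den <- 0
  n <- length(obs)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (obs[i] == obs[j]) next
      den <- den + 1
      if (pred[i] == pred[j]) {
        num <- num + 0.5
      } else if ((pred[i] < pred[j]) == (obs[i] < obs[j])) {
        num <- num + 1
      }
    }
  }
  num / den
}

# Benjamini-Hochberg step-up, written out directly
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q <- numeric(m)
  q[o] <- pmin(qs, 1)
  q
}

# noiseless or lognormal-noise LQ survival on a dose grid
make_survival <- function(alpha, beta, doses, sigma = 0, seed = NULL) {
  s <- exp(-alpha * doses - beta * doses^2)
  if (sigma > 0) {
    s <- withr::with_seed(seed, s * exp(rnorm(length(doses), 0, sigma)))
  }
  s
}

# dense grid search minimising the same -ln(S) least-squares objective
oracle_lq_grid <- function(doses, survival, a_range, b_range, step_a, step_b) {
  y <- -log(survival)
  a <- seq(a_range[1], a_range[2], by = step_a)
  b <- seq(b_range[1], b_range[2], by = step_b)
  sd2 <- sum(doses^2); sd3 <- sum(doses^3); sd4 <- sum(doses^4)
  syd <- sum(y * doses); syd2 <- sum(y * doses^2)
  # rss(a,b) = const - 2(a*syd + b*syd2) + a^2*sd2 + 2ab*sd3 + b^2*sd4
  rss <- outer(a^2 * sd2 - 2 * a * syd, b^2 * sd4 - 2 * b * syd2, "+") +
    2 * outer(a, b) * sd3
  idx <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  c(alpha = a[idx[1]], beta = b[idx[2]])
}

# small aligned expression/response fixture with one planted block
make_small_cohort <- function(n_samples = 60, n_genes = 200, n_signal = 15,
                              seed = 42) {
  withr::with_seed(seed, {
    response <- rnorm(n_samples)
    genes <- sprintf("g%03d", seq_len(n_genes))
    expr <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
                   dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
    signal <- genes[seq_len(n_signal)]
    expr[signal, ] <- outer(runif(n_signal, 0.8, 1.5), scale(response)[, 1]) +
      matrix(rnorm(n_signal * n_samples, 0, 0.8), nrow = n_signal)
    list(expr = expr, response = response, signal = signal, genes = genes)
  })
}
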