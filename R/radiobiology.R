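# Linear-quadratic (LQ) model fitting and radioresponse indicators.
#
# The LQ model gives the surviving fraction after an acute dose D (Gy) as
#   S(D) = exp(-alpha*D - beta*D^2),
# with alpha (1/Gy) the single-hit killing coefficient and beta (1/Gy^2) the
# double-strand-break interaction term. Two scalar indicators summarise a
# fitted curve: SF2 = S(2 Gy), and AUC = integral of S over [0, dmax] (Gy).

#' Construct a dose-response record for one cell line
#'
#' Holds the (dose, surviving fraction) observations of a single cell line.
#' The implicit anchor S(0) = 1 is not stored. Survival values are sanitized
#' by clipping to `[1e-6, cap]` (with a warning) so the log transform used by
#' [fit_lq()] is defined; assay noise occasionally yields values above 1.
#'
#' @param cell_line character scalar, cell line identifier.
#' @param doses numeric vector of administered doses in Gy, all > 0; at least
#'   2 distinct values; replicate doses permitted.
#' @param survival numeric vector of surviving fractions, same length as
#'   `doses`.
#' @param tissue optional character scalar, tissue/histology label.
#' @param cap upper clip bound for survival after sanitization (default 1.5).
#' @return An object of class `dose_response`: a list with elements
#'   `cell_line`, `tissue`, `doses`, `survival`.
#' @export
dose_response <- function(cell_line, doses, survival, tissue = NA_character_,
                          cap = 1.5) {
  doses <- as.numeric(doses)
  survival <- as.numeric(survival)
  if (length(doses) != length(survival))
    .stop_invalid("doses and survival must have the same length")
  if (any(!is.finite(doses)) || any(doses <= 0))
    .stop_invalid("all doses must be finite and > 0")
  if (length(unique(doses)) < 2)
    .stop_invalid("at least 2 distinct dose values are required")
  if (any(!is.finite(survival)))
    .stop_invalid("survival values must be finite")
  n_clip <- sum(survival < 1e-6 | survival > cap)
  if (n_clip > 0) {
    warning(sprintf("%s: %d survival value(s) clipped to [1e-06, %g]",
                    cell_line, n_clip, cap))
    survival <- pmin(pmax(survival, 1e-6), cap)
  }
  structure(
    list(cell_line = as.character(cell_line), tissue = tissue,
         doses = doses, survival = survival),
    class = "dose_response"
  )
}

#' Surviving fraction under the linear-quadratic model
#'
#' Evaluates `S(D) = exp(-alpha*D - beta*D^2)`.
#'
#' @param dose numeric vector of doses in Gy, all >= 0.
#' @param alpha linear coefficient (1/Gy), >= 0.
#' @param beta quadratic coefficient (1/Gy^2), >= 0.
#' @return Surviving fraction(s) in (0, 1] for non-negative parameters.
#' @examples
#' lq_survival(2, alpha = 0.3, beta = 0.03)  # ~0.4868
#' @export
lq_survival <- function(dose, alpha, beta = 0) {
  if (any(!is.finite(dose)) || any(dose < 0))
    .stop_invalid("dose must be finite and >= 0")
  exp(-alpha * dose - beta * dose^2)
}

#' Surviving fraction at 2 Gy (SF2)
#'
#' The classical point-estimate radiosensitivity indicator: the fitted curve
#' evaluated at D = 2 Gy, i.e. `exp(-2*alpha - 4*beta)`.
#'
#' @param fit an `lq_fit` object from [fit_lq()], or a numeric alpha when
#'   `beta` is supplied.
#' @param beta quadratic coefficient, used only when `fit` is numeric.
#' @return SF2, dimensionless in (0, 1].
#' @export
compute_sf2 <- function(fit, beta = NULL) {
  if (inherits(fit, "lq_fit")) {
    alpha <- fit$alpha; beta <- fit$beta
  } else {
    alpha <- fit
    if (is.null(beta)) .stop_invalid("beta required when fit is numeric")
  }
  lq_survival(2, alpha, beta)
}

#' Integral of the LQ survival curve (AUC)
#'
#' Computes `integral_0^dmax exp(-alpha*D - beta*D^2) dD` in Gy, the
#' preferred radioresponse indicator: it integrates response over the whole
#' administered dose range rather than at a single dose point. Higher AUC
#' means more radioresistant.
#'
#' For `beta > 0` the Gaussian-integral closed form is used, evaluated
#' through upper-tail normal log-probabilities so that the
#' `exp(alpha^2 / (4*beta))` prefactor never overflows; for `beta = 0` the
#' exponential closed form; for `alpha = beta = 0` the integrand is 1 and the
#' result is `dmax`. If the closed form degenerates numerically the function
#' falls back to adaptive quadrature.
#'
#' @param alpha linear coefficient (1/Gy), >= 0.
#' @param beta quadratic coefficient (1/Gy^2), >= 0.
#' @param dmax integration upper bound in Gy, > 0 (the maximum administered
#'   dose for the cell line).
#' @return AUC in Gy, in (0, dmax].
#' @examples
#' compute_auc(0, 0, 8)      # 8
#' compute_auc(0.5, 0, 8)    # (1 - exp(-4)) / 0.5
#' compute_auc(0.3, 0.03, 8)
#' @export
compute_auc <- function(alpha, beta, dmax) {
  if (!is.finite(dmax) || dmax <= 0) .stop_invalid("dmax must be > 0")
  if (!is.finite(alpha) || alpha < 0 || !is.finite(beta) || beta < 0)
    .stop_invalid("alpha and beta must be finite and >= 0")
  if (beta == 0) {
    if (alpha == 0) return(dmax)
    return((1 - exp(-alpha * dmax)) / alpha)
  }
  # complete the square: S(D) = exp(c) * exp(-2*beta*(D + alpha/(2*beta))^2 / 2)
  # with c = alpha^2/(4*beta); integral expressed via upper normal tails at
  # a = alpha/sqrt(2*beta) and b = (alpha + 2*beta*dmax)/sqrt(2*beta), both
  # combined with c on the log scale for stability (c ~ a^2/2 cancels).
  s <- sqrt(2 * beta)
  a <- alpha / s
  b <- (alpha + 2 * beta * dmax) / s
  cc <- alpha^2 / (4 * beta)
  if (cc > 1e4) {
    # nearly-exponential regime: cc + log-tail cancellation would erode the
    # mantissa below the 1e-8 contract, so integrate directly
    return(integrate(function(d) exp(-alpha * d - beta * d^2), 0, dmax,
                     rel.tol = 1e-10)$value)
  }
  lq_a <- pnorm(a, lower.tail = FALSE, log.p = TRUE)
  lq_b <- pnorm(b, lower.tail = FALSE, log.p = TRUE)
  val <- sqrt(pi / beta) * (exp(cc + lq_a) - exp(cc + lq_b))
  if (!is.finite(val) || val <= 0 || val > dmax * (1 + 1e-12)) {
    val <- integrate(function(d) exp(-alpha * d - beta * d^2), 0, dmax,
                     rel.tol = 1e-10)$value
  }
  min(val, dmax)
}

#' Fit the linear-quadratic model to one cell line
#'
#' Linearized least squares on `y = -ln(S)` with regressors `D` and `D^2` and
#' no intercept (which enforces the anchor S(0) = 1), minimising
#' `sum (y - alpha*D - beta*D^2)^2`. Non-negativity of (alpha, beta) is
#' enforced by an active-set refit: if the unconstrained solution has a
#' negative coefficient, each single-parameter fit with the other coefficient
#' pinned at zero is evaluated (clamped at zero) and the feasible candidate
#' with the lowest residual sum of squares is returned. The procedure is
#' deterministic and closed-form.
#'
#' @param dr a [dose_response()] object, or a numeric dose vector when
#'   `survival` is supplied.
#' @param survival surviving fractions, used only when `dr` is numeric.
#' @param cap survival clip cap passed to [dose_response()] in the two-vector
#'   form.
#' @return An object of class `lq_fit`: list with `alpha`, `beta`, `auc`,
#'   `sf2`, `dmax` (max administered dose; AUC integration bound), `rss`
#'   (residual sum of squares on the -ln S scale), `n_points`, plus
#'   `cell_line` and `tissue` carried over.
#' @examples
#' d <- c(2, 4, 6, 8)
#' fit_lq(d, exp(-0.3 * d - 0.03 * d^2))
#' @export
fit_lq <- function(dr, survival = NULL, cap = 1.5) {
  if (!inherits(dr, "dose_response")) {
    dr <- dose_response("unnamed", dr, survival, cap = cap)
  }
  d <- dr$doses
  y <- -log(dr$survival)
  sd2 <- sum(d^2); sd3 <- sum(d^3); sd4 <- sum(d^4)
  syd <- sum(y * d); syd2 <- sum(y * d^2)
  det <- sd2 * sd4 - sd3^2
  rss_of <- function(a, b) sum((y - a * d - b * d^2)^2)
  if (abs(det) > .Machine$double.eps * sd2 * sd4) {
    a_u <- (syd * sd4 - syd2 * sd3) / det
    b_u <- (sd2 * syd2 - sd3 * syd) / det
  } else {
    a_u <- -1; b_u <- -1  # collinear design (single distinct dose is rejected upstream)
  }
  if (a_u >= 0 && b_u >= 0) {
    alpha <- a_u; beta <- b_u
  } else {
    cands <- list(c(max(0, syd / sd2), 0), c(0, max(0, syd2 / sd4)), c(0, 0))
    rss_c <- vapply(cands, function(p) rss_of(p[1], p[2]), numeric(1))
    best <- cands[[which.min(rss_c)]]
    alpha <- best[1]; beta <- best[2]
  }
  dmax <- max(d)
  structure(
    list(cell_line = dr$cell_line, tissue = dr$tissue,
         alpha = alpha, beta = beta,
         auc = compute_auc(alpha, beta, dmax),
         sf2 = lq_survival(2, alpha, beta),
         dmax = dmax, rss = rss_of(alpha, beta), n_points = length(d)),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf(
    "LQ fit [%s]: alpha = %.4f /Gy, beta = %.4f /Gy^2, AUC = %.3f Gy, SF2 = %.3f (n = %d, rss = %.3g)\n",
    x$cell_line, x$alpha, x$beta, x$auc, x$sf2, x$n_points, x$rss))
  invisible(x)
}

#' Fit the LQ model across a cohort
#'
#' Applies [fit_lq()] to each cell line and assembles a per-line table with
#' resistant/sensitive group labels from [stratify_by_mean()].
#'
#' @param drs list of [dose_response()] objects.
#' @return A `data.frame` of class `cohort_fits` with columns `cell_line`,
#'   `tissue`, `alpha`, `beta`, `auc`, `sf2`, `dmax`, `rss`, `n_points`,
#'   `group`, and attribute `threshold` (the cohort mean AUC in Gy).
#' @export
fit_cohort <- function(drs) {
  if (length(drs) < 2) .stop_invalid("a cohort needs at least 2 cell lines")
  fits <- lapply(drs, fit_lq)
  out <- data.frame(
    cell_line = vapply(fits, `[[`, character(1), "cell_line"),
    tissue = vapply(fits, function(f) as.character(f$tissue), character(1)),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    auc = vapply(fits, `[[`, numeric(1), "auc"),
    sf2 = vapply(fits, `[[`, numeric(1), "sf2"),
    dmax = vapply(fits, `[[`, numeric(1), "dmax"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    n_points = vapply(fits, `[[`, integer(1), "n_points"),
    stringsAsFactors = FALSE
  )
  strat <- stratify_by_mean(out$auc)
  out$group <- strat$group
  attr(out, "threshold") <- strat$threshold
  class(out) <- c("cohort_fits", class(out))
  out
}

#' Stratify a cohort into resistant and sensitive groups by mean AUC
#'
#' A cell line is labelled `resistant` iff its AUC is strictly greater than
#' the cohort mean AUC; ties at the threshold go to `sensitive`. Higher AUC
#' means more resistant.
#'
#' @param aucs numeric vector of per-line AUC values (Gy), length >= 2.
#' @return List with `group` (character vector of "resistant"/"sensitive")
#'   and `threshold` (the mean AUC in Gy).
#' @examples
#' stratify_by_mean(c(1, 2, 3, 6))  # only the 6 is resistant
#' @export
stratify_by_mean <- function(aucs) {
  if (length(aucs) < 2) .stop_invalid("need at least 2 cell lines to stratify")
  if (any(!is.finite(aucs))) .stop_invalid("AUC values must be finite")
  thr <- mean(aucs)
  group <- ifelse(aucs > thr, "resistant", "sensitive")
  if (all(group == "sensitive"))
    warning("degenerate stratification: no AUC exceeds the mean; all lines labelled sensitive")
  list(group = group, threshold = thr)
}

#' Per-tissue radioresponse summary
#'
#' Summarises AUC by tissue/histology, keeping only tissues with at least
#' `min_n` cell lines, sorted by median AUC ascending (most sensitive tissue
#' first).
#'
#' @param fits a `cohort_fits` data frame from [fit_cohort()], or any data
#'   frame with `tissue` and `auc` columns.
#' @param min_n minimum cell lines per tissue (default 10).
#' @return `data.frame` with columns `tissue`, `n`, `median_auc`, `sd_auc`.
#' @export
summarize_by_tissue <- function(fits, min_n = 10) {
  if (!all(c("tissue", "auc") %in% names(fits)))
    .stop_invalid("fits must contain 'tissue' and 'auc' columns")
  keep <- !is.na(fits$tissue)
  tab <- split(fits$auc[keep], fits$tissue[keep])
  tab <- tab[vapply(tab, length, integer(1)) >= min_n]
  if (length(tab) == 0) {
    warning(sprintf("no tissue has at least %d cell lines", min_n))
    return(data.frame(tissue = character(0), n = integer(0),
                      median_auc = numeric(0), sd_auc = numeric(0)))
  }
  out <- data.frame(
    tissue = names(tab),
    n = vapply(tab, length, integer(1)),
    median_auc = vapply(tab, median, numeric(1)),
    sd_auc = vapply(tab, sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$median_auc), , drop = FALSE]
}
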