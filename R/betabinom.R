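#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution: a binomial count whose success
#' probability is itself Beta(alpha, beta) distributed. This is the noise
#' model used for clone counts in repeated blood draws, where biological
#' fluctuation between draws adds overdispersion on top of sampling noise.
#' Parameterised either directly by `alpha`/`beta` or by a mean `p` and
#' intra-class overdispersion `rho`, with
#' `alpha = p (1 - rho) / rho`, `beta = (1 - p) (1 - rho) / rho`;
#' `rho -> 0` recovers the binomial.
#'
#' @param k Integer count(s), `0 <= k <= n` (vectorised).
#' @param n Number of trials.
#' @param alpha,beta Positive shape parameters.
#' @param log Return log-probabilities.
#' @return Probabilities (summing to 1 over `k = 0:n` for fixed `n`).
#' @examples
#' betabinom_pmf(0:10, 10, 1, 1) # uniform: 1/11 each
#' @export
betabinom_pmf <- function(k, n, alpha, beta, log = FALSE) {
  if (length(n) != 1 || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer.",
      class = "clonotrack_value_error")
  }
  if (alpha <= 0 || beta <= 0 || !is.finite(alpha) || !is.finite(beta)) {
    abort("`alpha` and `beta` must be positive and finite.",
      class = "clonotrack_value_error")
  }
  if (any(k < 0 | k > n | k != round(k))) {
    abort("`k` must be integer(s) in [0, n].", class = "clonotrack_value_error")
  }
  lp <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

bb_shapes <- function(p, rho) {
  list(alpha = p * (1 - rho) / rho, beta = (1 - p) * (1 - rho) / rho)
}

# Two-sided minimum-likelihood tail probability of observing k under
# beta-binomial(n, alpha, beta): the summed mass of all outcomes no more
# likely than k. Evaluates the pmf only on the region where it is
# non-negligible (the distribution here concentrates far below n), treating
# the monotone far tail analytically.
bb_two_sided_p <- function(k, n, alpha, beta) {
  mu <- n * alpha / (alpha + beta)
  v <- n * alpha * beta * (alpha + beta + n) /
    ((alpha + beta)^2 * (alpha + beta + 1))
  kmax <- min(n, max(k, ceiling(mu + 25 * sqrt(max(v, 1)) + 25)))
  ks <- 0:kmax
  pmf <- betabinom_pmf(ks, n, alpha, beta)
  pk <- pmf[k + 1]
  tol <- pk * (1 + 1e-7)
  p <- sum(pmf[pmf <= tol])
  if (kmax < n) {
    # pmf is unimodal; beyond kmax (past the mode) it is decreasing, so if
    # the boundary mass is already below the threshold the whole residual
    # upper tail belongs in the sum
    residual <- max(0, 1 - sum(pmf))
    if (pmf[kmax + 1] <= tol) p <- p + residual
  }
  min(1, p)
}

#' Estimate repertoire overdispersion from negative-control pairs
#'
#' Fits the intra-class overdispersion `rho` of a beta-binomial noise model
#' by maximum likelihood on clone pairs from no-treatment sample pairs
#' (e.g. two blood draws one month apart from an untreated donor). For each
#' clone the baseline frequency `p = x1 / n1` is plugged in as the mean,
#' and the follow-up count is modelled as
#' beta-binomial(`n2`, `alpha = p(1-rho)/rho`, `beta = (1-p)(1-rho)/rho`).
#' Conditioning on the baseline draw rather than the pooled mean keeps the
#' fitted count out of its own null mean, which would otherwise absorb
#' half of the between-draw variability and bias `rho` low by about a
#' factor of two. The likelihood is maximised over `log(rho)` by
#' one-dimensional bounded optimisation; the procedure is deterministic.
#'
#' @param control_pairs A clone-pair tibble ([pair_samples()]) from a
#'   no-treatment pair; only clones detected at baseline are informative and
#'   at least 50 such clones are required.
#' @param interval Search interval for `rho`.
#' @return The estimated overdispersion, a value in `interval`.
#' @export
estimate_dispersion <- function(control_pairs, interval = c(1e-8, 0.499)) {
  check_pairs(control_pairs)
  pairs <- filter(control_pairs, .data$baseline_templates > 0)
  if (nrow(pairs) < 50) {
    abort(paste0(
      "Need at least 50 control clone pairs detected at baseline (got ",
      nrow(pairs), "); generate synthetic controls if no negative-control ",
      "samples are available."
    ), class = "clonotrack_value_error")
  }
  x2 <- pairs$followup_templates
  n2 <- pairs$followup_total[1]
  p <- pairs$baseline_templates / pairs$baseline_total
  negll <- function(log_rho) {
    rho <- exp(log_rho)
    sh <- bb_shapes(p, rho)
    -sum(lchoose(n2, x2) + lbeta(x2 + sh$alpha, n2 - x2 + sh$beta) -
      lbeta(sh$alpha, sh$beta))
  }
  opt <- optimize(negll, interval = log(interval), tol = 1e-8)
  exp(opt$minimum)
}

#' Beta-binomial differential abundance between paired samples
#'
#' Per-clone two-sided test of frequency change between a baseline and a
#' follow-up sample under a pooled-mean beta-binomial null: for each clone,
#' the null holds the mean frequency at `p = (x1 + x2)/(n1 + n2)` with
#' control-estimated overdispersion `rho`, and the p-value is the two-sided
#' minimum-likelihood tail probability of the observed follow-up count.
#' P-values are Benjamini-Hochberg adjusted across all tested clones; the
#' significant expansion set is `fdr_q < q_threshold & direction == "up"`.
#'
#' This is the differential-abundance comparator used to demonstrate, on
#' negative-control pairs with biological drift, why per-clone testing
#' over-calls expansions relative to the calibrated threshold criteria; it
#' is not the primary expansion caller.
#'
#' @param pairs A clone-pair tibble ([pair_samples()]).
#' @param rho Overdispersion in (0, 0.5), typically from
#'   [estimate_dispersion()].
#' @param q_threshold FDR level for the `significant` flag (default 0.01).
#' @return A tibble: `rearrangement`, `p_value`, `fdr_q`, `direction`
#'   (`up`/`down`), `significant` (logical, up-and-significant).
#' @export
betabinom_differential_abundance <- function(pairs, rho, q_threshold = 0.01) {
  check_pairs(pairs)
  if (!is.finite(rho) || rho <= 0 || rho >= 0.5) {
    abort("`rho` must lie in (0, 0.5).", class = "clonotrack_value_error")
  }
  if (nrow(pairs) == 0) {
    return(tibble(rearrangement = character(), p_value = numeric(),
      fdr_q = numeric(), direction = character(), significant = logical()))
  }
  n1 <- pairs$baseline_total[1]
  n2 <- pairs$followup_total[1]
  if (n1 <= 0 || n2 <= 0) {
    abort("Both samples must have positive totals.",
      class = "clonotrack_value_error")
  }
  p_pool <- (pairs$baseline_templates + pairs$followup_templates) / (n1 + n2)
  sh <- bb_shapes(p_pool, rho)
  p_value <- vapply(seq_len(nrow(pairs)), function(i) {
    bb_two_sided_p(pairs$followup_templates[i], n2, sh$alpha[i], sh$beta[i])
  }, numeric(1))
  tibble(
    rearrangement = pairs$rearrangement,
    p_value = p_value,
    fdr_q = p.adjust(p_value, method = "BH"),
    direction = dplyr::if_else(pairs$followup_freq >= pairs$baseline_freq,
      "up", "down"),
  ) |>
    mutate(significant = .data$fdr_q < q_threshold & .data$direction == "up")
}

#' Two-sided Fisher exact test per clone pair
#'
#' For each clone, the two-sided Fisher exact p-value on the 2x2 table
#' `[[x1, n1 - x1], [x2, n2 - x2]]` (baseline vs follow-up counts), using
#' the minimum-likelihood definition of the two-sided p (the convention of
#' `stats::fisher.test`). Vectorised over the rows of `pairs` via the
#' hypergeometric density, which makes repertoire-scale screens practical.
#' Serves as the uncorrected per-clone comparator in the negative-control
#' calibration study.
#'
#' @param pairs A clone-pair tibble ([pair_samples()]).
#' @return `pairs` with a `fisher_p` column added.
#' @export
fisher_exact_pair <- function(pairs) {
  check_pairs(pairs)
  if (nrow(pairs) == 0) return(mutate(pairs, fisher_p = numeric(0)))
  n1 <- pairs$baseline_total[1]
  n2 <- pairs$followup_total[1]
  if (n1 <= 0 || n2 <= 0) {
    abort("Both samples must have positive totals.",
      class = "clonotrack_value_error")
  }
  fisher_p <- vapply(seq_len(nrow(pairs)), function(i) {
    x1 <- pairs$baseline_templates[i]
    x2 <- pairs$followup_templates[i]
    m <- x1 + x2
    support <- max(0, m - n2):min(m, n1)
    d <- dhyper(support, n1, n2, m)
    obs <- d[support == x1]
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, numeric(1))
  mutate(pairs, fisher_p = fisher_p)
}
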