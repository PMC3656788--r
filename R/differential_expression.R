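## Consensus differential expression between two conditions from unique-hit
## counts: the MA-plot random-sampling z statistic, Fisher's exact test on
## the 2x2 count table, and the binomial likelihood-ratio test, combined by
## an all-three-methods consensus with ratio and floor filters.

## Two-sided Fisher p for the 2x2 table (k1, N1-k1; k2, N2-k2) by the
## minimum-likelihood convention: sum the probabilities of all tables with
## the observed margins whose probability does not exceed the observed
## table's (relative tolerance 1 + 1e-7, as in stats::fisher.test).
.fisher2x2_p <- function(k1, N1, k2, N2) {
  m <- k1 + k2
  lo <- max(0, m - N2)
  hi <- min(m, N1)
  x <- lo:hi
  d <- dhyper(x, N1, N2, m)
  sum(d[d <= d[x == k1] * (1 + 1e-7)])
}

.binom_loglik <- function(k, N, p) {
  t1 <- ifelse(k == 0, 0, k * log(p))
  t2 <- ifelse(k == N, 0, (N - k) * log1p(-p))
  t1 + t2
}

#' Differential-expression statistics for one gene's counts
#'
#' Given unique-hit counts `k1, k2` with library totals `N1, N2`, computes
#' `M = log2(k1/N1) - log2(k2/N2)`, `A` (the mean of the two logs), the
#' normal-approximation z score of M under binomial random sampling with
#' pooled proportion `(k1+k2)/(N1+N2)` (the MA-plot random-sampling model)
#' with its two-sided p, the two-sided Fisher exact p, and the
#' likelihood-ratio p comparing pooled vs separate binomial proportions
#' against chi-squared(1). All arguments are vectorised over genes.
#'
#' @param k1,k2 Gene counts (non-negative, `k <= N`).
#' @param N1,N2 Library totals (> 0).
#' @return `data.frame(M, A, z, p_mars, p_fisher, p_lrt, undefined)`;
#'   `undefined = TRUE` (with NA statistics) when `k1 = k2 = 0`.
#' @export
deg_tests <- function(k1, N1, k2, N2) {
  n <- max(length(k1), length(k2))
  k1 <- rep_len(k1, n); k2 <- rep_len(k2, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  if (any(N1 <= 0) || any(N2 <= 0)) .stopf("library totals must be > 0")
  if (any(k1 < 0) || any(k2 < 0) || any(k1 > N1) || any(k2 > N2))
    .stopf("counts must satisfy 0 <= k <= N")
  undef <- (k1 + k2) == 0
  l1 <- log2(k1 / N1)
  l2 <- log2(k2 / N2)
  M <- l1 - l2
  A <- (l1 + l2) / 2
  phat <- (k1 + k2) / (N1 + N2)
  varM <- (1 - phat) * (1 / (N1 * phat) + 1 / (N2 * phat)) / log(2)^2
  z <- M / sqrt(varM)
  p_mars <- 2 * pnorm(-abs(z))
  p_mars[is.nan(z)] <- NA_real_          # both counts zero
  p_fisher <- vapply(seq_len(n), function(i) {
    if (undef[i]) return(NA_real_)
    .fisher2x2_p(k1[i], N1[i], k2[i], N2[i])
  }, 0)
  p1 <- k1 / N1; p2 <- k2 / N2
  G <- 2 * (.binom_loglik(k1, N1, pmin(pmax(p1, 0), 1)) +
            .binom_loglik(k2, N2, pmin(pmax(p2, 0), 1)) -
            .binom_loglik(k1, N1, phat) - .binom_loglik(k2, N2, phat))
  p_lrt <- pchisq(G, df = 1, lower.tail = FALSE)
  M[undef] <- NA_real_; A[undef] <- NA_real_; z[undef] <- NA_real_
  p_mars[undef] <- NA_real_; p_lrt[undef] <- NA_real_
  data.frame(M = M, A = A, z = z, p_mars = p_mars, p_fisher = p_fisher,
             p_lrt = p_lrt, undefined = undef)
}

#' Consensus differential-expression call with the four filters
#'
#' Applies, in order: (1) `|log2(NTA_a/NTA_b)| >= ratio_log2`; (2) positive
#' ratios with numerator NTA below `floor` are ignored; (3) negative ratios
#' with denominator NTA below `floor` are not selected; (4) all three test
#' p-values must be `<= p_cutoff`. A gene is a consensus DEG only when all
#' filters pass; the first failing filter is recorded.
#'
#' @param nta_a,nta_b NTA values of the two conditions (vectorised).
#' @param tests Output of [deg_tests()] for the same genes.
#' @param ratio_log2 Absolute log2-ratio cutoff (default 2).
#' @param floor NTA floor for filters 2 and 3 (default 0.01).
#' @param p_cutoff P-value cutoff. Presets: `deg_preset("methods_default")`
#'   = 0.05, `deg_preset("results_strict")` = 0.001.
#' @param gene_id Optional gene identifiers carried into the result.
#' @return `data.frame(gene_id, log2_ratio, p_mars, p_fisher, p_lrt,
#'   consensus_deg, filter_reason)`.
#' @export
consensus_deg <- function(nta_a, nta_b, tests, ratio_log2 = 2, floor = 0.01,
                          p_cutoff = deg_preset("methods_default"),
                          gene_id = NULL) {
  n <- length(nta_a)
  stopifnot(length(nta_b) == n, nrow(tests) == n)
  log2_ratio <- log2(nta_a / nta_b)
  reason <- rep(NA_character_, n)
  ok <- rep(TRUE, n)
  f1 <- !is.na(log2_ratio) & abs(log2_ratio) >= ratio_log2
  reason[ok & !f1] <- "ratio_below_cutoff"; ok <- ok & f1
  f2 <- !(log2_ratio > 0 & nta_a < floor)
  reason[ok & !f2] <- "numerator_floor"; ok <- ok & f2
  f3 <- !(log2_ratio < 0 & nta_b < floor)
  reason[ok & !f3] <- "denominator_floor"; ok <- ok & f3
  pmax3 <- pmax(tests$p_mars, tests$p_fisher, tests$p_lrt)
  f4 <- !is.na(pmax3) & pmax3 <= p_cutoff
  reason[ok & !f4] <- "p_above_cutoff"; ok <- ok & f4
  ok[tests$undefined] <- FALSE
  reason[tests$undefined] <- NA_character_
  data.frame(gene_id = gene_id %||% sprintf("gene_%d", seq_len(n)),
             log2_ratio = log2_ratio, p_mars = tests$p_mars,
             p_fisher = tests$p_fisher, p_lrt = tests$p_lrt,
             consensus_deg = ok, filter_reason = reason,
             stringsAsFactors = FALSE)
}

#' Named p-value cutoff presets
#'
#' `"methods_default"` (0.05) is the filter-4 cutoff; `"results_strict"`
#' (0.001) is the stricter genome-wide DEG threshold.
#'
#' @param name Preset name.
#' @return Numeric cutoff.
#' @export
deg_preset <- function(name = c("methods_default", "results_strict")) {
  switch(match.arg(name), methods_default = 0.05, results_strict = 0.001)
}

#' Reconstruct counts from an expression table
#'
#' When only NTA tables are available, testing counts are reconstructed as
#' `k = round(TA * length)` and `N = round(ASD * genome length)` (a
#' documented approximation).
#'
#' @param expr An `ExpressionTable`.
#' @param condition Condition name.
#' @return `list(k = per-gene counts, N = library total)`.
#' @export
reconstruct_counts <- function(expr, condition) {
  ta <- expr$ta[, condition]
  k <- round(ta * expr$gene_length[expr$genes])
  N <- round(expr$asd[[condition]] * expr$genome_length)
  k <- pmin(k, N)
  list(k = unname(k), N = N)
}

#' Full DEG table for one condition pair
#'
#' Runs [deg_tests()] on reconstructed counts and [consensus_deg()] on the
#' NTA values for conditions `a` vs `b`.
#'
#' @param expr An `ExpressionTable`.
#' @param a,b Condition names (numerator, denominator).
#' @param ... Passed to [consensus_deg()].
#' @return The [consensus_deg()] data frame with `M` and `A` columns added.
#' @export
deg_table <- function(expr, a, b, ...) {
  ca <- reconstruct_counts(expr, a)
  cb <- reconstruct_counts(expr, b)
  tests <- deg_tests(ca$k, ca$N, cb$k, cb$N)
  res <- consensus_deg(expr$nta[, a], expr$nta[, b], tests,
                       gene_id = expr$genes, ...)
  res$M <- tests$M
  res$A <- tests$A
  res$condition_pair <- paste(a, b, sep = "_vs_")
  res
}
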