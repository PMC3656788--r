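## Correlation-based co-expression and regulator-target linkage: squared
## Pearson correlations between expression profiles (cellulosomal
## co-expression, regulator anti-correlation), the carbon-catabolite-
## repression signature (expression vs growth-rate Spearman), and
## two-component-system locus scanning with category assignment.

#' Profile correlation between two gene groups
#'
#' With `aggregate = "mean"` the per-condition mean NTA profile of each
#' group is correlated (squared Pearson R^2 on raw NTA by default, as
#' regulator-target scatter plots are drawn in NTA units); with
#' `aggregate = "none"` all pairwise gene-gene correlations are returned.
#'
#' @param expr An `ExpressionTable`.
#' @param group_a,group_b Gene-id character vectors (non-empty).
#' @param aggregate `"mean"` or `"none"`.
#' @param log_space Correlate log-transformed NTA (floor 0.01) instead.
#' @return For `"mean"`: `list(r2, slope_sign, n_conditions, undefined)`.
#'   For `"none"`: `data.frame(unit_a, unit_b, r2, slope_sign)`.
#' @export
profile_r2 <- function(expr, group_a, group_b,
                       aggregate = c("mean", "none"), log_space = FALSE) {
  aggregate <- match.arg(aggregate)
  if (!length(group_a) || !length(group_b)) .stopf("groups must be non-empty")
  if (length(expr$conditions) < 3L) .stopf("need >= 3 shared conditions")
  m <- expr$nta
  if (log_space) m <- log(pmax(m, 0.01))
  if (aggregate == "mean") {
    a <- colMeans(m[group_a, , drop = FALSE])
    b <- colMeans(m[group_b, , drop = FALSE])
    if (sd(a) == 0 || sd(b) == 0)
      return(list(r2 = NA_real_, slope_sign = NA_character_,
                  n_conditions = length(a), undefined = TRUE))
    r <- cor(a, b)
    return(list(r2 = r^2, slope_sign = if (r >= 0) "+" else "-",
                n_conditions = length(a), undefined = FALSE))
  }
  pairs <- expand.grid(unit_a = group_a, unit_b = group_b,
                       stringsAsFactors = FALSE)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- m[pairs$unit_a[i], ]; y <- m[pairs$unit_b[i], ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, 0)
  data.frame(pairs, r2 = r^2,
             slope_sign = ifelse(is.na(r), NA, ifelse(r >= 0, "+", "-")),
             stringsAsFactors = FALSE)
}

#' Expression vs growth-rate anti-correlation (CCR signature)
#'
#' Spearman rank correlation between an expression profile and per-condition
#' growth rates; the carbon-catabolite-repression signature is a strongly
#' negative rho. Exact permutation p for n <= 8 (one-sided `"less"` by
#' default, testing anti-correlation), asymptotic otherwise. Conditions
#' with tied growth rates can be excluded via `rankable_conditions`.
#'
#' @param expr_profile Named numeric vector (condition -> expression).
#' @param growth Named numeric vector (condition -> growth rate, 1/h).
#' @param rankable_conditions Optional subset of conditions to use.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @return `list(rho, p, n, undefined)`.
#' @export
growth_anticorrelation <- function(expr_profile, growth,
                                   rankable_conditions = NULL,
                                   alternative = "less") {
  conds <- rankable_conditions %||% intersect(names(expr_profile),
                                              names(growth))
  if (length(conds) < 3L) .stopf("need >= 3 rankable conditions")
  x <- expr_profile[conds]
  g <- growth[conds]
  if (length(unique(g)) == 1L || sd(x) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(conds),
                undefined = TRUE))
  rho <- cor(x, g, method = "spearman")
  p <- if (length(conds) <= 8L) .spearman_perm_p(x, g, alternative)
  else suppressWarnings(stats::cor.test(x, g, method = "spearman",
                                        alternative = alternative)$p.value)
  list(rho = rho, p = p, n = length(conds), undefined = FALSE)
}

## operon of gene i: maximal run of same-strand genes around i with
## intergenic gaps <= max_gap (wrapping the origin on circular records)
.operon_members <- function(g, i, max_gap, circular, L) {
  n <- nrow(g)
  nxt <- function(j) if (j == n) 1L else j + 1L
  prv <- function(j) if (j == 1L) n else j - 1L
  gap_fwd <- function(j) {                       # gap between gene j and j+1
    k <- nxt(j)
    d <- g$start[k] - g$end[j]
    if (d < 0 && circular) d <- d + L
    d
  }
  members <- i
  j <- i
  while (length(members) < n) {
    k <- nxt(j)
    if (!circular && k < j) break
    if (k %in% members) break
    if (g$strand[k] != g$strand[i] || gap_fwd(j) > max_gap) break
    members <- c(members, k); j <- k
  }
  j <- i
  while (length(members) < n) {
    k <- prv(j)
    if (!circular && k > j) break
    if (k %in% members) break
    if (g$strand[k] != g$strand[i] || gap_fwd(k) > max_gap) break
    members <- c(k, members); j <- k
  }
  members
}

#' Scan a genome for two-component-system loci
#'
#' Finds adjacent same-strand sensor-kinase + response-regulator gene pairs,
#' expands each to its operon (adjacency, same strand, intergenic gap at
#' most `max_operon_gap` bases), collects CAZyme and ABC-transporter genes
#' within `max_flank` genes on either side, and assigns the locus category:
#' `I` when a solute-binding protein (SBP) gene lies inside the TCS operon,
#' `II` when a CAZyme does, `III` otherwise.
#'
#' @param record A [genome_record()] whose gene table has a `role` column
#'   (`CAZyme`, `ABC`, `TCS_sensor`, `TCS_regulator`, `SBP`, `other`).
#' @param max_flank Flank size in genes (default 5).
#' @param max_operon_gap Operon gap threshold in bases (default 100).
#' @return `data.frame(locus_id, category, sensor, regulator, operon_genes,
#'   flank_cazymes, flank_abc, start, end)`.
#' @export
tcs_locus_scan <- function(record, max_flank = 5L, max_operon_gap = 100L) {
  g <- record$genes
  empty <- data.frame(locus_id = character(), category = character(),
                      sensor = character(), regulator = character(),
                      operon_genes = character(), flank_cazymes = character(),
                      flank_abc = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nrow(g) || !"role" %in% names(g)) return(empty)
  n <- nrow(g)
  role <- g$role
  loci <- list()
  seen <- logical(n)
  for (i in seq_len(n)) {
    j <- if (i == n) { if (record$circular) 1L else next } else i + 1L
    pair <- sort(c(role[i], role[j]))
    if (!identical(pair, c("TCS_regulator", "TCS_sensor"))) next
    if (g$strand[i] != g$strand[j]) next
    if (seen[i] || seen[j]) next
    members <- .operon_members(g, i, max_operon_gap, record$circular,
                               record$length)
    if (!j %in% members) next
    seen[members] <- TRUE
    op_roles <- role[members]
    category <- if ("SBP" %in% op_roles) "I"
    else if ("CAZyme" %in% op_roles) "II" else "III"
    lo <- min(members); hi <- max(members)
    flank_idx <- unique(c(
      vapply(seq_len(max_flank), function(d)
        if (record$circular) ((lo - 1L - d - 1L) %% n) + 1L
        else lo - d, 0L),
      vapply(seq_len(max_flank), function(d)
        if (record$circular) ((hi - 1L + d) %% n) + 1L
        else hi + d, 0L)))
    flank_idx <- setdiff(flank_idx[flank_idx >= 1L & flank_idx <= n], members)
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = sprintf("tcs_%s", g$gene_id[min(members)]),
      category = category,
      sensor = paste(g$gene_id[members[op_roles == "TCS_sensor"]],
                     collapse = ","),
      regulator = paste(g$gene_id[members[op_roles == "TCS_regulator"]],
                        collapse = ","),
      operon_genes = paste(g$gene_id[members], collapse = ","),
      flank_cazymes = paste(g$gene_id[flank_idx[role[flank_idx] == "CAZyme"]],
                            collapse = ","),
      flank_abc = paste(g$gene_id[flank_idx[role[flank_idx] == "ABC"]],
                        collapse = ","),
      start = min(g$start[members]), end = max(g$end[members]),
      stringsAsFactors = FALSE)
  }
  if (!length(loci)) return(empty)
  out <- do.call(rbind, loci)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
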