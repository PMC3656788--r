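## Degradome membership, Row Z-scores, hierarchical expression classes,
## CAZyme groups I-IV (core vs accessory), and flat-term enrichment.

#' Degradome and substrate-specific degradome membership
#'
#' The degradome is the set of genes transcribed (NTA strictly > `nta_min`)
#' under the target substrate. The substrate-specific degradome
#' additionally requires, against every reference substrate, an NTA ratio
#' strictly greater than `ratio_min` and a differential-expression p-value
#' below `p_max` (all three consensus tests must pass, i.e. the maximum of
#' the three p-values is used).
#'
#' @param expr An `ExpressionTable`.
#' @param target Target condition (e.g. cellulose).
#' @param refs Reference conditions (e.g. glucose and cellobiose).
#' @param nta_min Expression floor (strict >; default 1).
#' @param ratio_min NTA ratio threshold against each reference (strict >;
#'   default 2).
#' @param p_max Differential-expression p threshold (strict <; default
#'   0.001).
#' @return `list(degradome, specific)` of gene-id character vectors.
#' @export
degradome_membership <- function(expr, target, refs, nta_min = 1,
                                 ratio_min = 2, p_max = 0.001) {
  if (target %in% refs) .stopf("target condition cannot be its own reference")
  if (!all(c(target, refs) %in% expr$conditions))
    .stopf("target and refs must be conditions of the expression table")
  in_deg <- expr$nta[, target] > nta_min
  ok <- in_deg
  ct <- reconstruct_counts(expr, target)
  for (r in refs) {
    ratio_ok <- expr$nta[, target] / expr$nta[, r] > ratio_min
    cr <- reconstruct_counts(expr, r)
    tests <- deg_tests(ct$k, ct$N, cr$k, cr$N)
    pmax3 <- pmax(tests$p_mars, tests$p_fisher, tests$p_lrt)
    ok <- ok & !is.na(ratio_ok) & ratio_ok & !is.na(pmax3) & pmax3 < p_max
  }
  list(degradome = expr$genes[which(in_deg)],
       specific = expr$genes[which(ok)])
}

#' Row Z-scores of an expression table
#'
#' Per-gene standardisation across conditions: `(NTA - row mean) / row
#' sample standard deviation`. Rows with zero variance become all-zero and
#' are flagged in the `"zero_variance"` attribute.
#'
#' @param expr An `ExpressionTable` or a numeric genes-by-conditions matrix.
#' @param genes,conditions Optional subsets.
#' @return Z-score matrix with attribute `zero_variance` (named logical).
#' @export
row_zscore <- function(expr, genes = NULL, conditions = NULL) {
  m <- if (inherits(expr, "ExpressionTable")) expr$nta else as.matrix(expr)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(conditions)) m <- m[, conditions, drop = FALSE]
  if (ncol(m) < 2L) .stopf("need at least 2 conditions for Row Z-scores")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / s
  zero <- s == 0
  z[zero, ] <- 0
  attr(z, "zero_variance") <- setNames(zero, rownames(m))
  z
}

## label one cluster's mean Z profile with the CAZyme group rules
.cazyme_group_label <- function(zbar, ccr_high, ccr_low, substrate_conditions,
                                cs_condition, margin) {
  conds <- names(zbar)
  hi <- intersect(ccr_high, conds)
  lo <- intersect(ccr_low, conds)
  if (length(hi) && length(lo) &&
      min(zbar[hi]) - max(zbar[lo]) >= margin / 2 &&
      mean(zbar[hi]) - mean(zbar[lo]) >= margin) return("I")
  if (cs_condition %in% conds &&
      zbar[cs_condition] - max(zbar[setdiff(conds, cs_condition)]) >= margin)
    return("III")
  subs <- intersect(substrate_conditions, conds)
  if (length(subs)) {
    top <- subs[which.max(zbar[subs])]
    if (zbar[top] - max(zbar[setdiff(conds, top)]) >= margin) return("II")
  }
  "IV"
}

#' Hierarchical clustering of Row Z-scores with class labelling
#'
#' Agglomerative clustering (average linkage on `1 - Pearson correlation`
#' distance by default) of gene Z-score profiles, with the tree cut into
#' `n_clusters`. Each cluster is labelled either by the condition
#' maximising its mean profile (`by_max_condition`, giving classes C1, C2,
#' ... in the priority order of `class_order`) or by the CAZyme group rule
#' set (`cazyme_groups`): Group I profiles are high under the
#' slow-growth/recalcitrant conditions relative to the preferred sugars
#' (carbon catabolite repression signature), Group II is high under exactly
#' one substrate, Group III is dominant under the composite substrate, and
#' Group IV is the remainder.
#'
#' @param z Row Z-score matrix from [row_zscore()].
#' @param n_clusters Number of clusters to cut the tree into.
#' @param labeling `"by_max_condition"` or `"cazyme_groups"`.
#' @param expr Optional `ExpressionTable` (used for max-condition labelling
#'   in NTA units; Z means are used when absent).
#' @param linkage,distance `stats::hclust` method and `"correlation"` or
#'   `"euclidean"`.
#' @param margin Z-contrast margin for the group rules (default 0.5).
#' @param ccr_high,ccr_low Condition sets defining the Group-I contrast.
#' @param substrate_conditions Candidate single-substrate conditions for
#'   Group II.
#' @param cs_condition Composite substrate for Group III.
#' @param class_order Condition priority mapping max-conditions to C-class
#'   numbers.
#' @return `data.frame(gene_id, cluster, class_label, subclass,
#'   max_condition)`.
#' @export
cluster_and_label_groups <- function(z, n_clusters,
                                     labeling = c("by_max_condition",
                                                  "cazyme_groups"),
                                     expr = NULL,
                                     linkage = "average",
                                     distance = c("correlation", "euclidean"),
                                     margin = 0.5,
                                     ccr_high = c("Glu", "Cel", "Xyn", "CS"),
                                     ccr_low = c("Ceb", "Xyl"),
                                     substrate_conditions = c("Cel", "Ceb",
                                                              "Xyl", "Xyn"),
                                     cs_condition = "CS",
                                     class_order = c("Cel", "Ceb", "Glu")) {
  labeling <- match.arg(labeling)
  distance <- match.arg(distance)
  if (anyNA(z)) .stopf("Z-score matrix contains missing values")
  if (n_clusters > nrow(z))
    .stopf("n_clusters (%d) exceeds number of genes (%d)", n_clusters, nrow(z))
  d <- if (distance == "correlation") {
    cm <- suppressWarnings(cor(t(z)))
    cm[!is.finite(cm)] <- 0            # zero-variance rows: maximal distance
    as.dist(1 - cm)
  } else stats::dist(z)
  cl <- cutree(hclust(d, method = linkage), k = n_clusters)
  conds <- colnames(z)
  mean_profile <- function(members) {
    if (!is.null(expr)) colMeans(expr$nta[members, conds, drop = FALSE])
    else colMeans(z[members, , drop = FALSE])
  }
  cl_label <- character(n_clusters)
  cl_maxcond <- character(n_clusters)
  order_rank <- match(conds, c(class_order, setdiff(conds, class_order)))
  for (k in seq_len(n_clusters)) {
    members <- rownames(z)[cl == k]
    prof <- mean_profile(members)
    ## ties in the max condition broken by configured condition order
    mx <- conds[order(-prof, match(conds, conds))][1L]
    cl_maxcond[k] <- mx
    if (labeling == "by_max_condition") {
      cl_label[k] <- paste0("C", order_rank[match(mx, conds)])
    } else {
      zbar <- colMeans(z[members, , drop = FALSE])
      cl_label[k] <- .cazyme_group_label(zbar, ccr_high, ccr_low,
                                         substrate_conditions, cs_condition,
                                         margin)
    }
  }
  subclass <- rep(NA_character_, nrow(z))
  for (i in seq_len(nrow(z))) {
    mx <- cl_maxcond[cl[i]]
    sec <- setdiff(conds, mx)
    pos <- sec[z[i, sec] > 0]
    if (length(pos)) {
      best <- pos[which.max(z[i, pos])]
      subclass[i] <- sprintf("%s-%s-high", cl_label[cl[i]], best)
    }
  }
  data.frame(gene_id = rownames(z), cluster = unname(cl),
             class_label = cl_label[cl], subclass = subclass,
             max_condition = cl_maxcond[cl], stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment on a flat term table
#'
#' Upper-tail hypergeometric test of term over-representation in a gene
#' set, with Benjamini-Hochberg adjustment and the representation ratio
#' `(set_count/set_size) / (term_count/universe_size)` (1 = on par with
#' genome content).
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param term_table `data.frame(gene_id, term_id)` flat annotation.
#' @param universe Gene universe; defaults to all genes with at least one
#'   term.
#' @param min_count Terms with fewer than this many universe members are
#'   skipped (default 5; use 20 to drop under-powered broad classes).
#' @return `data.frame(term_id, set_count, set_size, term_count,
#'   universe_size, representation_ratio, p, q)` sorted by p.
#' @export
enrichment_test <- function(gene_set, term_table, universe = NULL,
                            min_count = 5L) {
  universe <- unique(universe %||% term_table$gene_id)
  if (!length(universe)) .stopf("empty universe")
  if (!all(gene_set %in% universe))
    .stopf("gene_set must be a subset of the universe")
  gene_set <- unique(gene_set)
  tt <- term_table[term_table$gene_id %in% universe, , drop = FALSE]
  empty <- data.frame(term_id = character(), set_count = integer(),
                      set_size = integer(), term_count = integer(),
                      universe_size = integer(),
                      representation_ratio = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (!length(gene_set) || !nrow(tt)) return(empty)
  N <- length(universe)
  n <- length(gene_set)
  terms <- split(unique(tt)$gene_id, unique(tt)$term_id)
  terms <- terms[lengths(terms) >= min_count]
  if (!length(terms)) return(empty)
  K <- lengths(terms)
  k <- vapply(terms, function(gs) sum(gs %in% gene_set), 0L)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(terms), set_count = k, set_size = n,
                    term_count = K, universe_size = N,
                    representation_ratio = (k / n) / (K / N),
                    p = p, q = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
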