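## Transcript abundance (TA), average sequencing depth (ASD) and normalized
## transcript abundance (NTA = TA / ASD): the study's expression unit.
## TA_j is the mean per-base unique-hit depth over gene j; ASD is total
## mapped bases divided by genome length, so a gene covering the whole
## genome has NTA exactly 1 and NTA is invariant to scaling all depths.

#' Construct a coverage track
#'
#' @param condition Condition name.
#' @param depth Integer vector of per-base unique-hit depth over the genome.
#' @param genome_id Genome identifier the track belongs to.
#' @param seed Optional provenance seed recorded in the object.
#' @return Object of class `CoverageTrack`.
#' @export
coverage_track <- function(condition, depth, genome_id, seed = NA_integer_) {
  if (!length(depth)) .stopf("empty depth vector")
  if (any(depth < 0)) .stopf("depth must be non-negative")
  structure(list(condition = condition, depth = as.numeric(depth),
                 genome_id = genome_id, seed = seed),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s' on %s: %d bases, ASD = %.3f\n",
              x$condition, x$genome_id, length(x$depth), compute_asd(x)))
  invisible(x)
}

#' Average sequencing depth of a track
#'
#' `ASD = sum(per-base depth) / genome length`.
#'
#' @param track A [coverage_track()].
#' @return Numeric ASD (mean depth, x).
#' @export
compute_asd <- function(track) {
  n <- length(track$depth)
  if (n == 0L) .stopf("zero-length genome")
  sum(track$depth) / n
}

#' Compute the genes-by-conditions NTA expression table
#'
#' For each gene j, `TA_j` is the sum of per-base depths over the gene
#' divided by gene length; `NTA_j = TA_j / ASD` of that condition's track.
#' Gene bases are counted strand-blind; bases shared by overlapping genes
#' count fully toward each gene.
#'
#' @param tracks Named list of [coverage_track()]s, one per condition.
#' @param record A [genome_record()].
#' @return Object of class `ExpressionTable`: fields `genes`, `conditions`,
#'   `nta` and `ta` (matrices), `asd` (named vector), `gene_length`,
#'   `genome_length`.
#' @export
compute_nta_table <- function(tracks, record) {
  if (!length(tracks)) .stopf("no coverage tracks supplied")
  conds <- unname(vapply(tracks, function(t) t$condition, character(1L)))
  names(tracks) <- conds
  g <- record$genes
  if (any(g$end > record$length))
    .stopf("validation error: gene outside genome")
  ta <- matrix(0, nrow(g), length(conds),
               dimnames = list(g$gene_id, conds))
  asd <- setNames(numeric(length(conds)), conds)
  for (c in conds) {
    tr <- tracks[[c]]
    if (length(tr$depth) != record$length)
      .stopf("track '%s' length %d does not match genome length %d",
             c, length(tr$depth), record$length)
    asd[c] <- compute_asd(tr)
    cs <- c(0, cumsum(tr$depth))
    ta[, c] <- (cs[g$end + 1L] - cs[g$start + 1L]) / (g$end - g$start)
  }
  nta <- sweep(ta, 2L, asd, "/")
  nta[, asd == 0] <- 0
  structure(list(genes = g$gene_id, conditions = conds, nta = nta, ta = ta,
                 asd = asd, gene_length = setNames(g$end - g$start, g$gene_id),
                 genome_length = record$length),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d conditions (%s)\n",
              length(x$genes), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Expressed-gene call
#'
#' A gene is expressed under a condition when its NTA is strictly greater
#' than the threshold (default 1).
#'
#' @param expr An [compute_nta_table()] result.
#' @param condition Condition name.
#' @param threshold NTA threshold (strict inequality; default 1).
#' @return Named logical vector over genes.
#' @export
is_expressed <- function(expr, condition, threshold = 1) {
  if (!condition %in% expr$conditions)
    .stopf("unknown condition '%s'", condition)
  expr$nta[, condition] > threshold
}

#' Correlate two quantifications
#'
#' `pearson_r2_on_log` returns the squared Pearson correlation of
#' log-transformed values (zeros replaced by `log_floor`); `spearman`
#' returns the rank correlation with an exact-permutation p-value for
#' n <= 8 and the asymptotic p otherwise.
#'
#' @param x,y Equal-length numeric vectors (length >= 3; non-negative for
#'   the log mode).
#' @param method `"pearson_r2_on_log"` or `"spearman"`.
#' @param log_floor Replacement for zeros before log transform (default
#'   0.01).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (spearman
#'   permutation p only).
#' @return `list(coefficient, p, undefined)`; `undefined = TRUE` (with NA
#'   coefficient) for constant input rather than an error.
#' @export
correlate_quantifications <- function(x, y,
                                      method = c("pearson_r2_on_log",
                                                 "spearman"),
                                      log_floor = 0.01,
                                      alternative = "two.sided") {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    .stopf("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(coefficient = NA_real_, p = NA_real_, undefined = TRUE))
  if (method == "pearson_r2_on_log") {
    if (any(x < 0) || any(y < 0)) .stopf("negative values in log mode")
    lx <- log(ifelse(x == 0, log_floor, x))
    ly <- log(ifelse(y == 0, log_floor, y))
    ct <- stats::cor.test(lx, ly, method = "pearson")
    return(list(coefficient = unname(ct$estimate)^2, p = ct$p.value,
                undefined = FALSE))
  }
  rho <- cor(x, y, method = "spearman")
  p <- if (length(x) <= 8L) .spearman_perm_p(x, y, alternative)
  else suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                        alternative = alternative)$p.value)
  list(coefficient = rho, p = p, undefined = FALSE)
}

## all permutations of 1..n (n <= 8), deterministic order
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[r + seq_len(nrow(sub)), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

.spearman_perm_p <- function(x, y, alternative = "two.sided") {
  n <- length(x)
  obs <- cor(x, y, method = "spearman")
  perms <- .permutations(n)
  rhos <- apply(perms, 1L, function(ix) cor(x, y[ix], method = "spearman"))
  eps <- 1e-12
  switch(alternative,
         less = mean(rhos <= obs + eps),
         greater = mean(rhos >= obs - eps),
         two.sided = mean(abs(rhos) >= abs(obs) - eps),
         .stopf("unknown alternative '%s'", alternative))
}

## ---- coverage and expression TSV I/O ----

#' Write / read a coverage track TSV
#'
#' Two-column TSV `pos, depth` with 1-based positions; bases with zero
#' depth may be omitted on read. A `#` header records condition, genome and
#' seed for provenance.
#'
#' @param track A [coverage_track()].
#' @param path File path.
#' @return Invisibly `path` (write) or a `CoverageTrack` (read).
#' @export
write_coverage_tsv <- function(track, path) {
  hdr <- sprintf("#condition:%s\tgenome:%s\tlength:%d\tseed:%s",
                 track$condition, track$genome_id, length(track$depth),
                 track$seed)
  keep <- which(track$depth > 0)
  writeLines(hdr, path)
  if (length(keep)) {
    data.table::fwrite(data.table::data.table(pos = keep,
                                              depth = track$depth[keep]),
                       path, sep = "\t", append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @param genome_length,condition,genome_id Overrides when the header is
#'   absent.
#' @export
read_coverage_tsv <- function(path, genome_length = NULL, condition = NULL,
                              genome_id = NULL) {
  hdr <- readLines(path, n = 1L)
  if (startsWith(hdr, "#")) {
    f <- strsplit(sub("^#", "", hdr), "\t")[[1L]]
    kv <- do.call(rbind, strsplit(f, ":", fixed = TRUE))
    vals <- setNames(kv[, 2L], kv[, 1L])
    condition <- condition %||% unname(vals["condition"])
    genome_id <- genome_id %||% unname(vals["genome"])
    genome_length <- genome_length %||% as.integer(vals["length"])
  }
  if (is.null(genome_length)) .stopf("genome_length unknown for '%s'", path)
  dt <- data.table::fread(path, sep = "\t", skip = if (startsWith(hdr, "#")) 1L else 0L,
                          header = FALSE, col.names = c("pos", "depth"))
  depth <- numeric(genome_length)
  if (nrow(dt)) depth[dt$pos] <- dt$depth
  coverage_track(condition %||% "unknown", depth, genome_id %||% "unknown")
}

#' Write / read an expression table TSV
#'
#' Genes-by-conditions NTA matrix with `#asd:` and `#genome_length:` header
#' lines and a `length` column, so counts can be reconstructed.
#'
#' @param expr An `ExpressionTable`.
#' @param path File path.
#' @return Invisibly `path` (write) or an `ExpressionTable` (read).
#' @export
write_expression_tsv <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#asd:%s", paste(sprintf("%s=%.10g", expr$conditions,
                                                expr$asd), collapse = ",")),
               sprintf("#genome_length:%d", expr$genome_length)), con)
  df <- data.frame(gene_id = expr$genes,
                   length = unname(expr$gene_length[expr$genes]),
                   expr$nta, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  asd_line <- sub("^#asd:", "", hdr[1L])
  pairs <- strsplit(strsplit(asd_line, ",")[[1L]], "=")
  asd <- setNames(vapply(pairs, function(p) as.numeric(p[2L]), 0),
                  vapply(pairs, `[`, "", 1L))
  gl <- as.integer(sub("^#genome_length:", "", hdr[2L]))
  df <- as.data.frame(data.table::fread(path, sep = "\t", skip = 2L))
  conds <- setdiff(names(df), c("gene_id", "length"))
  nta <- as.matrix(df[, conds, drop = FALSE])
  rownames(nta) <- df$gene_id
  ta <- sweep(nta, 2L, asd[conds], "*")
  structure(list(genes = df$gene_id, conditions = conds, nta = nta, ta = ta,
                 asd = asd[conds],
                 gene_length = setNames(df$length, df$gene_id),
                 genome_length = gl),
            class = "ExpressionTable")
}
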