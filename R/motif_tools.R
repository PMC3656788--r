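## Palindromic operator-motif tools: position-specific scoring matrices with
## the two central columns constrained to C,G (the conserved central
## dinucleotide of catabolite-responsive elements bound by LacI/CcpA-family
## dimers), an exact null score distribution by dynamic programming over
## discretised log-odds scores, region scanning at a p-value threshold, and
## site-to-gene assignment with translation-start offsets.

## 1-based indices of the two central columns (even width w: w/2, w/2+1;
## odd width: floor(w/2), floor(w/2)+1)
.pssm_center <- function(width) {
  c(floor(width / 2), floor(width / 2) + 1L)
}

#' Build a palindromic PSSM with fixed central CG
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 pseudocount)`;
#' the two central columns are overridden to the fixed-CG constraint (C and
#' G receive `1 - 3 eps` with `eps = pseudocount / (n + 4 pseudocount)`),
#' enforcing the constraint as part of the model rather than as post-hoc
#' filtering. Log-odds are `log2(prob / background)`.
#'
#' @param sites Character vector of aligned equal-length sites over
#'   `{A,C,G,T}` (at least 2).
#' @param pseudocount Per-cell pseudocount (default 0.25).
#' @param background Named base frequencies (default uniform).
#' @param fixed_center Apply the central-CG override (default TRUE).
#' @return Object of class `Pssm` with fields `width`, `probs` (4 x width),
#'   `log_odds`, `background`, `center` (1-based column indices),
#'   `pseudocount`, `n_sites`, `consensus`.
#' @export
build_palindromic_pssm <- function(sites, pseudocount = 0.25,
                                   background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                   fixed_center = TRUE) {
  if (length(sites) < 2L) .stopf("need at least 2 aligned sites")
  w <- unique(nchar(sites))
  if (length(w) != 1L) .stopf("sites must all have the same length")
  if (w < 4L) .stopf("width must be >= 4")
  bad <- grep("[^ACGT]", toupper(sites))
  if (length(bad))
    .stopf("site(s) %s contain characters outside {A,C,G,T}",
           paste(bad, collapse = ", "))
  background <- background[DNA_BASES4] / sum(background[DNA_BASES4])
  n <- length(sites)
  mat <- matrix(0L, 4L, w, dimnames = list(DNA_BASES4, NULL))
  chars <- do.call(rbind, strsplit(toupper(sites), ""))
  for (j in seq_len(w)) {
    tb <- table(factor(chars[, j], levels = DNA_BASES4))
    mat[, j] <- as.integer(tb)
  }
  probs <- (mat + pseudocount) / (n + 4 * pseudocount)
  center <- .pssm_center(w)
  if (fixed_center) {
    eps <- pseudocount / (n + 4 * pseudocount)
    probs[, center[1L]] <- c(eps, 1 - 3 * eps, eps, eps)   # C column
    probs[, center[2L]] <- c(eps, eps, 1 - 3 * eps, eps)   # G column
  }
  log_odds <- log2(sweep(probs, 1L, background, "/"))
  consensus <- paste(DNA_BASES4[apply(probs, 2L, which.max)], collapse = "")
  structure(list(width = as.integer(w), probs = probs, log_odds = log_odds,
                 background = background, center = center,
                 pseudocount = pseudocount, n_sites = n,
                 consensus = consensus),
            class = "Pssm")
}

#' @export
print.Pssm <- function(x, ...) {
  cat(sprintf("Pssm: width %d, %d sites, consensus %s (central C,G at %d,%d)\n",
              x$width, x$n_sites, x$consensus, x$center[1L], x$center[2L]))
  invisible(x)
}

.pssm_int_matrix <- function(pssm, granularity) {
  m <- round(pssm$log_odds / granularity)
  storage.mode(m) <- "integer"
  m
}

#' Exact null score distribution of a PSSM
#'
#' Distribution of the log-odds score of an i.i.d. background sequence of
#' length `width`, computed by position-wise convolution (dynamic
#' programming) over scores discretised at `granularity` bits. Returns the
#' survival function `P(score >= s)` used as the scan p-value.
#'
#' @param pssm A [build_palindromic_pssm()] result.
#' @param background Base frequencies of the null (defaults to the PSSM's).
#' @param granularity Score bin width in bits (default 0.01).
#' @return Object of class `PssmNull` with `granularity`, integer score
#'   range `smin:smax`, `prob` (point masses) and `sf` (survival function).
#' @export
score_pvalue_table <- function(pssm, background = NULL, granularity = 0.01) {
  .check_number(granularity, "granularity", min = 0, strict = TRUE)
  bg <- background %||% pssm$background
  bg <- bg[DNA_BASES4] / sum(bg[DNA_BASES4])
  imat <- .pssm_int_matrix(pssm, granularity)
  v <- 1
  smin <- 0L; smax <- 0L
  for (j in seq_len(pssm$width)) {
    cmin <- min(imat[, j]); cmax <- max(imat[, j])
    nv <- numeric(smax + cmax - (smin + cmin) + 1L)
    for (b in 1:4) {
      off <- imat[b, j] - cmin
      idx <- seq_along(v) + off
      nv[idx] <- nv[idx] + v * bg[b]
    }
    v <- nv
    smin <- smin + cmin; smax <- smax + cmax
  }
  sf <- rev(cumsum(rev(v)))
  sf <- pmin(sf, 1)
  structure(list(granularity = granularity, smin = smin, smax = smax,
                 prob = v, sf = sf, background = bg,
                 width = pssm$width),
            class = "PssmNull")
}

#' P-value of a discretised score under a null table
#'
#' @param null_table A [score_pvalue_table()] result.
#' @param score_int Integer score(s) in `granularity` units.
#' @return `P(score >= score_int)` under the background model.
#' @export
pssm_score_pvalue <- function(null_table, score_int) {
  p <- numeric(length(score_int))
  p[score_int < null_table$smin] <- 1
  p[score_int > null_table$smax] <- 0
  inb <- score_int >= null_table$smin & score_int <= null_table$smax
  p[inb] <- null_table$sf[score_int[inb] - null_table$smin + 1L]
  p
}

## scores of every window of width w, NA where the window contains N
.window_scores <- function(code, imat) {
  w <- ncol(imat)
  m <- length(code) - w + 1L
  if (m < 1L) return(integer())
  sc <- integer(m)
  bad <- logical(m)
  code1 <- code
  code1[is.na(code1)] <- 1L
  for (j in seq_len(w)) {
    cj <- code[j:(j + m - 1L)]
    bad <- bad | is.na(cj)
    sc <- sc + imat[cbind(code1[j:(j + m - 1L)], j)]
  }
  sc[bad] <- NA_integer_
  sc
}

#' Scan sequences with a PSSM at a p-value threshold
#'
#' Every window whose exact null p-value is at most `p_max` is reported,
#' on both strands when requested; windows containing N are skipped.
#' A window where forward and reverse-complement hits coincide on a
#' self-reverse-complementary sequence (perfect palindrome) is reported
#' once with strand `"."`. All overlapping hits are reported.
#'
#' @param seqs Named character vector of sequences.
#' @param pssm A [build_palindromic_pssm()] result.
#' @param p_max P-value threshold (default 1e-4).
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @param null_table Optional precomputed [score_pvalue_table()].
#' @param background Background for the null when `null_table` is absent.
#' @return `data.frame(seq_id, offset, strand, score_bits, p, match)`;
#'   `offset` is the 0-based window start within the sequence, `match` is
#'   the motif-strand sequence.
#' @export
scan_sequences <- function(seqs, pssm, p_max = 1e-4, both_strands = TRUE,
                           null_table = NULL, background = NULL) {
  nt <- null_table %||% score_pvalue_table(pssm, background = background)
  imat <- .pssm_int_matrix(pssm, nt$granularity)
  w <- pssm$width
  ## reverse-complement scoring matrix: scanning the reverse strand of a
  ## window equals scoring with complemented rows in reversed column order
  imat_rc <- imat[4:1, w:1, drop = FALSE]
  rownames(imat_rc) <- DNA_BASES4
  pass <- which(nt$sf <= p_max)
  thr <- if (length(pass)) nt$smin + pass[1L] - 1L else NA_integer_
  out <- list()
  for (sid in names(seqs)) {
    s <- toupper(seqs[[sid]])
    if (nchar(s) < w) {
      message(sprintf("region '%s' shorter than motif width; skipped", sid))
      next
    }
    if (is.na(thr)) next
    code <- .encode_dna(s)
    fwd <- .window_scores(code, imat)
    rev_ <- if (both_strands) .window_scores(code, imat_rc) else
      rep(NA_integer_, length(fwd))
    hit_f <- !is.na(fwd) & fwd >= thr
    hit_r <- both_strands & !is.na(rev_) & rev_ >= thr
    for (i in which(hit_f | hit_r)) {
      win <- substr(s, i, i + w - 1L)
      pal <- hit_f[i] && hit_r[i] && identical(win, .revcomp(win))
      if (pal) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, offset = i - 1L, strand = ".",
          score_bits = fwd[i] * nt$granularity,
          p = pssm_score_pvalue(nt, fwd[i]), match = win,
          stringsAsFactors = FALSE)
        next
      }
      if (hit_f[i])
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, offset = i - 1L, strand = "+",
          score_bits = fwd[i] * nt$granularity,
          p = pssm_score_pvalue(nt, fwd[i]), match = win,
          stringsAsFactors = FALSE)
      if (hit_r[i])
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, offset = i - 1L, strand = "-",
          score_bits = rev_[i] * nt$granularity,
          p = pssm_score_pvalue(nt, rev_[i]), match = .revcomp(win),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score_bits = numeric(),
                      p = numeric(), match = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan genomic regions with a PSSM
#'
#' Wraps [scan_sequences()] over a region table (e.g. the upstream-sequence
#' database from [extract_regions()]), scanning the plus-strand genomic
#' sequence of each region on both strands. Background defaults to the
#' genome-wide mononucleotide frequencies of the record. Sites are reported
#' in genome coordinates.
#'
#' @param record A [genome_record()].
#' @param regions Region table from [extract_regions()].
#' @param pssm A [build_palindromic_pssm()] result.
#' @param p_max,both_strands,null_table See [scan_sequences()].
#' @return `data.frame(position, strand, score_bits, p, match, region_id,
#'   anchor_gene)`; `position` is the 0-based genomic window start.
#' @export
scan_regions <- function(record, regions, pssm, p_max = 1e-4,
                         both_strands = TRUE, null_table = NULL) {
  if (is.null(null_table)) {
    bg <- genome_background(record)
    null_table <- score_pvalue_table(pssm, background = bg)
  }
  if (!nrow(regions))
    return(data.frame(position = integer(), strand = character(),
                      score_bits = numeric(), p = numeric(),
                      match = character(), region_id = character(),
                      anchor_gene = character(), stringsAsFactors = FALSE))
  key <- sprintf("row%08d", seq_len(nrow(regions)))
  seqs <- setNames(vapply(seq_len(nrow(regions)), function(k)
    substr(record$sequence, regions$start[k] + 1L, regions$end[k]), ""), key)
  seqs <- seqs[nchar(seqs) >= pssm$width]
  hits <- suppressMessages(
    scan_sequences(seqs, pssm, p_max = p_max, both_strands = both_strands,
                   null_table = null_table))
  if (!nrow(hits))
    return(data.frame(position = integer(), strand = character(),
                      score_bits = numeric(), p = numeric(),
                      match = character(), region_id = character(),
                      anchor_gene = character(), stringsAsFactors = FALSE))
  ridx <- match(hits$seq_id, key)
  out <- data.frame(position = regions$start[ridx] + hits$offset,
                    strand = hits$strand, score_bits = hits$score_bits,
                    p = hits$p, match = hits$match,
                    region_id = regions$region_id[ridx],
                    anchor_gene = regions$anchor_gene[ridx],
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Genome-wide mononucleotide background frequencies
#'
#' @param record A [genome_record()].
#' @return Named frequency vector over A, C, G, T (Ns excluded).
#' @export
genome_background <- function(record) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(record$sequence),
                                        DNA_BASES4)
  counts / sum(counts)
}

#' Assign motif sites to genes with translation-start offsets
#'
#' Each site is assigned to the nearest downstream gene on the matching
#' strand (strand `"."` matches both) within `window` bases. The offset to
#' the first base of the translation start is negative upstream and 0 for a
#' site starting exactly at the start. Pairs of sites assigned to the same
#' gene are reported with their start-to-start separation.
#'
#' @param sites Site table from [scan_regions()] (columns `position`,
#'   `strand`, `match`).
#' @param record A [genome_record()].
#' @param window Maximum upstream distance in bases (default 500).
#' @return `list(sites, pairs)`: `sites` gains `assigned_gene` and
#'   `offset_to_start`; `pairs` has `gene_id, position_a, position_b,
#'   separation`.
#' @export
map_sites_to_genes <- function(sites, record, window = 500L) {
  g <- record$genes
  L <- record$length
  n <- nrow(sites)
  assigned <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    w <- nchar(sites$match[i])
    send <- sites$position[i] + w
    best_d <- Inf; best_g <- NA_character_
    for (k in seq_len(nrow(g))) {
      if (!(sites$strand[i] %in% c(".", g$strand[k]))) next
      d <- if (g$strand[k] == "+") g$start[k] - sites$position[i]
      else send - g$end[k]
      if (record$circular) d <- ((d %% L) + L) %% L
      if (is.na(d) || d < 0 || d > window) next
      if (d < best_d) { best_d <- d; best_g <- g$gene_id[k] }
    }
    if (!is.na(best_g)) { assigned[i] <- best_g; offset[i] <- -best_d }
  }
  sites$assigned_gene <- assigned
  sites$offset_to_start <- offset
  pairs <- list()
  for (gene in unique(assigned[!is.na(assigned)])) {
    idx <- which(!is.na(assigned) & assigned == gene)
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    for (c in seq_len(ncol(cmb))) {
      a <- cmb[1L, c]; b <- cmb[2L, c]
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = gene, position_a = sites$position[a],
        position_b = sites$position[b],
        separation = abs(sites$position[a] - sites$position[b]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(gene_id = character(), position_a = integer(),
                  position_b = integer(), separation = integer(),
                  stringsAsFactors = FALSE)
  list(sites = sites, pairs = pairs)
}

#' Serialise a PSSM in MEME minimal text format
#'
#' @param pssm A [build_palindromic_pssm()] result.
#' @param path Output path.
#' @param name Motif name.
#' @return Invisibly, `path`.
#' @export
write_meme_pssm <- function(pssm, path, name = "motif1") {
  bg <- pssm$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"],
                     bg["G"], bg["T"]), "",
             sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     pssm$width, pssm$n_sites),
             vapply(seq_len(pssm$width), function(j)
               sprintf(" %.6f %.6f %.6f %.6f", pssm$probs["A", j],
                       pssm$probs["C", j], pssm$probs["G", j],
                       pssm$probs["T", j]), ""))
  writeLines(lines, path)
  invisible(path)
}
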