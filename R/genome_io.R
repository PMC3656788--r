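## Genome records, GenBank/FASTA+GFF3 I/O and upstream/intergenic region
## extraction. Internal coordinates are 0-based half-open; file output is
## 1-based inclusive (GenBank/GFF3 convention). BED output is 0-based
## half-open per the BED standard.

ANNOTATION_COLS <- c("cazy_family", "cellulosomal", "cluster", "role")

#' Construct a genome record
#'
#' A `GenomeRecord` bundles a (possibly circular) chromosome sequence with an
#' ordered table of gene models and is the coordinate authority for every
#' region and motif operation in the pipeline.
#'
#' @param id Character scalar, sequence identifier.
#' @param sequence Character scalar or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `feature_type` (`CDS`, `tRNA`,
#'   `rRNA`, `other`), and optionally the annotation columns `cazy_family`,
#'   `cellulosomal`, `cluster`, `role`.
#' @param circular Logical; is the chromosome circular?
#' @param source_format Character, provenance tag (`"genbank"`,
#'   `"fasta+gff3"`, `"synthetic"` ...).
#' @return An object of class `GenomeRecord` with fields `id`, `length`,
#'   `circular`, `sequence` (character), `genes` (data.frame sorted by
#'   `start`) and `source_format`.
#' @export
genome_record <- function(id, sequence, genes = NULL, circular = FALSE,
                          source_format = "unknown") {
  .check_flag(circular, "circular")
  seq_char <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", seq_char))
    .stopf("sequence contains characters outside {A,C,G,T,N}")
  len <- nchar(seq_char)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        feature_type = character(), stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "start", "end", "strand", "feature_type")
  miss <- setdiff(req, names(genes))
  if (length(miss)) .stopf("genes table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      .stopf("duplicated locus tags in gene table")
    if (any(genes$start >= genes$end))
      .stopf("gene intervals must satisfy start < end")
    if (any(genes$start < 0L) || any(genes$end > len))
      .stopf("gene interval outside [0, genome length)")
    if (!all(genes$strand %in% c("+", "-")))
      .stopf("gene strand must be '+' or '-'")
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(id = as.character(id), length = len, circular = circular,
                 sequence = seq_char, genes = genes,
                 source_format = source_format),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d bp (%s, %s)\n", x$id, x$length,
              if (x$circular) "circular" else "linear", x$source_format))
  if (nrow(x$genes)) {
    tab <- table(x$genes$feature_type)
    cat("  features:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  } else cat("  features: none\n")
  invisible(x)
}

## ---- GenBank flat-file parsing (no offline parser available elsewhere) ----

.parse_gb_location <- function(loc, line_no) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc) || grepl("^order\\(", loc)) {
    ## bacterial records: treat multi-part locations as their spanning interval
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  nums <- as.numeric(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2L || anyNA(nums))
    .stopf("GenBank parse error at line %d: unparseable location '%s'",
           line_no, loc)
  ## GenBank 1-based inclusive -> 0-based half-open
  list(start = as.integer(min(nums) - 1L), end = as.integer(max(nums)),
       strand = strand)
}

.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L]))
    .stopf("GenBank parse error at line 1: missing LOCUS line")
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  id <- locus[2L]
  circular <- any(tolower(locus) == "circular")
  feat_from <- which(grepl("^FEATURES", lines))[1L]
  orig_from <- which(grepl("^ORIGIN", lines))[1L]
  if (is.na(orig_from)) .stopf("GenBank parse error: no ORIGIN section")
  seq_lines <- lines[(orig_from + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq_char <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  genes <- list()
  if (!is.na(feat_from)) {
    fl <- (feat_from + 1L):(orig_from - 1L)
    cur <- NULL
    for (i in fl) {
      ln <- lines[i]
      if (grepl("^ {5}[A-Za-z]", ln)) {            # new feature
        if (!is.null(cur)) genes[[length(genes) + 1L]] <- cur
        key <- trimws(substr(ln, 1L, 21L))
        loc <- trimws(substr(ln, 22L, nchar(ln)))
        cur <- list(key = key, loc = loc, quals = character(), line = i)
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else if (!grepl("^/", txt) && !length(cur$quals))
          cur$loc <- paste0(cur$loc, txt)          # wrapped location
      }
    }
    if (!is.null(cur)) genes[[length(genes) + 1L]] <- cur
  }
  keep <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  rows <- list()
  for (f in genes) {
    if (!f$key %in% names(keep)) next
    pl <- .parse_gb_location(f$loc, f$line)
    tag <- sub('.*?/locus_tag="([^"]+)".*', "\\1",
               paste(f$quals, collapse = " "))
    if (identical(tag, paste(f$quals, collapse = " ")) || tag == "")
      tag <- sprintf("%s_%d_%d", f$key, pl$start, pl$end)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = tag, start = pl$start, end = pl$end, strand = pl$strand,
      feature_type = keep[[f$key]], stringsAsFactors = FALSE)
  }
  gt <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(gt) && any(gt$end > nchar(seq_char)))
    .stopf("validation error: feature beyond declared sequence length")
  genome_record(id, seq_char, gt, circular = circular,
                source_format = "genbank")
}

## ---- FASTA + GFF3 ----

.read_fasta_gff3 <- function(fasta, gff, circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) .stopf("empty FASTA file '%s'", fasta)
  id <- sub("\\s.*$", "", names(seqs)[1L])
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == id]
  types <- as.character(gr$type)
  keep <- types %in% c("CDS", "tRNA", "rRNA")
  gr <- gr[keep]
  types <- types[keep]
  ids <- if ("locus_tag" %in% names(S4Vectors::mcols(gr)) &&
             !all(is.na(gr$locus_tag))) as.character(gr$locus_tag)
         else as.character(gr$ID)
  gt <- NULL
  if (length(gr)) {
    gt <- data.frame(
      gene_id = ids,
      start = GenomicRanges::start(gr) - 1L,   # GFF3 1-based -> 0-based
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      feature_type = types, stringsAsFactors = FALSE)
    for (col in ANNOTATION_COLS)
      if (col %in% names(S4Vectors::mcols(gr)))
        gt[[col]] <- as.character(S4Vectors::mcols(gr)[[col]])
  }
  if (!is.null(gt) && any(gt$end > nchar(as.character(seqs[[1L]]))))
    .stopf("validation error: GFF3 feature beyond sequence end")
  genome_record(id, as.character(seqs[[1L]]), gt, circular = circular,
                source_format = "fasta+gff3")
}

#' Read a genome record from GenBank or FASTA+GFF3
#'
#' All CDS/tRNA/rRNA features become gene models with 0-based half-open
#' coordinates; strand and `locus_tag` qualifiers are preserved. Annotation
#' tags (CAZy family, cellulosomal flag, cluster, role) can be supplied as a
#' side TSV with header `gene_id, cazy_family, cellulosomal, cluster, role`.
#'
#' @param path GenBank flat file, or FASTA file when `format = "fasta+gff3"`.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff GFF3 path (required for `"fasta+gff3"`).
#' @param annotation Optional annotation TSV path.
#' @param circular Logical override for circularity when the format does not
#'   state it (GFF3 has no circular flag).
#' @return A [genome_record()].
#' @export
read_genome_record <- function(path, format = c("genbank", "fasta+gff3"),
                               gff = NULL, annotation = NULL,
                               circular = FALSE) {
  format <- match.arg(format)
  rec <- if (format == "genbank") .read_genbank(path)
         else {
           if (is.null(gff)) .stopf("'gff' is required for format fasta+gff3")
           .read_fasta_gff3(path, gff, circular = circular)
         }
  if (format == "genbank" && circular) rec$circular <- TRUE
  if (!is.null(annotation)) rec <- apply_annotation_table(rec, annotation)
  rec
}

#' Attach a gene-annotation side table to a record
#'
#' @param record A [genome_record()].
#' @param path TSV with header `gene_id, cazy_family, cellulosomal, cluster,
#'   role`; `cellulosomal` is interpreted as logical.
#' @return The record with annotation columns merged into `genes`.
#' @export
apply_annotation_table <- function(record, path) {
  ann <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"gene_id" %in% names(ann)) .stopf("annotation TSV lacks 'gene_id'")
  idx <- match(record$genes$gene_id, ann$gene_id)
  for (col in intersect(ANNOTATION_COLS, names(ann))) {
    v <- ann[[col]][idx]
    if (col == "cellulosomal") v <- as.logical(v)
    record$genes[[col]] <- v
  }
  record
}

#' Write a genome record as FASTA + GFF3
#'
#' @param record A [genome_record()].
#' @param fasta,gff Output paths. GFF3 is written 1-based inclusive.
#' @return Invisibly, the two paths.
#' @export
write_genome_record <- function(record, fasta, gff) {
  ss <- Biostrings::DNAStringSet(record$sequence)
  names(ss) <- record$id
  Biostrings::writeXStringSet(ss, fasta)
  g <- record$genes
  gr <- GenomicRanges::GRanges(
    seqnames = record$id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- g$feature_type
  gr$ID <- g$gene_id
  gr$locus_tag <- g$gene_id
  gr$phase <- ifelse(g$feature_type == "CDS", 0L, NA_integer_)
  for (col in intersect(ANNOTATION_COLS, names(g))) {
    val <- g[[col]]
    val[is.na(val)] <- ""
    S4Vectors::mcols(gr)[[col]] <- as.character(val)
  }
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

## ---- region extraction ----

.empty_regions <- function() {
  data.frame(region_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             anchor_gene = character(), stringsAsFactors = FALSE)
}

## split a possibly origin-wrapping interval [start, end) (end may exceed L,
## start may be negative) into in-bounds sub-intervals
.wrap_interval <- function(start, end, L, circular) {
  if (start >= end) return(NULL)
  if (!circular) {
    s <- max(0, start); e <- min(L, end)
    if (s >= e) return(NULL)
    return(data.frame(start = s, end = e))
  }
  s <- ((start %% L) + L) %% L
  len <- min(end - start, L)
  e <- s + len
  if (e <= L) data.frame(start = s, end = e)
  else data.frame(start = c(s, 0), end = c(L, e - L))
}

#' Extract upstream or intergenic regions
#'
#' Upstream mode returns, for each gene, the region 5' of its translation
#' start on its own strand, up to `max_len` bases, optionally truncated at the
#' nearest annotated feature on either strand. Intergenic mode returns the
#' maximal intervals covered by no gene. On circular records regions wrap the
#' origin and are represented as two sub-interval rows sharing a `region_id`.
#'
#' @param record A [genome_record()].
#' @param mode `"upstream"` or `"intergenic"`.
#' @param max_len Maximum upstream length in bases (default 500).
#' @param truncate_at_neighbor Truncate upstream regions at the nearest
#'   annotated feature (default `TRUE`).
#' @return `data.frame` with columns `region_id, start, end, strand, kind,
#'   anchor_gene` (0-based half-open).
#' @export
extract_regions <- function(record, mode = c("upstream", "intergenic"),
                            max_len = 500L, truncate_at_neighbor = TRUE) {
  mode <- match.arg(mode)
  .check_number(max_len, "max_len", min = 0, strict = TRUE)
  g <- record$genes
  L <- record$length
  if (mode == "upstream") {
    if (!nrow(g)) .stopf("upstream mode requires at least one gene")
    out <- list()
    for (i in seq_len(nrow(g))) {
      plus <- g$strand[i] == "+"
      anchor <- if (plus) g$start[i] else g$end[i]
      len <- max_len
      if (truncate_at_neighbor && nrow(g) > 1L) {
        others <- g[-i, , drop = FALSE]
        d <- if (plus) (anchor - others$end) else (others$start - anchor)
        if (record$circular) d <- ((d %% L) + L) %% L
        else d[d < 0] <- Inf
        len <- min(len, min(d))
      }
      len <- min(len, L - (g$end[i] - g$start[i]))
      iv <- if (plus) .wrap_interval(anchor - len, anchor, L, record$circular)
            else .wrap_interval(anchor, anchor + len, L, record$circular)
      if (is.null(iv)) next
      out[[length(out) + 1L]] <- data.frame(
        region_id = sprintf("up_%s", g$gene_id[i]),
        start = iv$start, end = iv$end, strand = g$strand[i],
        kind = "upstream", anchor_gene = g$gene_id[i],
        stringsAsFactors = FALSE)
    }
    if (!length(out)) return(.empty_regions())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }
  ## intergenic: complement of the union of gene intervals
  if (!nrow(g)) {
    return(data.frame(region_id = "ig_1", start = 0L, end = L, strand = ".",
                      kind = "intergenic", anchor_gene = NA_character_,
                      stringsAsFactors = FALSE))
  }
  cov <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
  gaps <- IRanges::gaps(cov, start = 1L, end = L)
  if (!length(gaps)) return(.empty_regions())
  df <- data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
  df$region_id <- sprintf("ig_%d", seq_len(nrow(df)))
  ## circular: a gap touching base 0 and a gap touching base L-1 are one region
  if (record$circular && nrow(df) >= 2L &&
      df$start[1L] == 0L && df$end[nrow(df)] == L) {
    df$region_id[1L] <- df$region_id[nrow(df)]
  }
  data.frame(region_id = df$region_id, start = df$start, end = df$end,
             strand = ".", kind = "intergenic", anchor_gene = NA_character_,
             stringsAsFactors = FALSE)
}

#' Fetch region sequences from a record
#'
#' Wrapped circular regions (rows sharing a `region_id`) are concatenated in
#' genomic order across the origin; minus-strand regions are
#' reverse-complemented so the returned sequence reads 5' to 3' on the
#' region's own strand.
#'
#' @param record A [genome_record()].
#' @param regions Region table from [extract_regions()].
#' @return Named character vector of sequences, one per `region_id`.
#' @export
region_sequences <- function(record, regions) {
  if (!nrow(regions)) return(setNames(character(), character()))
  ids <- unique(regions$region_id)
  out <- vapply(ids, function(rid) {
    part <- regions[regions$region_id == rid, , drop = FALSE]
    ## genomic order across the origin: the part ending at L comes first
    if (nrow(part) > 1L) part <- part[order(part$start, decreasing = TRUE), ]
    s <- paste(vapply(seq_len(nrow(part)), function(k)
      substr(record$sequence, part$start[k] + 1L, part$end[k]), ""),
      collapse = "")
    if (part$strand[1L] == "-") s <- .revcomp(s)
    s
  }, character(1L))
  setNames(out, ids)
}

#' Write regions as BED6
#'
#' @param regions Region table (0-based half-open, as produced by
#'   [extract_regions()]).
#' @param path Output BED path.
#' @param genome_id Chromosome name to write.
#' @param score Numeric score column (recycled; default 0).
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, genome_id, score = 0) {
  strand <- ifelse(regions$strand %in% c("+", "-"), regions$strand, "*")
  if (nrow(regions)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome_id,
      ranges = IRanges::IRanges(start = regions$start + 1L,
                                end = regions$end),
      strand = strand)
    gr$name <- regions$region_id
    gr$score <- rep_len(score, nrow(regions))
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
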