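## Transcribed-region calling from per-base coverage and classification into
## the core transcriptional glycobiome (expressed under every substrate) vs
## condition-specific regions (expressed under exactly one substrate, not
## overlapping any other condition's transcription, mean depth strictly > 2),
## with genomic context (CDS overlap / intergenic / putative 5'-UTR).

#' Call transcribed regions from a coverage track
#'
#' Maximal runs of bases with depth >= `min_base_depth`, allowing internal
#' gaps of at most `max_gap` bases, discarding runs shorter than
#' `min_length`.
#'
#' @param track A [coverage_track()].
#' @param min_base_depth Minimum per-base depth to call a base expressed
#'   (default 1).
#' @param min_length Minimum region length in bases (default 30, about one
#'   read length).
#' @param max_gap Maximum internal gap of sub-threshold bases (default 0).
#' @return `data.frame(start, end)`, 0-based half-open, sorted.
#' @export
call_transcribed_regions <- function(track, min_base_depth = 1,
                                     min_length = 30L, max_gap = 0L) {
  .check_number(min_base_depth, "min_base_depth", min = 0)
  .check_number(min_length, "min_length", min = 1)
  .check_number(max_gap, "max_gap", min = 0)
  on <- track$depth >= min_base_depth
  r <- rle(on)
  if (max_gap > 0 && length(r$lengths) > 2L) {
    inner <- seq_along(r$values)[-c(1L, length(r$values))]
    close_ <- inner[!r$values[inner] & r$lengths[inner] <= max_gap]
    if (length(close_)) {
      r$values[close_] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep])
}

.mean_depth <- function(depth_cumsum, start, end) {
  (depth_cumsum[end + 1L] - depth_cumsum[start + 1L]) / (end - start)
}

#' Classify transcribed regions into core and condition-specific sets
#'
#' Core regions are the interval intersection of the per-condition region
#' sets (expressed under every condition). Condition-specific regions are
#' regions called under exactly one condition that (i) do not overlap any
#' region transcribed under another condition and (ii) have mean depth
#' strictly greater than `min_specific_depth` in that condition. Each
#' output region gets a genomic context: `cds_overlap` when it overlaps a
#' CDS, `putative_5utr` when intergenic but within the upstream window of a
#' downstream gene on that gene's strand, `intergenic` otherwise.
#'
#' @param region_sets Named list (per condition) of `data.frame(start, end)`
#'   interval tables from [call_transcribed_regions()].
#' @param record The [genome_record()] the regions live on.
#' @param tracks Named list of [coverage_track()]s (for mean depths).
#' @param min_specific_depth Strict lower bound on mean depth for
#'   condition-specific regions (default 2).
#' @param upstream_window 5'-UTR context window in bases (default 500).
#' @return `data.frame` with `region_id, start, end, category, conditions,
#'   context` and one `mean_depth_<condition>` column per condition.
#' @export
classify_regions <- function(region_sets, record, tracks,
                             min_specific_depth = 2, upstream_window = 500L) {
  conds <- names(region_sets)
  if (is.null(conds) || !length(conds)) .stopf("region_sets must be named")
  if (!all(conds %in% names(tracks)))
    .stopf("tracks missing for some conditions")
  for (c in conds)
    if (length(tracks[[c]]$depth) != record$length)
      .stopf("validation error: track '%s' not on this genome", c)
  ir <- lapply(region_sets, function(df)
    IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end)))
  cumd <- lapply(tracks[conds], function(t) c(0, cumsum(t$depth)))

  rows <- list()
  ## core: interval intersection across all conditions
  core <- Reduce(IRanges::intersect, ir)
  if (length(core)) {
    for (k in seq_along(core)) {
      s <- IRanges::start(core)[k] - 1L
      e <- IRanges::end(core)[k]
      md <- vapply(conds, function(c) .mean_depth(cumd[[c]], s, e), 0)
      rows[[length(rows) + 1L]] <-
        c(list(start = s, end = e, category = "core",
               conditions = paste(conds, collapse = ",")),
          as.list(setNames(md, paste0("mean_depth_", conds))))
    }
  }
  ## condition-specific
  for (cond in conds) {
    others <- setdiff(conds, cond)
    other_union <- if (length(others))
      IRanges::reduce(do.call(base::c, unname(ir[others])))
    else IRanges::IRanges()
    cand <- ir[[cond]]
    if (!length(cand)) next
    ov <- IRanges::countOverlaps(cand, other_union) > 0L
    cand <- cand[!ov]
    for (k in seq_along(cand)) {
      s <- IRanges::start(cand)[k] - 1L
      e <- IRanges::end(cand)[k]
      md_c <- .mean_depth(cumd[[cond]], s, e)
      if (!(md_c > min_specific_depth)) next       # strict >
      md <- vapply(conds, function(cc) .mean_depth(cumd[[cc]], s, e), 0)
      rows[[length(rows) + 1L]] <-
        c(list(start = s, end = e, category = "condition_specific",
               conditions = cond),
          as.list(setNames(md, paste0("mean_depth_", conds))))
    }
  }
  if (!length(rows)) {
    out <- data.frame(region_id = character(), start = integer(),
                      end = integer(), category = character(),
                      conditions = character(), context = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$region_id <- sprintf("tr_%04d", seq_len(nrow(out)))
  out$context <- .region_context(out, record, upstream_window)
  rownames(out) <- NULL
  cols <- c("region_id", "start", "end", "category", "conditions", "context")
  out[, c(cols, setdiff(names(out), cols))]
}

## cds_overlap > putative_5utr > intergenic
.region_context <- function(regions, record, upstream_window) {
  g <- record$genes
  ctx <- rep("intergenic", nrow(regions))
  if (!nrow(g)) return(ctx)
  reg_ir <- IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  cds <- g[g$feature_type == "CDS", , drop = FALSE]
  gene_ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
  if (nrow(cds)) {
    cds_ir <- IRanges::IRanges(start = cds$start + 1L, end = cds$end)
    ctx[IRanges::countOverlaps(reg_ir, cds_ir) > 0L] <- "cds_overlap"
  } else {
    ctx[IRanges::countOverlaps(reg_ir, gene_ir) > 0L] <- "cds_overlap"
  }
  up <- extract_regions(record, "upstream", max_len = upstream_window,
                        truncate_at_neighbor = TRUE)
  if (nrow(up)) {
    up_ir <- IRanges::IRanges(start = up$start + 1L, end = up$end)
    hit <- IRanges::countOverlaps(reg_ir, up_ir) > 0L
    ctx[ctx == "intergenic" & hit] <- "putative_5utr"
  }
  ctx
}

#' Fraction of the genome covered by called regions
#'
#' @param regions `data.frame(start, end)` interval table.
#' @param genome_length Genome size in bases.
#' @return Fraction in `[0, 1]` of bases covered by the region union.
#' @export
transcribed_fraction <- function(regions, genome_length) {
  if (!nrow(regions)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = regions$start + 1L,
                                         end = regions$end))
  sum(IRanges::width(ir)) / genome_length
}
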