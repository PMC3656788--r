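# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing binary is stored.

# tiny linear record with hand-placed genes
toy_record <- function(genes, length = 1000L, circular = FALSE, seed = 42L) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  genome_record("toy", seq, genes, circular = circular,
                source_format = "synthetic")
}

toy_genes <- function(starts, ends, strands = "+", types = "CDS") {
  n <- length(starts)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), start = starts,
             end = ends, strand = rep_len(strands, n),
             feature_type = rep_len(types, n), stringsAsFactors = FALSE)
}

# small full simulation reused by several tests (computed once per worker)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7L)
      sim <- simulate_genome(cfg)
      tracks <- lapply(cfg$conditions, function(cond)
        simulate_coverage(sim$record, sim$truth, cfg, cond))
      names(tracks) <- cfg$conditions
      cache <<- list(cfg = cfg, record = sim$record, truth = sim$truth,
                     tracks = tracks,
                     expr = compute_nta_table(tracks, sim$record))
    }
    cache
  }
})

# hand-written GenBank flat file: 3 genes, one on the minus strand with
# printed 1-based coordinates 101..200
write_toy_genbank <- function(path) {
  seq <- paste(rep("acgt", 125), collapse = "")   # 500 bp
  blocks <- substring(seq, seq(1, 491, 10), seq(10, 500, 10))
  origin <- vapply(seq(1, 50, 6), function(i)
    sprintf("%9d %s", (i - 1) * 10 + 1,
            paste(blocks[i:min(i + 5, 50)], collapse = " ")), "")
  writeLines(c(
    "LOCUS       TOYREC                 500 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "     CDS             11..70",
    '                     /locus_tag="toy_0001"',
    "     CDS             complement(101..200)",
    '                     /locus_tag="toy_0002"',
    "     tRNA            301..380",
    '                     /locus_tag="toy_0003"',
    "ORIGIN",
    origin,
    "//"), path)
  path
}

# an ExpressionTable built directly (for threshold/membership unit tests)
make_expr <- function(nta, asd = 10, gene_length = 1000L,
                      genome_length = 1e6L) {
  genes <- rownames(nta)
  conds <- colnames(nta)
  structure(list(genes = genes, conditions = conds, nta = nta,
                 ta = sweep(nta, 2L, rep_len(asd, ncol(nta)), "*"),
                 asd = setNames(rep_len(asd, ncol(nta)), conds),
                 gene_length = setNames(rep_len(gene_length, length(genes)),
                                        genes),
                 genome_length = genome_length),
            class = "ExpressionTable")
}
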