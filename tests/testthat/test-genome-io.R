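test_that("GenBank features convert to 0-based half-open gene models", {
  gb <- write_toy_genbank(withr::local_tempfile(fileext = ".gb"))
  rec <- read_genome_record(gb, format = "genbank")
  expect_equal(rec$length, 500L)
  expect_true(rec$circular)
  expect_equal(nrow(rec$genes), 3L)
  expect_equal(sort(unique(rec$genes$feature_type)), c("CDS", "tRNA"))
  g2 <- rec$genes[rec$genes$gene_id == "toy_0002", ]
  expect_equal(g2$start, 100L)          # printed 101..200, minus strand
  expect_equal(g2$end, 200L)
  expect_equal(g2$strand, "-")
  g1 <- rec$genes[rec$genes$gene_id == "toy_0001", ]
  expect_equal(c(g1$start, g1$end), c(10L, 70L))
})

test_that("malformed GenBank input raises a parse error", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not a genbank file", "at all"), p)
  expect_error(read_genome_record(p, format = "genbank"), "LOCUS")
})

test_that("a record without features has an empty gene list", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X   20 bp DNA linear", "ORIGIN",
               "        1 acgtacgtac gtacgtacgt", "//"), p)
  rec <- read_genome_record(p, format = "genbank")
  expect_equal(nrow(rec$genes), 0L)
  expect_equal(rec$length, 20L)
})

test_that("FASTA+GFF3 round trip preserves intervals, strands, annotations", {
  cfg <- sim_config(seed = 11L, layout = "plain", n_genes = 15L,
                    genome_length = 20000L)
  rec <- simulate_genome(cfg)$record
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  suppressWarnings(write_genome_record(rec, fa, gff))
  back <- read_genome_record(fa, format = "fasta+gff3", gff = gff,
                             circular = TRUE)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$genes$start, rec$genes$start)
  expect_equal(back$genes$end, rec$genes$end)
  expect_equal(back$genes$strand, rec$genes$strand)
  expect_equal(back$genes$gene_id, rec$genes$gene_id)
  expect_equal(back$genes$role, rec$genes$role)
})

test_that("upstream regions follow the strand and truncate at neighbors", {
  rec <- toy_record(toy_genes(500L, 800L), length = 1000L)
  up <- extract_regions(rec, "upstream", max_len = 300L)
  expect_equal(up$start, 200L)
  expect_equal(up$end, 500L)

  # truncation at the previous feature
  rec2 <- toy_record(toy_genes(c(100L, 500L), c(150L, 800L)), length = 1000L)
  up2 <- extract_regions(rec2, "upstream", max_len = 500L)
  g2 <- up2[up2$anchor_gene == "g02", ]
  expect_equal(c(g2$start, g2$end), c(150L, 500L))
  # no truncation when disabled
  up3 <- extract_regions(rec2, "upstream", max_len = 500L,
                         truncate_at_neighbor = FALSE)
  g3 <- up3[up3$anchor_gene == "g02", ]
  expect_equal(c(g3$start, g3$end), c(0L, 500L))

  # minus-strand gene: upstream lies after its end
  rec4 <- toy_record(toy_genes(500L, 800L, "-"), length = 1000L)
  up4 <- extract_regions(rec4, "upstream", max_len = 100L)
  expect_equal(c(up4$start, up4$end), c(800L, 900L))

  expect_error(extract_regions(rec, "upstream", max_len = 0), "max_len")
})

test_that("circular upstream regions wrap the origin as two sub-intervals", {
  rec <- toy_record(toy_genes(10L, 200L), length = 1000L, circular = TRUE)
  up <- extract_regions(rec, "upstream", max_len = 300L)
  expect_equal(nrow(up), 2L)
  expect_equal(length(unique(up$region_id)), 1L)
  parts <- up[order(up$start), ]
  expect_equal(parts$start, c(0L, 710L))
  expect_equal(parts$end, c(10L, 1000L))
  # wrapped sequence reads contiguously across the origin
  s <- region_sequences(rec, up)
  expect_equal(unname(s),
               paste0(substr(rec$sequence, 711, 1000),
                      substr(rec$sequence, 1, 10)))
})

test_that("convergent genes leave the expected intergenic region", {
  rec <- toy_record(toy_genes(c(0L, 150L), c(100L, 300L), c("+", "-")),
                    length = 300L)
  ig <- extract_regions(rec, "intergenic")
  expect_equal(nrow(ig), 1L)
  expect_equal(c(ig$start, ig$end), c(100L, 150L))
})

test_that("gene and intergenic intervals partition the genome", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- sim_config(seed = seed, layout = "plain", n_genes = 10L,
                      genome_length = 8000L, gene_length_range = c(200, 500))
    rec <- simulate_genome(cfg)$record
    ig <- extract_regions(rec, "intergenic")
    covered <- logical(rec$length)
    for (i in seq_len(nrow(rec$genes)))
      covered[(rec$genes$start[i] + 1):rec$genes$end[i]] <- TRUE
    ig_cov <- logical(rec$length)
    for (i in seq_len(nrow(ig))) {
      span <- (ig$start[i] + 1):ig$end[i]
      expect_false(any(ig_cov[span]))          # no overlap among regions
      ig_cov[span] <- TRUE
    }
    expect_false(any(covered & ig_cov))        # disjoint from genes
    expect_true(all(covered | ig_cov))         # union is the genome
  }
})

test_that("upstream regions never overlap their anchor gene", {
  sim <- small_sim()
  up <- extract_regions(sim$record, "upstream", max_len = 500L)
  g <- sim$record$genes
  for (i in seq_len(nrow(up))) {
    gi <- g[g$gene_id == up$anchor_gene[i], ]
    expect_true(up$end[i] <= gi$start || up$start[i] >= gi$end)
  }
})

test_that("minus-strand region sequences are reverse-complemented", {
  rec <- toy_record(toy_genes(500L, 800L, "-"), length = 1000L)
  up <- extract_regions(rec, "upstream", max_len = 50L)
  s <- region_sequences(rec, up)
  fwd <- substr(rec$sequence, 801, 850)
  expect_equal(unname(s),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd))))
})

test_that("annotation side tables merge onto gene models", {
  rec <- toy_record(toy_genes(c(0L, 150L), c(100L, 300L)), length = 400L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcazy_family\tcellulosomal\tcluster\trole",
               "g01\tGH48\tTRUE\tcip-cel-like\tCAZyme"), tsv)
  rec <- apply_annotation_table(rec, tsv)
  expect_equal(rec$genes$cazy_family, c("GH48", NA))
  expect_equal(rec$genes$cellulosomal, c(TRUE, NA))
  expect_equal(rec$genes$role, c("CAZyme", NA))
})
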