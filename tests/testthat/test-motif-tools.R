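test_that("PSSM construction follows the smoothing and center constraint", {
  # the canonical 16-nt operator site has C,G at its two central positions
  site <- "AAGTTATCGTTAATTA"
  expect_equal(substr(site, 8, 8), "C")
  expect_equal(substr(site, 9, 9), "G")
  p <- build_palindromic_pssm(c(site, site, site))
  expect_equal(p$center, c(8L, 9L))
  expect_equal(unname(which.max(p$probs[, 8])), 2L)   # C
  expect_equal(unname(which.max(p$probs[, 9])), 3L)   # G
  expect_true(all(abs(colSums(p$probs) - 1) < 1e-12))

  # n identical sites, zero pseudocount: observed columns are certain
  p0 <- build_palindromic_pssm(c(site, site), pseudocount = 0)
  expect_equal(unname(p0$probs["A", 1]), 1)
  expect_equal(unname(p0$probs["C", 8]), 1)

  # two sites, pseudocount 0.25: cell probability (count + 0.25) / (2 + 1)
  p2 <- build_palindromic_pssm(c("AAAACGAA", "AACACGAA"), pseudocount = 0.25)
  expect_equal(unname(p2$probs["A", 3]), 1.25 / 3)
  expect_equal(unname(p2$probs["C", 3]), 1.25 / 3)
  expect_equal(unname(p2$probs["G", 3]), 0.25 / 3)
  # center override: eps = pc / (n + 4 pc)
  eps <- 0.25 / 3
  expect_equal(unname(p2$probs["C", 4]), 1 - 3 * eps)

  # odd width places the CG pair at floor(w/2), floor(w/2)+1
  p9 <- build_palindromic_pssm(c("AAACGAAAA", "AAACGAAAA"))
  expect_equal(p9$center, c(4L, 5L))

  expect_error(build_palindromic_pssm(c("AANACGAA", "AACACGAA")), "1")
  expect_error(build_palindromic_pssm(c("AAAACGAA", "AAAACGA")), "length")
  expect_error(build_palindromic_pssm("AAAACGAA"), "2")
})

test_that("the DP null distribution equals exhaustive enumeration (w <= 8)", {
  set.seed(55)
  for (w in 4:8) {
    cons <- paste(c(rep("A", ceiling((w - 2) / 2)), "C", "G",
                    rep("T", floor((w - 2) / 2))), collapse = "")
    sites <- vapply(1:6, function(i) {
      s <- strsplit(cons, "")[[1]]
      j <- sample(seq_len(w), 1)
      s[j] <- sample(c("A", "C", "G", "T"), 1)
      paste(s, collapse = "")
    }, "")
    sites <- c(sites, cons)
    ctr <- c(floor(w / 2), floor(w / 2) + 1)
    substr(sites, ctr[1], ctr[1]) <- "C"
    substr(sites, ctr[2], ctr[2]) <- "G"
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    pssm <- build_palindromic_pssm(sites, background = bg)
    nt <- score_pvalue_table(pssm, background = bg)

    # oracle: enumerate all 4^w words
    words <- do.call(expand.grid, rep(list(1:4), w))
    imat <- round(pssm$log_odds / nt$granularity)
    sc <- as.integer(rowSums(vapply(seq_len(w), function(j)
      imat[cbind(words[[j]], j)], numeric(nrow(words)))))
    pr <- apply(vapply(seq_len(w), function(j) bg[words[[j]]],
                       numeric(nrow(words))), 1, prod)
    agg <- rowsum(pr, sc)                     # probability mass per score bin
    uscores <- as.integer(rownames(agg))
    sf_enum <- rev(cumsum(rev(agg[, 1])))
    expect_equal(pssm_score_pvalue(nt, uscores), unname(sf_enum),
                 tolerance = 1e-12)
    # boundary behaviour of the survival function
    expect_equal(pssm_score_pvalue(nt, min(sc)), 1, tolerance = 1e-12)
    expect_equal(pssm_score_pvalue(nt, max(sc)), sum(pr[sc == max(sc)]),
                 tolerance = 1e-12)
    # the consensus word attains the maximal score
    cons_sc <- sum(vapply(seq_len(w), function(j)
      imat[match(substr(pssm$consensus, j, j), c("A", "C", "G", "T")), j], 0))
    expect_equal(cons_sc, max(sc))
  }
})

test_that("scanning respects the p threshold, strands and N windows", {
  sim <- small_sim()
  ps <- sim$truth$planted_sites
  pssm <- build_palindromic_pssm(ps$sequence)
  nt <- score_pvalue_table(pssm, background = genome_background(sim$record))

  # a region shorter than the motif width yields no hits
  expect_equal(nrow(suppressMessages(
    scan_sequences(c(r1 = "ACGTACGTACGT"), pssm, null_table = nt))), 0L)

  # strand symmetry: scanning a reverse complement flips strands only
  seqfwd <- paste0("TTTTTTTT", ps$sequence[1], "TTTTTTTT")
  seqrev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqfwd)))
  hf <- scan_sequences(c(a = seqfwd), pssm, null_table = nt)
  hr <- scan_sequences(c(a = seqrev), pssm, null_table = nt)
  expect_equal(nrow(hf), nrow(hr))
  expect_equal(sort(hf$score_bits), sort(hr$score_bits))
  expect_setequal(hf$match, hr$match)
  expect_true(all(hf$p <= 1e-4))

  # windows containing N are skipped
  seqn <- seqfwd
  substr(seqn, 12, 12) <- "N"                  # inside the planted window
  expect_equal(nrow(scan_sequences(c(a = seqn), pssm, null_table = nt)), 0L)

  # a perfectly palindromic window is reported once with strand "."
  pal <- "AAGTTATCGATAACTT"
  expect_equal(pal, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pal))))
  psm2 <- build_palindromic_pssm(c(pal, pal, pal))
  h2 <- scan_sequences(c(a = paste0("TTTTT", pal, "TTTTT")), psm2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, ".")
})

test_that("planted upstream sites are recovered at the scan threshold", {
  sim <- small_sim()
  ps <- sim$truth$planted_sites
  pssm <- build_palindromic_pssm(ps$sequence)
  up <- extract_regions(sim$record, "upstream", max_len = 500L)
  hits <- scan_regions(sim$record, up, pssm, p_max = 1e-4)
  found <- vapply(seq_len(nrow(ps)), function(i)
    any(hits$position == ps$position[i]), TRUE)
  expect_gte(mean(found), 0.95)
})

test_that("site-to-gene mapping computes translation-start offsets", {
  rec <- toy_record(toy_genes(c(100L, 400L), c(200L, 500L), c("+", "-")),
                    length = 600L)
  sites <- data.frame(
    position = c(60L, 100L, 484L, 550L, 300L),
    strand = c("+", "+", "-", "-", "+"),
    match = rep(strrep("A", 16), 5), stringsAsFactors = FALSE)
  m <- map_sites_to_genes(sites, rec, window = 100L)
  s <- m$sites
  expect_equal(s$assigned_gene[1], "g01")
  expect_equal(s$offset_to_start[1], -40L)
  expect_equal(s$offset_to_start[2], 0L)     # starts exactly at the start
  # minus-strand gene: site ending exactly at gene end has offset 0
  expect_equal(s$assigned_gene[3], "g02")
  expect_equal(s$offset_to_start[3], 0L)
  expect_equal(s$offset_to_start[4], -66L)
  # orphan: no same-strand gene within the window
  expect_true(is.na(s$assigned_gene[5]))
  # pairwise start-to-start separation within one upstream region
  expect_equal(nrow(m$pairs), 2L)
  p1 <- m$pairs[m$pairs$position_a == 60L | m$pairs$position_b == 60L, ]
  expect_equal(p1$separation, 40L)
})

test_that("two sites planted 87 bases apart are reported at that separation", {
  rec <- toy_record(toy_genes(400L, 500L), length = 600L, seed = 8L)
  s1 <- "AAGTTATCGTTAATTA"
  sq <- rec$sequence
  substr(sq, 261, 276) <- s1                  # start-to-start 87 bp apart
  substr(sq, 348, 363) <- s1
  rec2 <- genome_record("toy", sq, rec$genes)
  pssm <- build_palindromic_pssm(c(s1, s1, s1))
  up <- extract_regions(rec2, "upstream", max_len = 400L)
  hits <- scan_regions(rec2, up, pssm, p_max = 1e-4)
  m <- map_sites_to_genes(hits, rec2, window = 400L)
  expect_true(87L %in% m$pairs$separation)
})

test_that("background hit counts match the 2 p L expectation", {
  sim <- small_sim()
  pssm <- build_palindromic_pssm(sim$truth$planted_sites$sequence)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  nt <- score_pvalue_table(pssm, background = bg)
  set.seed(77)
  L <- 20000L
  nhit <- 0
  nseq <- 10L
  for (i in seq_len(nseq)) {
    sq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    nhit <- nhit + nrow(scan_sequences(setNames(sq, "bg"), pssm,
                                       p_max = 1e-4, null_table = nt))
  }
  expected <- 2e-4 * (L - pssm$width + 1) * nseq
  expect_lt(abs(nhit - expected), 3 * sqrt(expected))
})

test_that("MEME serialisation writes a parseable matrix", {
  sim <- small_sim()
  pssm <- build_palindromic_pssm(sim$truth$planted_sites$sequence)
  p <- withr::local_tempfile(fileext = ".meme")
  write_meme_pssm(pssm, p, name = "operator")
  lines <- readLines(p)
  expect_true(any(grepl("^MOTIF operator", lines)))
  hdr <- grep("letter-probability matrix", lines)
  mat <- do.call(rbind, lapply(strsplit(trimws(
    lines[(hdr + 1):(hdr + pssm$width)]), "\\s+"), as.numeric))
  expect_equal(dim(mat), c(16L, 4L))
  expect_equal(unname(mat[, 2][8]), unname(pssm$probs["C", 8]),
               tolerance = 1e-6)
  expect_true(all(abs(rowSums(mat) - 1) < 1e-4))
})
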