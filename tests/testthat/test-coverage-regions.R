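test_that("region calling finds maximal qualifying runs", {
  expect_equal(nrow(call_transcribed_regions(
    coverage_track("x", numeric(50), "g"))), 0L)

  r <- call_transcribed_regions(coverage_track("x", rep(3, 100), "g"))
  expect_equal(c(r$start, r$end), c(0L, 100L))

  r2 <- call_transcribed_regions(
    coverage_track("x", c(0, 1, 1, 0, 0, 1), "g"),
    min_base_depth = 1, max_gap = 0, min_length = 1)
  expect_equal(r2$start, c(1L, 5L))
  expect_equal(r2$end, c(3L, 6L))

  # gap closing merges sub-threshold gaps up to max_gap
  r3 <- call_transcribed_regions(
    coverage_track("x", c(1, 0, 1, 0, 0, 1), "g"),
    min_base_depth = 1, max_gap = 1, min_length = 1)
  expect_equal(r3$start, c(0L, 5L))
  expect_equal(r3$end, c(3L, 6L))

  # min_length filters short runs
  r4 <- call_transcribed_regions(coverage_track("x", c(1, 1, 0, 1), "g"),
                                 min_length = 2, max_gap = 0)
  expect_equal(nrow(r4), 1L)
})

test_that("region calling matches a brute-force run scan on random tracks", {
  set.seed(101)
  for (rep in 1:5) {
    d <- rbinom(400, 3, 0.35)
    trk <- coverage_track("x", d, "g")
    got <- call_transcribed_regions(trk, min_base_depth = 1, min_length = 3,
                                    max_gap = 0)
    # oracle: explicit base-by-base scan
    runs <- list(); s <- NA
    for (i in seq_len(400)) {
      if (d[i] >= 1 && is.na(s)) s <- i - 1
      if ((d[i] < 1 || i == 400) && !is.na(s)) {
        e <- if (d[i] < 1) i - 1 else i
        if (e - s >= 3) runs[[length(runs) + 1]] <- c(s, e)
        s <- NA
      }
    }
    oracle <- if (length(runs)) do.call(rbind, runs) else
      matrix(0L, 0, 2)
    expect_equal(got$start, oracle[, 1])
    expect_equal(got$end, oracle[, 2])
  }
})

# two-condition toy: depth layouts chosen so every rule branch is exercised
toy_two_condition <- function() {
  rec <- toy_record(toy_genes(c(10L, 200L), c(60L, 260L)), length = 400L)
  d1 <- numeric(400); d2 <- numeric(400)
  d1[11:60] <- 5;  d2[11:60] <- 4        # shared region -> core
  d1[101:140] <- 3                        # condition-A-only, depth 3 > 2
  d1[161:190] <- 2                        # condition-A-only, depth exactly 2
  d1[201:260] <- 6; d2[231:290] <- 6      # A region overlapping a B region
  d2[301:340] <- 8                        # condition-B-only (intergenic)
  tracks <- list(A = coverage_track("A", d1, "toy"),
                 B = coverage_track("B", d2, "toy"))
  sets <- lapply(tracks, call_transcribed_regions, min_base_depth = 1,
                 min_length = 30, max_gap = 0)
  list(rec = rec, tracks = tracks, sets = sets)
}

test_that("core and condition-specific classification follows the filters", {
  tc <- toy_two_condition()
  cls <- classify_regions(tc$sets, tc$rec, tc$tracks)
  core <- cls[cls$category == "core", ]
  # both the shared region and the A/B overlap segment are transcribed
  # under every condition
  expect_equal(core$start, c(10L, 230L))
  expect_equal(core$end, c(60L, 260L))

  spec <- cls[cls$category == "condition_specific", ]
  # depth-3 region kept; depth-exactly-2 rejected (strict >);
  # the A/B-overlapping region rejected by filter (i)
  expect_equal(sort(spec$start), c(100L, 300L))
  expect_false(any(spec$start == 160L))
  expect_false(any(spec$start == 200L))
  expect_equal(spec$conditions[order(spec$start)], c("A", "B"))
  # no condition-specific region overlaps another condition's transcription
  for (i in which(cls$category == "condition_specific")) {
    others <- setdiff(names(tc$sets), cls$conditions[i])
    for (o in others) {
      ov <- tc$sets[[o]]$start < cls$end[i] & tc$sets[[o]]$end > cls$start[i]
      expect_false(any(ov))
    }
  }
})

test_that("region context distinguishes CDS overlap, intergenic and 5'-UTR", {
  tc <- toy_two_condition()
  cls <- classify_regions(tc$sets, tc$rec, tc$tracks, upstream_window = 80L)
  expect_equal(cls$context[cls$start == 10L], "cds_overlap")
  # [100,140) lies inside the upstream window of the gene at 200 (+ strand)
  expect_equal(cls$context[cls$start == 100L], "putative_5utr")
  expect_equal(cls$context[cls$start == 300L], "intergenic")
})

test_that("core regions equal a per-base boolean-AND oracle", {
  cfg <- sim_config(seed = 17L, layout = "plain", n_genes = 10L,
                    genome_length = 9000L, asd_per_condition = 8,
                    conditions = c("Glu", "Ceb", "Cel"),
                    growth_rates = c(Glu = 0.05, Ceb = 0.2, Cel = 0.1))
  sim <- simulate_genome(cfg)
  tracks <- lapply(c("Glu", "Ceb", "Cel"), function(cond)
    simulate_coverage(sim$record, sim$truth, cfg, cond))
  names(tracks) <- c("Glu", "Ceb", "Cel")
  sets <- lapply(tracks, call_transcribed_regions, min_base_depth = 1,
                 min_length = 30, max_gap = 0)
  cls <- classify_regions(sets, sim$record, tracks)
  core <- cls[cls$category == "core", ]
  # oracle: AND of the per-condition region masks, base by base
  mask <- rep(TRUE, cfg$genome_length)
  for (cond in names(sets)) {
    m <- rep(FALSE, cfg$genome_length)
    for (i in seq_len(nrow(sets[[cond]])))
      m[(sets[[cond]]$start[i] + 1):sets[[cond]]$end[i]] <- TRUE
    mask <- mask & m
  }
  got <- rep(FALSE, cfg$genome_length)
  for (i in seq_len(nrow(core))) got[(core$start[i] + 1):core$end[i]] <- TRUE
  expect_identical(got, mask)
})

test_that("planted single-condition genes are recovered as specific regions", {
  cfg <- sim_config(seed = 29L, layout = "plain", n_genes = 40L,
                    genome_length = 50000L)
  sim <- simulate_genome(cfg)
  # plant 10 genes expressed under cellulose only
  planted <- sprintf("SYN_%04d", seq(2, 38, by = 4))
  sim$truth$nta[planted, setdiff(cfg$conditions, "Cel")] <- 0
  tracks <- lapply(cfg$conditions, function(cond)
    simulate_coverage(sim$record, sim$truth, cfg, cond))
  names(tracks) <- cfg$conditions
  sets <- lapply(tracks, call_transcribed_regions, min_base_depth = 1,
                 min_length = 30, max_gap = 0)
  cls <- classify_regions(sets, sim$record, tracks)
  spec <- cls[cls$category == "condition_specific" & cls$conditions == "Cel", ]
  g <- sim$record$genes
  recovered <- vapply(planted, function(id) {
    gi <- g[g$gene_id == id, ]
    any(spec$start < gi$end & spec$end > gi$start)
  }, TRUE)
  expect_gte(mean(recovered), 0.9)
})

test_that("transcribed fraction accounts for region unions", {
  r <- data.frame(start = c(0L, 50L, 40L), end = c(50L, 80L, 60L))
  expect_equal(transcribed_fraction(r, 100L), 0.8)
  expect_equal(transcribed_fraction(r[0, ], 100L), 0)
})
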