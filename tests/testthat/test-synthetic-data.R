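test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 19L, n_genes = 150L, genome_length = 160000L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$genes, b$record$genes)
  expect_identical(a$truth$nta, b$truth$nta)
  expect_identical(a$truth$planted_sites, b$truth$planted_sites)
  ta <- simulate_coverage(a$record, a$truth, cfg, "Cel")
  tb <- simulate_coverage(b$record, b$truth, cfg, "Cel")
  expect_identical(ta$depth, tb$depth)
})

test_that("motif planting follows the configured rate and CG constraint", {
  cfg0 <- sim_config(seed = 5L, motif_rate = 0)
  expect_equal(nrow(simulate_genome(cfg0)$truth$planted_sites), 0L)

  sim <- small_sim()
  ps <- sim$truth$planted_sites
  nI <- sum(sim$truth$group_label == "I")
  expect_equal(nrow(ps), ceiling(sim$cfg$motif_rate * nI))
  ctr <- c(8L, 9L)                      # central positions of a 16-mer
  expect_true(all(substr(ps$sequence, ctr[1], ctr[1]) == "C"))
  expect_true(all(substr(ps$sequence, ctr[2], ctr[2]) == "G"))
  # planted sites sit in the upstream region of their gene, on its strand,
  # and the genome carries the (strand-adjusted) site sequence
  g <- sim$record$genes
  for (i in seq_len(nrow(ps))) {
    gi <- g[g$gene_id == ps$gene_id[i], ]
    written <- substr(sim$record$sequence, ps$position[i] + 1,
                      ps$position[i] + 16)
    if (gi$strand == "+") {
      expect_true(ps$position[i] + 16 <= gi$start)
      expect_equal(written, ps$sequence[i])
    } else {
      expect_true(ps$position[i] >= gi$end)
      expect_equal(written, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ps$sequence[i]))))
    }
  }
})

test_that("group structure matches the configured study conditions", {
  sim <- small_sim()
  tr <- sim$truth
  gI <- tr$nta[tr$group_label == "I", , drop = FALSE]
  prof <- colMeans(gI)
  # carbon catabolite repression: expression anti-ordered with growth rate
  expect_true(prof["Ceb"] < prof["Xyl"])
  expect_true(prof["Xyl"] < prof["Xyn"])
  expect_true(prof["Xyn"] < prof["Cel"])
  expect_equal(unname(prof["Cel"]), unname(prof["Glu"]))  # tied growth, tied NTA
  expect_equal(unname(prof["Cel"]), unname(prof["CS"]))
  rankable <- c("Ceb", "Xyl", "Xyn", "Cel")
  expect_equal(cor(prof[rankable], tr$growth_rates[rankable],
                   method = "spearman"), -1)
  # true NTA is a proper abundance: length-weighted sum equals genome length
  tot <- colSums(tr$gene_length * tr$nta)
  expect_equal(unname(tot), rep(sim$cfg$genome_length, 6), tolerance = 1e-9)
})

test_that("coverage reproduces the configured depth and the true NTA", {
  sim <- small_sim()
  for (cond in c("Glu", "Cel")) {
    trk <- sim$tracks[[cond]]
    expect_lt(abs(compute_asd(trk) - sim$cfg$asd_per_condition[[cond]]) /
                sim$cfg$asd_per_condition[[cond]], 0.05)
  }
  err <- abs(sim$expr$nta[, "Cel"] - sim$truth$nta[, "Cel"]) /
    sim$truth$nta[, "Cel"]
  expect_lt(median(err), 0.10)
})

test_that("a gene with true NTA zero gets zero depth when noise is off", {
  cfg <- sim_config(seed = 23L, layout = "plain", n_genes = 8L,
                    genome_length = 10000L)
  sim <- simulate_genome(cfg)
  sim$truth$nta["SYN_0003", ] <- 0
  trk <- simulate_coverage(sim$record, sim$truth, cfg, "Glu")
  g <- sim$record$genes[3L, ]
  expect_true(all(trk$depth[(g$start + 1):g$end] == 0))
  expect_error(simulate_coverage(sim$record, sim$truth, cfg, "Mal"),
               "unknown condition")
})

test_that("total simulated bases converge to the configured depth", {
  cfg <- sim_config(seed = 31L, n_genes = 600L, genome_length = 600000L,
                    dispersion = 0.005)
  sim <- simulate_genome(cfg)
  asd <- mean(vapply(c("Cel", "Glu"), function(cond)
    sum(simulate_coverage(sim$record, sim$truth, cfg, cond)$depth) /
      cfg$genome_length, 0))
  expect_lt(abs(asd - 20) / 20, 0.01)
})

test_that("degradation curves are noiseless logistics when noise_sd = 0", {
  p <- list(K = 6, r = 1, t0 = 5, noise_sd = 0)
  tp <- seq(0, 14, by = 0.5)
  cv <- simulate_degradation_curve(p, tp, seed = 3L)
  expect_equal(cv$degraded, 6 / (1 + exp(-(tp - 5))), tolerance = 1e-12)
  # maximal finite-difference slope approximates the analytic peak r*K/4
  fine <- simulate_degradation_curve(p, seq(0, 14, by = 0.1), seed = 3L)
  slope <- max(diff(fine$degraded) / diff(fine$day))
  expect_equal(slope, 1.5, tolerance = 0.01)
  # seeded noise is reproducible
  a <- simulate_degradation_curve(list(K = 6, r = 1, t0 = 5, noise_sd = 0.1),
                                  tp, seed = 9L)
  b <- simulate_degradation_curve(list(K = 6, r = 1, t0 = 5, noise_sd = 0.1),
                                  tp, seed = 9L)
  expect_identical(a, b)
  expect_error(simulate_degradation_curve(p, 1:3, seed = 1L), "timepoints")
})

test_that("undersized genomes and bad configs are rejected", {
  expect_error(sim_config(seed = 1L, group_fractions = c(I = 0.5)),
               "sum to 1")
  expect_error(sim_config(seed = 1L, conditions = "Glu"), "2 conditions")
  expect_error(simulate_genome(sim_config(seed = 1L, n_genes = 200L,
                                          genome_length = 50000L)),
               "too short")
})
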