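## Seeded synthetic-data generator. Emulates the statistical structure of a
## multi-condition bacterial RNA-Seq study of a cellulolytic clostridium:
## a small circular genome with operonic gene clusters (a 13-gene
## cellulosomal "cip-cel"-like cluster, a 14-gene hemicellulasic
## "xyl-doc"-like cluster, three two-component-system loci), six carbon
## sources with group-structured expression (a carbon-catabolite-repression
## group anti-correlated with growth rate, substrate-specific groups),
## per-base coverage from 36-base uniquely mapped reads, planted 16-nt
## palindromic operator sites with a fixed central CG, and sigmoidal
## substrate-degradation curves. Ground truth for every stage is returned
## alongside the data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: six carbon
#' sources, growth ordering Ceb > Xyl > Xyn > Cel = CS = Glu, an 8-fold
#' separation between high and low expression states, 36-base single-end
#' reads, and a 16-nt palindromic operator motif with fixed central CG.
#'
#' @param seed Integer master seed; every operation derives its own stream
#'   from it.
#' @param genome_length Genome size in bases (default 200000).
#' @param n_genes Number of genes (default 200; the full layout needs at
#'   least 150).
#' @param conditions Ordered condition names.
#' @param group_fractions Named proportions for expression groups
#'   `I, II, III, IV, background`; must sum to 1.
#' @param asd_per_condition Mean sequencing depth (x) per condition; scalar
#'   or named vector.
#' @param growth_rates Named growth rates (1/h) per condition.
#' @param read_length Read length in bases (default 36).
#' @param dispersion Negative-binomial overdispersion of per-gene read
#'   counts (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param motif_width,motif_consensus Width and consensus of the planted
#'   palindromic operator; the two central bases must be "CG".
#' @param motif_rate Fraction of Group-I genes receiving a planted upstream
#'   site.
#' @param motif_fidelity Per-position probability that a planted site
#'   carries the consensus base (center CG is always exact).
#' @param intergenic_leak Expected background depth outside genes (default
#'   0, i.e. clean intergenic space).
#' @param high_fold Fold separation between high- and low-expression
#'   conditions (default 8).
#' @param kinetics_params List `K` (g/L), `r` (1/day), `t0` (day),
#'   `noise_sd` (g/L) for degradation curves.
#' @param gene_length_range Min/max gene length in bases (default 300-1100).
#' @param layout `"full"` plants the clusters and TCS loci; `"plain"` places
#'   plain background genes only (useful for tiny oracle genomes).
#' @param cs_condition Condition treated as the lignocellulosic composite
#'   substrate (Group III high there).
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_genes = 200L,
                       conditions = c("Glu", "Ceb", "Xyl", "Cel", "Xyn", "CS"),
                       group_fractions = c(I = 0.15, II = 0.15, III = 0.10,
                                           IV = 0.10, background = 0.50),
                       asd_per_condition = 20,
                       growth_rates = c(Glu = 0.05, Ceb = 0.20, Xyl = 0.15,
                                        Cel = 0.05, Xyn = 0.10, CS = 0.05),
                       read_length = 36L,
                       dispersion = 0.01,
                       motif_width = 16L,
                       motif_consensus = "AAGTTATCGTTAATTA",
                       motif_rate = 0.8,
                       motif_fidelity = 0.85,
                       intergenic_leak = 0,
                       high_fold = 8,
                       kinetics_params = list(K = 6, r = 1, t0 = 5,
                                              noise_sd = 0.1),
                       gene_length_range = c(300, 1100),
                       layout = c("full", "plain"),
                       cs_condition = "CS") {
  layout <- match.arg(layout)
  if (length(conditions) < 2L) .stopf("need at least 2 conditions")
  if (abs(sum(group_fractions) - 1) > 1e-8)
    .stopf("group_fractions must sum to 1")
  if (!all(names(group_fractions) %in% c("I", "II", "III", "IV", "background")))
    .stopf("group_fractions must be named I, II, III, IV, background")
  if (!all(conditions %in% names(growth_rates)))
    .stopf("growth_rates must cover every condition")
  if (any(growth_rates <= 0)) .stopf("all growth rates must be > 0")
  .check_number(high_fold, "high_fold", min = 1, strict = TRUE)
  .check_number(motif_rate, "motif_rate", min = 0)
  if (nchar(motif_consensus) != motif_width)
    .stopf("motif_consensus length must equal motif_width")
  ctr <- .pssm_center(motif_width)
  if (substr(motif_consensus, ctr[1L], ctr[1L]) != "C" ||
      substr(motif_consensus, ctr[2L], ctr[2L]) != "G")
    .stopf("motif_consensus must carry C,G at its two central positions")
  asd <- if (length(asd_per_condition) == 1L)
    setNames(rep(asd_per_condition, length(conditions)), conditions)
  else asd_per_condition
  if (!all(conditions %in% names(asd)))
    .stopf("asd_per_condition must be scalar or named per condition")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_genes = as.integer(n_genes), conditions = conditions,
                 group_fractions = group_fractions,
                 asd_per_condition = asd[conditions],
                 growth_rates = growth_rates[conditions],
                 read_length = as.integer(read_length),
                 dispersion = dispersion, motif_width = as.integer(motif_width),
                 motif_consensus = motif_consensus, motif_rate = motif_rate,
                 motif_fidelity = motif_fidelity,
                 intergenic_leak = intergenic_leak, high_fold = high_fold,
                 kinetics_params = kinetics_params,
                 gene_length_range = gene_length_range, layout = layout,
                 cs_condition = cs_condition),
            class = "SimulationConfig")
}

## CCR multiplier per condition: conditions ranked by growth (descending);
## distinct growth levels map to geometric steps 1 ... high_fold, so true
## Group-I expression is exactly rank-anti-correlated with growth rate
## (ties in growth produce ties in expression).
.ccr_multipliers <- function(growth, high_fold) {
  lev <- sort(unique(growth), decreasing = TRUE)
  k <- length(lev)
  if (k == 1L) return(setNames(rep(1, length(growth)), names(growth)))
  step <- high_fold^(1 / (k - 1))
  setNames(step^(match(growth, lev) - 1), names(growth))
}

## operator sites are consensus-like with a bounded number of mismatches
## (cre-like sites are reported with up to 3 substitutions); the center CG
## is always exact
.sample_motif_site <- function(consensus, fidelity, center,
                               max_mismatch = 3L) {
  w <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1L]]
  free <- setdiff(seq_len(w), center)
  nmm <- min(rbinom(1L, length(free), 1 - fidelity), max_mismatch)
  mm <- if (nmm > 0L) sample(free, nmm) else integer()
  out <- cons
  for (j in mm) out[j] <- sample(setdiff(DNA_BASES4, cons[j]), 1L)
  paste(out, collapse = "")
}

#' Simulate a genome with ground truth
#'
#' Places `n_genes` genes with 50-400 bp intergenic gaps on a circular
#' chromosome. The full layout includes a contiguous 13-gene Group-I
#' cellulosomal cluster, a 14-gene Group-III cluster and three
#' two-component-system loci (one per locus category: solute-binding
#' protein inside the TCS operon, CAZyme inside it, or a bare
#' sensor-regulator pair). Palindromic operator sites with exact central CG
#' are planted upstream of a `motif_rate` fraction of Group-I genes. True
#' per-gene NTA is normalised per condition so that
#' `sum(length * NTA) = genome length` (the identity real NTA obeys when all
#' coverage is genic), with the non-CAZyme background absorbing condition
#' imbalance so cross-condition group structure is exact.
#'
#' @param config A [sim_config()].
#' @return `list(record = GenomeRecord, truth = SimTruth)`. `truth` carries
#'   `group_label`, `subtype`, `nta` (true genes x conditions matrix),
#'   `planted_sites`, `tcs_loci`, `growth_rates`, `kinetics_params`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.child_seed(config$seed, "genome"))
  n <- config$n_genes
  L <- config$genome_length
  conds <- config$conditions
  full <- config$layout == "full"
  if (full && n < 150L)
    .stopf("full layout needs n_genes >= 150 (got %d)", n)

  ## ---- gene placement ----
  glr <- config$gene_length_range
  lens <- round(runif(n, glr[1L], glr[2L]))
  gaps <- if (full) round(runif(n, 150, 400)) else round(runif(n, 50, 400))
  cip_idx <- xyl_idx <- integer()
  tcs1_idx <- tcs2_idx <- tcs3_idx <- integer()
  strand <- sample(c("+", "-"), n, replace = TRUE)
  if (full) {
    cip_idx <- 21:33                    # 13-gene Group-I cluster
    xyl_idx <- 61:74                    # 14-gene Group-III cluster
    tcs1_idx <- 101:107                 # CAZyme, ABCx3, SBP, sensor, regulator
    tcs2_idx <- 121:123                 # sensor, regulator, CAZyme (in operon)
    tcs3_idx <- 141:142                 # sensor, regulator only
    ## the category-I locus mirrors its real counterpart as three
    ## transcription units: CAZyme | ABC transporter triplet | TCS operon
    ## carrying the solute-binding protein
    operonic <- c(cip_idx[-1L], xyl_idx[-1L], tcs1_idx[c(3L, 4L, 6L, 7L)],
                  tcs2_idx[-1L], tcs3_idx[-1L])
    gaps[operonic] <- round(runif(length(operonic), 50, 90))
    strand[c(cip_idx, xyl_idx, tcs1_idx, tcs2_idx, tcs3_idx)] <- "+"
  }
  total <- sum(lens) + sum(gaps)
  if (total > L)
    .stopf("genome too short: %d bases needed, %d available", total, L)
  starts <- cumsum(gaps) + c(0, cumsum(lens))[seq_len(n)]
  ends <- starts + lens

  ## ---- roles, groups, annotations ----
  label <- rep("background", n)
  subtype <- rep(NA_character_, n)
  role <- rep("other", n)
  cazy <- rep(NA_character_, n)
  cellulosomal <- rep(FALSE, n)
  cluster <- rep(NA_character_, n)
  substrates <- intersect(c("Cel", "Ceb", "Xyl", "Xyn"), conds)
  if (!length(substrates)) substrates <- setdiff(conds, config$cs_condition)

  if (full) {
    label[cip_idx] <- "I"; role[cip_idx] <- "CAZyme"
    cellulosomal[cip_idx] <- TRUE; cluster[cip_idx] <- "cip-cel-like"
    cazy[cip_idx] <- sample(c("GH5", "GH9", "GH26", "GH48", "CN"),
                            length(cip_idx), replace = TRUE)
    label[xyl_idx] <- "III"; role[xyl_idx] <- "CAZyme"
    cellulosomal[xyl_idx] <- TRUE; cluster[xyl_idx] <- "xyl-doc-like"
    cazy[xyl_idx] <- sample(c("GH43", "GH27", "GH10"),
                            length(xyl_idx), replace = TRUE)
    ## Category-I TCS locus: CAZyme, ABC transporter triplet, then the TCS
    ## operon carrying the solute-binding protein (signal collector)
    role[tcs1_idx] <- c("CAZyme", "ABC", "ABC", "ABC", "SBP",
                        "TCS_sensor", "TCS_regulator")
    label[tcs1_idx[1L]] <- "II"; subtype[tcs1_idx[1L]] <- "Cel"
    cazy[tcs1_idx[1L]] <- "GH94"
    label[tcs1_idx[2:4]] <- "II"; subtype[tcs1_idx[2:4]] <- "Cel"
    cluster[tcs1_idx] <- "tcs-locus-1"
    ## Category-II TCS locus: CAZyme inside the TCS operon
    role[tcs2_idx] <- c("TCS_sensor", "TCS_regulator", "CAZyme")
    label[tcs2_idx[3L]] <- "II"
    subtype[tcs2_idx[3L]] <- substrates[1L]
    cazy[tcs2_idx[3L]] <- "GH10"
    cluster[tcs2_idx] <- "tcs-locus-2"
    ## Category-III TCS locus: bare sensor-regulator pair
    role[tcs3_idx] <- c("TCS_sensor", "TCS_regulator")
    cluster[tcs3_idx] <- "tcs-locus-3"

    ## fill group quotas over the unassigned genes
    free <- which(label == "background" & role == "other")
    want <- round(config$group_fractions[c("I", "II", "III", "IV")] * n)
    add_I <- max(0L, want[["I"]] - sum(label == "I"))
    add_II <- max(0L, want[["II"]] - sum(label == "II" & role == "CAZyme"))
    add_III <- max(0L, want[["III"]] - sum(label == "III"))
    add_IV <- want[["IV"]]
    need <- add_I + add_II + add_III + add_IV
    if (need > length(free))
      .stopf("group fractions leave no background genes")
    pick <- sample(free, need)
    gI <- pick[seq_len(add_I)]
    gII <- pick[add_I + seq_len(add_II)]
    gIII <- pick[add_I + add_II + seq_len(add_III)]
    gIV <- pick[add_I + add_II + add_III + seq_len(add_IV)]
    label[gI] <- "I"; role[gI] <- "CAZyme"
    cazy[gI] <- sample(c("GH5", "GH9", "GH48"), add_I, replace = TRUE)
    label[gII] <- "II"; role[gII] <- "CAZyme"
    subtype[gII] <- substrates[(seq_len(add_II) - 1L) %% length(substrates) + 1L]
    cazy[gII] <- sample(c("GH10", "GH51", "GH94", "GH18"), add_II,
                        replace = TRUE)
    label[gIII] <- "III"; role[gIII] <- "CAZyme"
    cazy[gIII] <- sample(c("GH43", "GH27"), add_III, replace = TRUE)
    label[gIV] <- "IV"; role[gIV] <- "CAZyme"
    cazy[gIV] <- sample(c("GT1", "GT2", "CE8"), add_IV, replace = TRUE)
  }

  ## ---- true NTA ----
  base <- rlnorm(n, meanlog = 0, sdlog = 0.6)
  low_roles <- role %in% c("SBP", "TCS_sensor", "TCS_regulator")
  base[low_roles] <- base[low_roles] * 0.05   # constitutive low TCS operons
  multI <- .ccr_multipliers(config$growth_rates, config$high_fold)
  mult <- matrix(1, n, length(conds), dimnames = list(NULL, conds))
  if (any(label == "I"))
    mult[label == "I", ] <- matrix(multI[conds], sum(label == "I"),
                                   length(conds), byrow = TRUE)
  for (s in substrates) {
    sel <- label == "II" & !is.na(subtype) & subtype == s
    if (any(sel)) mult[sel, s] <- config$high_fold
  }
  if (config$cs_condition %in% conds)
    mult[label == "III", config$cs_condition] <- config$high_fold
  ## Group IV: glucose-associated remainder enzymes (high under the
  ## monosaccharide, a pattern matching none of the I-III rules)
  mono <- setdiff(conds, c(substrates, config$cs_condition))[1L]
  if (!is.na(mono)) mult[label == "IV", mono] <- config$high_fold
  nta_raw <- base * mult
  bg <- label == "background"
  if (any(bg) && any(!bg)) {
    A <- colSums(lens[!bg] * nta_raw[!bg, , drop = FALSE])
    B <- sum(lens[bg] * base[bg])
    Tstar <- max(A) + B
    b <- (Tstar - A) / B                 # per-condition balancing level >= 1
    nta_raw[bg, ] <- outer(base[bg], b)
  }
  tot <- colSums(lens * nta_raw)         # equal across conditions when bg used
  nta <- sweep(nta_raw, 2L, tot / L, "/")

  ## ---- sequence + planted motifs ----
  seq_v <- sample(DNA_BASES4, L, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  ctr <- .pssm_center(config$motif_width)
  w <- config$motif_width
  planted <- list()
  gI_all <- which(label == "I")
  n_plant <- if (config$motif_rate > 0 && length(gI_all))
    min(length(gI_all), ceiling(config$motif_rate * length(gI_all))) else 0L
  if (n_plant > 0L) {
    host <- sort(sample(gI_all, n_plant))
    for (i in host) {
      gap_avail <- if (i == 1L) starts[1L] else starts[i] - ends[i - 1L]
      dmax <- min(120L, gap_avail - w - 5L)
      if (dmax < 10L) next
      d <- sample(10:dmax, 1L)
      site <- .sample_motif_site(config$motif_consensus,
                                 config$motif_fidelity, ctr)
      if (strand[i] == "+") {
        pos <- starts[i] - d - w
        seq_v[(pos + 1L):(pos + w)] <- strsplit(site, "")[[1L]]
      } else {
        pos <- ends[i] + d
        seq_v[(pos + 1L):(pos + w)] <- strsplit(.revcomp(site), "")[[1L]]
      }
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = sprintf("SYN_%04d", i), position = pos, strand = strand[i],
        sequence = site, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted)
  else data.frame(gene_id = character(), position = integer(),
                  strand = character(), sequence = character(),
                  stringsAsFactors = FALSE)

  gene_id <- sprintf("SYN_%04d", seq_len(n))
  genes <- data.frame(gene_id = gene_id, start = as.integer(starts),
                      end = as.integer(ends), strand = strand,
                      feature_type = "CDS", cazy_family = cazy,
                      cellulosomal = cellulosomal, cluster = cluster,
                      role = role, stringsAsFactors = FALSE)
  record <- genome_record("synthetic_chromosome",
                          paste(seq_v, collapse = ""), genes,
                          circular = TRUE, source_format = "synthetic")
  rownames(nta) <- gene_id
  tcs_loci <- if (full) data.frame(
    locus = c("tcs-locus-1", "tcs-locus-2", "tcs-locus-3"),
    category = c("I", "II", "III"),
    stringsAsFactors = FALSE) else
    data.frame(locus = character(), category = character(),
               stringsAsFactors = FALSE)
  truth <- structure(list(group_label = setNames(label, gene_id),
                          subtype = setNames(subtype, gene_id),
                          nta = nta, gene_length = setNames(lens, gene_id),
                          planted_sites = planted, tcs_loci = tcs_loci,
                          growth_rates = config$growth_rates,
                          kinetics_params = config$kinetics_params,
                          motif_consensus = config$motif_consensus),
                     class = "SimTruth")
  list(record = record, truth = truth)
}

#' Simulate a per-base coverage track for one condition
#'
#' Per-gene read counts are drawn negative-binomially with mean
#' `NTA * ASD * length / read_length`; read start positions are uniform
#' within the gene (reads never span gene boundaries); per-base depth is
#' accumulated from `read_length`-base reads. Intergenic background depth is
#' 0 unless `intergenic_leak` is set.
#'
#' @param record,truth Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @param condition Condition name.
#' @return A `CoverageTrack` (see [coverage_track()]).
#' @export
simulate_coverage <- function(record, truth, config, condition) {
  if (!condition %in% config$conditions)
    .stopf("unknown condition '%s'", condition)
  set.seed(.child_seed(config$seed, paste0("coverage_", condition)))
  L <- record$length
  rl <- config$read_length
  asd <- config$asd_per_condition[[condition]]
  g <- record$genes
  delta <- numeric(L + rl + 1L)
  for (i in seq_len(nrow(g))) {
    len <- g$end[i] - g$start[i]
    span <- min(rl, len)
    mu <- truth$nta[g$gene_id[i], condition] * asd * len / span
    if (mu <= 0) next
    k <- if (config$dispersion > 0)
      rnbinom(1L, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(1L, mu)
    if (k == 0L) next
    s <- g$start[i] + sample.int(max(1L, len - span + 1L), k, replace = TRUE) - 1L
    tb <- tabulate(s + 1L, nbins = L)
    idx <- which(tb > 0L)
    delta[idx] <- delta[idx] + tb[idx]
    delta[idx + span] <- delta[idx + span] - tb[idx]
  }
  if (config$intergenic_leak > 0) {
    nleak <- stats::rpois(1L, config$intergenic_leak * L / rl)
    if (nleak > 0L) {
      s <- sample.int(L - rl + 1L, nleak, replace = TRUE) - 1L
      tb <- tabulate(s + 1L, nbins = L)
      idx <- which(tb > 0L)
      delta[idx] <- delta[idx] + tb[idx]
      delta[idx + rl] <- delta[idx + rl] - tb[idx]
    }
  }
  depth <- cumsum(delta)[seq_len(L)]
  coverage_track(condition, as.integer(round(depth)), record$id,
                 seed = .child_seed(config$seed, paste0("coverage_", condition)))
}

#' Simulate a sigmoidal substrate-degradation curve
#'
#' Logistic `K / (1 + exp(-r (t - t0)))` plus i.i.d. Gaussian noise.
#'
#' @param params List with `K` (g/L), `r` (1/day), `t0` (day), `noise_sd`
#'   (g/L).
#' @param timepoints Numeric vector of days (at least 5).
#' @param seed Integer seed.
#' @return `data.frame(day, degraded)`.
#' @export
simulate_degradation_curve <- function(params, timepoints, seed = 1L) {
  if (length(timepoints) < 5L) .stopf("need at least 5 timepoints")
  set.seed(.child_seed(seed, "kinetics"))
  mu <- params$K / (1 + exp(-params$r * (timepoints - params$t0)))
  noise <- if ((params$noise_sd %||% 0) > 0)
    rnorm(length(timepoints), 0, params$noise_sd) else 0
  data.frame(day = timepoints, degraded = mu + noise)
}
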