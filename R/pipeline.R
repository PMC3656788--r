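## End-to-end orchestration: simulate (or load) -> quantify -> regions ->
## differential expression -> degradome classification -> regulon inference
## -> motif scan -> kinetics, with every intermediate written as TSV/BED/
## FASTA/GFF3 and a JSON manifest recording config, seed and per-stage row
## counts. Reruns with the same config and seed are byte-identical.

.write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

#' Assemble a pipeline configuration
#'
#' @param path Optional YAML file; keys mirror the arguments and the file's
#'   values are overridden by arguments passed here.
#' @param seed Master seed for every stage.
#' @param sim Named list of [sim_config()] overrides.
#' @param coverage Optional named list of coverage TSV paths per condition
#'   (external data instead of simulation); requires `genome_fasta` and
#'   `genome_gff`.
#' @param genome_fasta,genome_gff,annotation Optional external genome
#'   inputs.
#' @param deg_p_cutoff Consensus DEG p cutoff (number or preset name).
#' @param degradome_target,degradome_refs Degradome definition conditions.
#' @param min_base_depth,min_region_length,max_region_gap Region-calling
#'   thresholds.
#' @param min_specific_depth Strict mean-depth bound for accessory regions.
#' @param upstream_len Upstream window for the motif-scan database (bases).
#' @param motif_p_max Motif-scan p threshold.
#' @param kinetics_timepoints Days sampled for the degradation curve.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(path = NULL, seed = 1L, sim = list(),
                            coverage = NULL, genome_fasta = NULL,
                            genome_gff = NULL, annotation = NULL,
                            deg_p_cutoff = "methods_default",
                            degradome_target = "Cel",
                            degradome_refs = c("Glu", "Ceb"),
                            min_base_depth = 1, min_region_length = 30L,
                            max_region_gap = 0L, min_specific_depth = 2,
                            upstream_len = 500L, motif_p_max = 1e-4,
                            kinetics_timepoints = 0:14) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  args <- list(seed = seed, sim = sim, coverage = coverage,
               genome_fasta = genome_fasta, genome_gff = genome_gff,
               annotation = annotation, deg_p_cutoff = deg_p_cutoff,
               degradome_target = degradome_target,
               degradome_refs = degradome_refs,
               min_base_depth = min_base_depth,
               min_region_length = min_region_length,
               max_region_gap = max_region_gap,
               min_specific_depth = min_specific_depth,
               upstream_len = upstream_len, motif_p_max = motif_p_max,
               kinetics_timepoints = kinetics_timepoints)
  defaults <- formals(pipeline_config)
  for (nm in names(args)) {
    passed <- !identical(args[[nm]], eval(defaults[[nm]]))
    if (passed || is.null(cfg[[nm]])) cfg[[nm]] <- args[[nm]]
  }
  if (is.character(cfg$deg_p_cutoff))
    cfg$deg_p_cutoff <- deg_preset(cfg$deg_p_cutoff)
  structure(cfg, class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Executes every stage on synthetic data (default) or on externally
#' supplied genome + coverage inputs, writes all intermediates under
#' `outdir`, and returns the run manifest. A stage failure is recorded in
#' the manifest (prior outputs are retained) rather than raised.
#'
#' @param config A [pipeline_config()] (or a YAML path passed to it).
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly also written as `manifest.json`.
#' @export
run_full <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- pipeline_config(path = config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ## fail fast: declared external inputs must exist before any stage runs
  ext <- unlist(config[c("genome_fasta", "genome_gff", "annotation")],
                use.names = FALSE)
  ext <- c(ext, unlist(config$coverage, use.names = FALSE))
  if (length(ext) && !all(file.exists(ext)))
    .stopf("validation failure: missing input file(s): %s",
           paste(ext[!file.exists(ext)], collapse = ", "))
  external <- !is.null(config$coverage)
  if (external && (is.null(config$genome_fasta) || is.null(config$genome_gff)))
    .stopf("validation failure: external coverage requires genome_fasta and genome_gff")

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(package = "degradomeR",
                   version = as.character(utils::packageVersion("degradomeR")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   stages = list())
  note <- function(stage, status, n, files = character()) {
    manifest$stages[[stage]] <<- list(status = status, rows = n,
                                      outputs = as.list(basename(files)))
    message(sprintf("[%s] %s (%s rows)", stage, status, n))
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      note(stage, paste0("failed: ", conditionMessage(e)), 0L)
      NULL
    })
  }

  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    if (external) {
      state$record <- read_genome_record(config$genome_fasta, "fasta+gff3",
                                         gff = config$genome_gff,
                                         annotation = config$annotation)
      state$truth <- NULL
      state$sim_cfg <- NULL
      state$tracks <- lapply(names(config$coverage), function(cond)
        read_coverage_tsv(config$coverage[[cond]],
                          genome_length = state$record$length,
                          condition = cond, genome_id = state$record$id))
      names(state$tracks) <- names(config$coverage)
      note("simulate", "ok (external inputs)", nrow(state$record$genes))
      return(invisible())
    }
    state$sim_cfg <- do.call(sim_config, c(list(seed = config$seed),
                                           config$sim))
    sim <- simulate_genome(state$sim_cfg)
    state$record <- sim$record
    state$truth <- sim$truth
    fa <- file.path(outdir, "genome.fasta")
    gff <- file.path(outdir, "genome.gff3")
    write_genome_record(state$record, fa, gff)
    tr <- file.path(outdir, "truth_nta.tsv")
    .write_tsv(data.frame(gene_id = rownames(sim$truth$nta),
                          group = unname(sim$truth$group_label),
                          subtype = unname(sim$truth$subtype),
                          sim$truth$nta, check.names = FALSE), tr)
    state$tracks <- list()
    covs <- character()
    for (cond in state$sim_cfg$conditions) {
      trk <- simulate_coverage(state$record, state$truth, state$sim_cfg, cond)
      state$tracks[[cond]] <- trk
      cv <- file.path(outdir, sprintf("coverage_%s.tsv", cond))
      write_coverage_tsv(trk, cv)
      covs <- c(covs, cv)
    }
    note("simulate", "ok", nrow(state$record$genes), c(fa, gff, tr, covs))
  })

  run_stage("quantify", function() {
    state$expr <- compute_nta_table(state$tracks, state$record)
    f <- file.path(outdir, "expression.tsv")
    write_expression_tsv(state$expr, f)
    note("quantify", "ok", length(state$expr$genes), f)
  })

  run_stage("regions", function() {
    state$region_sets <- lapply(state$tracks, call_transcribed_regions,
                                min_base_depth = config$min_base_depth,
                                min_length = config$min_region_length,
                                max_gap = config$max_region_gap)
    cls <- classify_regions(state$region_sets, state$record, state$tracks,
                            min_specific_depth = config$min_specific_depth,
                            upstream_window = config$upstream_len)
    f <- file.path(outdir, "regions_classified.tsv")
    .write_tsv(cls, f)
    b <- file.path(outdir, "regions_classified.bed")
    write_regions_bed(data.frame(region_id = cls$region_id,
                                 start = cls$start, end = cls$end,
                                 strand = "."), b, state$record$id)
    note("regions", "ok", nrow(cls), c(f, b))
  })

  run_stage("deg", function() {
    conds <- state$expr$conditions
    pairs <- utils::combn(conds, 2L)
    degs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
      deg_table(state$expr, pairs[1L, i], pairs[2L, i],
                p_cutoff = config$deg_p_cutoff)))
    state$degs <- degs
    f <- file.path(outdir, "deg_all_pairs.tsv")
    .write_tsv(degs, f)
    note("deg", "ok", nrow(degs), f)
  })

  run_stage("classify", function() {
    mem <- degradome_membership(state$expr, config$degradome_target,
                                config$degradome_refs)
    state$membership <- mem
    f1 <- file.path(outdir, "degradome_membership.tsv")
    .write_tsv(data.frame(gene_id = state$expr$genes,
                          in_degradome = state$expr$genes %in% mem$degradome,
                          in_specific = state$expr$genes %in% mem$specific),
               f1)
    z <- row_zscore(state$expr)
    f2 <- file.path(outdir, "row_zscores.tsv")
    .write_tsv(data.frame(gene_id = rownames(z), z, check.names = FALSE), f2)
    caz <- if (!is.null(state$record$genes$role))
      state$record$genes$gene_id[state$record$genes$role %in% "CAZyme"]
    else state$expr$genes
    if (!length(caz)) caz <- state$expr$genes
    zc <- z[intersect(caz, rownames(z)), , drop = FALSE]
    state$groups <- cluster_and_label_groups(
      zc, n_clusters = min(7L, nrow(zc)), labeling = "cazyme_groups",
      expr = state$expr)
    f3 <- file.path(outdir, "cazyme_groups.tsv")
    .write_tsv(state$groups, f3)
    note("classify", "ok", nrow(state$groups), c(f1, f2, f3))
  })

  run_stage("regulons", function() {
    g <- state$record$genes
    out <- list()
    grpI <- if (!is.null(state$truth))
      names(state$truth$group_label)[state$truth$group_label == "I"]
    else state$groups$gene_id[state$groups$class_label == "I"]
    if (length(grpI)) {
      prof <- colMeans(state$expr$nta[grpI, , drop = FALSE])
      growth <- if (!is.null(state$truth)) state$truth$growth_rates else NULL
      if (!is.null(growth)) {
        rankable <- names(growth)[!duplicated(growth) &
                                    !duplicated(growth, fromLast = TRUE)]
        cc <- growth_anticorrelation(prof, growth,
                                     rankable_conditions = rankable)
        out$growth <- data.frame(stat = c("spearman_rho", "perm_p", "n"),
                                 value = c(cc$rho, cc$p, cc$n))
        f <- file.path(outdir, "growth_correlation.tsv")
        .write_tsv(out$growth, f)
      }
    }
    loci <- tcs_locus_scan(state$record)
    f2 <- file.path(outdir, "tcs_loci.tsv")
    .write_tsv(loci, f2)
    state$tcs <- loci
    note("regulons", "ok", nrow(loci), f2)
  })

  run_stage("motifscan", function() {
    sites_in <- if (!is.null(state$truth) &&
                    nrow(state$truth$planted_sites) >= 2L)
      state$truth$planted_sites$sequence else NULL
    if (is.null(sites_in)) {
      note("motifscan", "skipped: no aligned sites available", 0L)
      return(invisible())
    }
    pssm <- build_palindromic_pssm(sites_in)
    fm <- file.path(outdir, "operator_pssm.meme")
    write_meme_pssm(pssm, fm, name = "operator")
    up <- extract_regions(state$record, "upstream",
                          max_len = config$upstream_len)
    hits <- scan_regions(state$record, up, pssm, p_max = config$motif_p_max)
    mapped <- map_sites_to_genes(hits, state$record,
                                 window = config$upstream_len)
    f <- file.path(outdir, "motif_sites.tsv")
    .write_tsv(mapped$sites, f)
    state$motif_sites <- mapped$sites
    note("motifscan", "ok", nrow(mapped$sites), c(fm, f))
  })

  run_stage("kinetics", function() {
    kp <- if (!is.null(state$sim_cfg)) state$sim_cfg$kinetics_params
    else list(K = 6, r = 1, t0 = 5, noise_sd = 0.1)
    curve <- simulate_degradation_curve(kp, config$kinetics_timepoints,
                                        seed = config$seed)
    ## measured degraded mass cannot be negative; clamp noise excursions
    fit <- fit_sigmoid_extract(curve$day, pmax(curve$degraded, 0))
    f <- file.path(outdir, "kinetics_curve.tsv")
    .write_tsv(curve, f)
    f2 <- file.path(outdir, "kinetics_fit.tsv")
    .write_tsv(data.frame(param = c("K", "r", "t0", "peak_rate", "lag_time",
                                    "rss", "converged"),
                          value = c(fit$K, fit$r, fit$t0, fit$peak_rate,
                                    fit$lag_time, fit$rss,
                                    as.numeric(fit$converged))), f2)
    state$kinetics <- fit
    note("kinetics", "ok", nrow(curve), c(f, f2))
  })

  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
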