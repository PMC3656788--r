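# degradomeR

Multi-condition bacterial RNA-Seq analysis of the *cellulose degradome* —
the genome-wide set of genes a cellulolytic bacterium deploys to sense,
degrade and import plant polysaccharides. The package is written for
microbial transcriptomics researchers who profile a strain across carbon
sources (e.g. glucose, cellobiose, xylose, cellulose, xylan, a
lignocellulosic composite) and want a tested, reproducible implementation
of the full analysis chain, from per-base coverage to regulatory
inference.

## What it computes

* **Quantification.** Per-gene transcript abundance
  `TA_j = (sum of per-base unique-hit depths in gene j) / L_j`, normalised
  by the sample's average sequencing depth `ASD = total bases / genome
  length` to give the **normalised transcript abundance**
  `NTA_j = TA_j / ASD`. A gene is *expressed* when `NTA > 1` (strict).
* **Transcribed regions.** Coverage-based region calling, the **core**
  set (transcribed under every substrate, by interval intersection) and
  **condition-specific** regions (exactly one substrate, no overlap with
  any other substrate's transcription, mean depth strictly > 2), each with
  genomic context (CDS overlap / intergenic / putative 5'-UTR).
* **Consensus differential expression.** Three tests on the same counts —
  MA-plot random-sampling z (`M = log2(k1/N1) - log2(k2/N2)` against its
  binomial null variance), two-sided Fisher exact, binomial
  likelihood-ratio vs chi-squared(1) — combined with the ratio filter
  `|M| >= 2`, 0.01 NTA floors, and a p cutoff (presets 0.05 / 0.001).
* **Degradome classification.** Degradome and substrate-specific
  degradome membership, Row Z-scores, hierarchical expression classes
  (C1-C3), CAZyme groups I-IV (core CCR-regulated cellulosomal genes;
  substrate-specific accessory enzymes; composite-substrate cluster;
  remainder), and flat-table hypergeometric enrichment with
  representation ratios.
* **Regulon inference.** Squared Pearson correlations between expression
  profiles (cellulosomal co-expression, regulator-target linkage), the
  carbon-catabolite-repression signature (Spearman anti-correlation of
  expression with growth rate, exact permutation p), and two-component
  system locus scanning with category assignment (solute-binding protein
  inside the TCS operon / CAZyme inside / bare pair).
* **Operator motifs.** Palindromic PSSMs with the two central columns
  constrained to C,G; **exact** null score distributions by dynamic
  programming (survival function = scan p-value); region scanning at
  `P <= 1e-4`; site-to-gene assignment with translation-start offsets and
  dual-site separations. MEME-format serialisation.
* **Kinetics.** Logistic fits `D(t) = K / (1 + exp(-r (t - t0)))` of
  substrate-degradation curves with the analytic peak rate `r K / 4` and
  lag time `t0`.
* **Synthetic data.** A seeded generator producing a genome with operonic
  CAZyme clusters and TCS loci, group-structured expression across six
  substrates, per-base coverage from 36-base reads, planted palindromic
  operator sites, and sigmoidal degradation curves — with full ground
  truth, so every stage above is testable end to end.

## Worked example

```r
library(degradomeR)

cfg <- sim_config(seed = 1)            # six substrates, 200 genes, ASD 20x
sim <- simulate_genome(cfg)
sim$record
#> GenomeRecord 'synthetic_chromosome': 200000 bp (circular, synthetic)
#>   features: CDS=200

tracks <- lapply(cfg$conditions, function(cond)
  simulate_coverage(sim$record, sim$truth, cfg, cond))
names(tracks) <- cfg$conditions
expr <- compute_nta_table(tracks, sim$record)
round(expr$asd, 2)
#>   Glu   Ceb   Xyl   Cel   Xyn    CS
#> 19.99 19.84 20.39 20.00 19.89 20.58
```

The recovered sequencing depths match the configured 20x. Degradome
membership under cellulose against its soluble derivatives:

```r
mem <- degradome_membership(expr, "Cel", c("Glu", "Ceb"))
length(mem$degradome); length(mem$specific)
#> [1] 79
#> [1] 12
```

79 genes are transcribed (NTA > 1) under cellulose but only 12 pass the
specific-degradome test (>2-fold over glucose *and* cellobiose, p < 0.001
in all three tests) — the core cellulosomal genes are excluded because
they are equally active under glucose, which is exactly the CCR behaviour
the generator encodes. Grouping the CAZymes and testing the CCR
signature:

```r
caz <- subset(sim$record$genes, role == "CAZyme")$gene_id
grp <- cluster_and_label_groups(row_zscore(expr, genes = caz),
                                n_clusters = 7, labeling = "cazyme_groups",
                                expr = expr)
table(grp$class_label)
#>   I  II III  IV
#>  30  30  20  20

gI <- grp$gene_id[grp$class_label == "I"]
growth_anticorrelation(colMeans(expr$nta[gI, ]), sim$truth$growth_rates,
                       rankable_conditions = c("Ceb", "Xyl", "Xyn", "Cel"))
#> rho = -1, exact permutation p = 1/24 = 0.0417
```

Group-I (core) expression is perfectly anti-ranked with growth rate.
Operator-motif scanning over the upstream-sequence database:

```r
pssm <- build_palindromic_pssm(sim$truth$planted_sites$sequence)
pssm
#> Pssm: width 16, 24 sites, consensus AAGTTATCGTTAATTA (central C,G at 8,9)
up <- extract_regions(sim$record, "upstream", max_len = 500)
hits <- scan_regions(sim$record, up, pssm, p_max = 1e-4)
nrow(hits)
#> [1] 42                               # all 24 planted sites + near-palindromic echoes
```

Each hit carries its exact p-value, bits score and translation-start
offset (negative = upstream) after `map_sites_to_genes()`. Finally, a
degradation curve and its kinetic summary:

```r
cv <- simulate_degradation_curve(cfg$kinetics_params, 0:14, seed = 1)
fit_sigmoid_extract(cv$day, pmax(cv$degraded, 0))
#> SigmoidFit: K = 5.983 g/L, r = 0.970 /day, t0 = 5.03 day
#>             (peak rate 1.450 g/L/day, lag 5.03 day)
```

The one-call pipeline (`run_full(pipeline_config(seed = 1), outdir)`)
executes every stage, writes all intermediates as TSV/BED/GFF3/FASTA and
a JSON manifest, and is byte-identical on rerun with the same seed.

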