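---
title: "Methods: multi-condition RNA-Seq analysis of a bacterial cellulose degradome"
author: "degradomeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-condition RNA-Seq analysis of a bacterial cellulose degradome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomeR)
```

## The analysis this package implements

Cellulolytic clostridia such as *Clostridium cellulolyticum* degrade
crystalline cellulose with a cell-surface multi-enzyme complex (the
cellulosome) plus a portfolio of free carbohydrate-active enzymes (CAZymes).
Which of these genes a cell transcribes depends on the carbon source it
grows on. Comparing transcriptomes across a panel of substrates — a
monosaccharide (glucose), a disaccharide (cellobiose), pentose sugars
(xylose), and polymeric substrates (cellulose, xylan, a lignocellulosic
composite) — exposes two regulatory layers:

* a **carbon catabolite repression (CCR)** layer controlling the *core*
  cellulosomal genes, whose hallmark is expression anti-correlated with
  growth rate across substrates (fast growth on preferred sugars represses
  the cellulolytic machinery), read out through palindromic
  catabolite-responsive-element (*cre*) operators bound by LacI/CcpA-family
  dimers; and
* a **two-component system (TCS)** layer inducing *accessory* CAZymes and
  their sugar ABC transporters substrate-specifically, organised in genomic
  loci where sensor-kinase/response-regulator operons sit next to the
  CAZyme and transporter genes they control.

`degradomeR` re-implements this analysis as a tested pipeline: transcript
quantification and normalisation, transcribed-region calling, consensus
differential expression, expression-class and CAZyme-group assignment,
regulator-target correlation, operator-motif modelling and scanning, and
degradation-kinetics fitting — together with a seeded synthetic-data
generator that provides ground truth for every stage.

## Transcript quantification

The expression unit is the **normalised transcript abundance**. For gene
$j$ with per-base unique-hit depths $k_b$:

$$\mathrm{TA}_j = \frac{1}{L_j}\sum_{b \in j} k_b,
\qquad \mathrm{NTA}_j = \frac{\mathrm{TA}_j}{\mathrm{ASD}},
\qquad \mathrm{ASD} = \frac{\sum_{b=1}^{G} k_b}{G},$$

where $L_j$ is the gene length and $G$ the genome length. NTA is
scale-free: multiplying all depths by a constant changes TA and ASD equally.
A gene spanning the whole genome has NTA exactly 1, and a gene is called
*expressed* when NTA is **strictly** greater than 1. Gene bases are counted
strand-blind (the emulated libraries are unstranded 36-base single-end
reads), and bases shared by overlapping genes count fully toward each gene.
ASD is computed from the supplied track as-is; if rRNA-mapped reads should
be excluded, they must be removed from the track upstream.

## Transcribed regions: core vs condition-specific

`call_transcribed_regions()` returns maximal runs of bases with depth at
least `min_base_depth` (default 1), allowing internal gaps up to `max_gap`
(default 0) and discarding runs shorter than `min_length` (default 30,
about one read). These base-level thresholds are genuinely open choices —
no published criterion pins them — so they are configurable and the
defaults are deliberately minimal.

`classify_regions()` then forms:

* the **core** set: the interval intersection of the per-condition region
  sets (transcribed under every substrate); and
* the **condition-specific** set: regions called under exactly one
  substrate that (i) overlap no region transcribed under any other
  substrate (one shared base counts as overlap — the strictest reading)
  and (ii) have mean depth **strictly** greater than 2 in their substrate.

Each region receives a genomic context: `cds_overlap`, `putative_5utr`
(intergenic but inside the upstream window of a downstream gene, default
500 bases, suggesting an untranslated leader), or `intergenic`.

## Consensus differential expression

For two conditions with gene counts $k_1, k_2$ and library totals
$N_1, N_2$, `deg_tests()` computes three statistics on the same 2x2 table:

* the **MA-plot random-sampling z score**: with pooled proportion
  $\hat p = (k_1+k_2)/(N_1+N_2)$, $M = \log_2(k_1/N_1) - \log_2(k_2/N_2)$
  has approximate null variance
  $(1-\hat p)\left(\tfrac{1}{N_1\hat p}+\tfrac{1}{N_2\hat p}\right)/\ln^2 2$
  by the delta method; the two-sided normal p-value is reported;
* **Fisher's exact test**, two-sided by the minimum-likelihood convention
  (all tables with the observed margins whose probability does not exceed
  the observed one, with the same $1+10^{-7}$ relative tolerance
  `stats::fisher.test` uses);
* the **likelihood-ratio test** of pooled vs separate binomial
  proportions against $\chi^2_1$.

`consensus_deg()` applies the four filters in order: (1) $|M| \ge 2$;
(2) positive ratios whose numerator NTA is below 0.01 are ignored;
(3) negative ratios whose denominator NTA is below 0.01 are not selected;
(4) all three p-values at most the cutoff. Two cutoff presets are named:
`methods_default` (0.05) and `results_strict` (0.001) — both appear in
practice, at the filtering and the genome-wide reporting stage
respectively, so the cutoff is an explicit argument rather than a hidden
constant. When only NTA tables are available, counts are reconstructed as
$k = \mathrm{round}(\mathrm{TA}\cdot L_j)$,
$N = \mathrm{round}(\mathrm{ASD}\cdot G)$; this is a documented
approximation (it treats every uniquely mapped base as an independent
draw). Raw p-values are reported; a Benjamini-Hochberg column is available
in `enrichment_test()` but no multiplicity correction is imposed on the
DEG calls themselves.

## Degradome membership and classification

The **degradome** is the set of genes with NTA strictly above 1 under the
target polysaccharide. The **substrate-specific degradome** additionally
requires, against every reference substrate, an NTA ratio strictly above 2
and differential-expression significance below 0.001 — implemented as the
*maximum* of the three test p-values, i.e. all three methods must agree,
consistent with the consensus logic above.

Expression classes use **Row Z-scores**,
$z = (\mathrm{NTA} - \bar x_{\mathrm{row}})/s_{\mathrm{row}}$ (sample
standard deviation; zero-variance rows become all-zero and are flagged).
`cluster_and_label_groups()` performs agglomerative hierarchical clustering
— average linkage on $1 - r$ (Pearson) distance by default, with complete/
Ward linkage and Euclidean distance available — and cuts the tree into
`n_clusters`. Clusters are labelled either

* **by max condition** (classes C1, C2, ... in a configurable condition
  priority, default cellulose, cellobiose, glucose), with per-gene
  subclasses marking positive Z under a secondary condition; or
* by the **CAZyme group rules** on the cluster's mean Z profile:
  * Group I (CCR/core): every slow-growth condition above every
    preferred-sugar condition, with margin — implemented as
    $\min z_{\mathrm{high}} - \max z_{\mathrm{low}} \ge m/2$ and
    $\bar z_{\mathrm{high}} - \bar z_{\mathrm{low}} \ge m$ (margin $m$,
    default 0.5 Z units; the split guards against ties at the boundary);
  * Group III: composite-substrate dominant by at least $m$;
  * Group II: exactly one soluble/polymeric substrate dominant by at
    least $m$;
  * Group IV: the remainder.
  The rule order is I, III, II, IV; ties in max-condition labelling break
  by the configured condition order, so labels are deterministic and
  invariant to gene input order.

Functional enrichment is a plain hypergeometric upper tail on a flat
`gene -> term` table with BH adjustment and the representation ratio
$(k/n)/(K/N)$; the universe defaults to genes with at least one term, and
terms below `min_count` members (default 5; a preset of 20 reproduces the
drop-underpowered-classes convention) are skipped. No term-hierarchy
propagation is performed — parent terms must be materialised in the table.

## Regulon inference

`profile_r2()` reports squared Pearson correlations between per-condition
mean NTA profiles (or all gene pairs). Raw NTA is the default scale since
regulator-target scatter plots are conventionally drawn in NTA units; a
log-scale option exists. `growth_anticorrelation()` computes the CCR
signature — Spearman rank correlation between an expression profile and
growth rates — with an exact permutation p-value for up to 8 conditions
(one-sided "less" by default, since the hypothesis is anti-correlation);
conditions with tied growth rates can be excluded via
`rankable_conditions`.

`tcs_locus_scan()` finds adjacent same-strand sensor + regulator pairs,
expands them to operons by adjacency, strand and intergenic gap at most
100 bases (a documented heuristic, not a published rule), and assigns
locus categories: **I** if a solute-binding protein gene lies inside the
TCS operon (the "signal collector" architecture), **II** if a CAZyme does,
**III** otherwise. CAZyme and ABC-transporter genes within 5 genes on
either side (configurable) are reported as flank candidates for
co-regulation.

## Operator motifs

LacI/CcpA-family regulators bind palindromic operators whose central CG
dinucleotide is strongly conserved. `build_palindromic_pssm()` builds a
position probability matrix from aligned sites with pseudocount smoothing,
$(c + \alpha)/(n + 4\alpha)$, and **overrides the two central columns**
(1-based $\lfloor w/2\rfloor, \lfloor w/2\rfloor + 1$) so C and G carry
probability $1 - 3\varepsilon$ with
$\varepsilon = \alpha/(n + 4\alpha)$ — the constraint is part of the
model, not a post-hoc filter. Log-odds are $\log_2(p/b)$ against a
background that defaults to the scanned genome's mononucleotide
frequencies (uniform is available).

P-values are exact: `score_pvalue_table()` convolves the per-column score
distributions of an i.i.d. background word (dynamic programming over
scores discretised at 1/100 bit). At widths up to 8 the binning is fine
enough that the survival function matches full enumeration of all $4^w$
words to floating-point accuracy, and at widths 16-19 the discretisation
error is negligible relative to the $10^{-4}$ scan threshold.
`scan_sequences()`/`scan_regions()` report every window with
$P(\mathrm{score} \ge s) \le p_{\max}$ on both strands, skip windows
containing N, report perfect palindromes once with strand ".", and do not
mask overlapping hits. `map_sites_to_genes()` assigns each site to the
nearest downstream same-strand gene within a window and reports the offset
to the first base of the translation start (negative upstream, 0 at the
start) plus start-to-start separations of co-occurring sites — the
convention used to describe dual operators in one promoter region;
end-to-start distance is one flag away if preferred.

## Degradation kinetics

`fit_sigmoid_extract()` fits the 3-parameter logistic
$D(t) = K/(1+e^{-r(t-t_0)})$ by Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`; initialisation $K \leftarrow \max D$,
$t_0 \leftarrow$ half-max crossing, $r \leftarrow 4\cdot\max\Delta D/K$;
bounds $K, r > 0$). The **peak degradation rate** is the analytic
$rK/4$ at the inflection and the **lag time** is $t_0$ — the day the peak
rate is reached. A fixed zero baseline is the default because degraded
mass starts at zero; a 4-parameter floating-baseline variant is available.
Degenerate inputs (constant or all-zero series) and non-convergence are
flagged, never raised. An alternative lag definition (argmax of smoothed
finite differences) was considered and rejected: it is noisier and equals
$t_0$ in expectation for the logistic model.

## The synthetic-data generator

`simulate_genome()` emulates the study design: a circular chromosome
(default 200 kb, 200 genes, gaps 50-400 bp) containing a contiguous
13-gene Group-I cellulosomal cluster, a 14-gene Group-III hemicellulase
cluster, and three TCS loci realising the three locus categories (the
category-I locus is laid out as three transcription units: CAZyme, ABC
transporter triplet, TCS operon carrying the solute-binding protein). Six
conditions are simulated with growth ordering
Ceb > Xyl > Xyn > Cel = CS = Glu.

Key design choices, with rationale:

* **Effect size**: high and low expression states differ 8-fold
  (`high_fold`), with geometric intermediate steps tied to the growth
  ranking so the Group-I profile is rank-anti-correlated with growth by
  construction (Spearman $\rho = -1$ on the four distinctly ranked
  conditions, exact permutation $p = 1/24$). No published effect sizes
  exist for the group separation; 8x is a typical strong induction and is
  documented, not claimed.
* **True NTA normalisation**: per condition,
  $\sum_j L_j \cdot \mathrm{NTA}_j = G$ — the identity real NTA satisfies
  when all coverage is genic — with the non-CAZyme background genes
  absorbing between-condition imbalance so that cross-condition group
  structure (including exact ties) is preserved.
* **Group profiles**: Group II genes are high under exactly one of
  cellulose/cellobiose/xylose/xylan; Group III under the composite
  substrate only; Group IV under the monosaccharide only (a coherent
  "sugar-utilisation remainder" profile — a perfectly flat row would have
  no recoverable identity after Row Z-scoring); TCS operon genes are
  constitutive at 5% of the typical level, mirroring the low constitutive
  expression of the sensor operon relative to its induced targets.
* **Counts**: per-gene reads are negative binomial
  ($\mathrm{var} = \mu + \phi\mu^2$, $\phi$ = `dispersion`, default 0.01)
  rather than Poisson, for robustness of downstream tests to
  overdispersion. At the default depth (ASD 20x, ~900 reads per gene) the
  count coefficient of variation is
  $\sqrt{1/\mu + \phi} \approx 0.10$, which puts the median relative NTA
  recovery error just under 10%.
* **Reads**: 36 bases, start positions uniform within the gene, never
  spanning gene boundaries (a simplification; intergenic signal is
  controlled separately by `intergenic_leak`, default 0).
* **Motifs**: planted sites are drawn from the 16-nt consensus
  `AAGTTATCGTTAATTA` with per-position fidelity 0.85 and **at most 3
  substitutions** (operator sites in this family are described as
  consensus-like with up to 3 mismatches); the central CG is always
  exact. Default planting rate: 80% of Group-I genes.
* **Kinetics**: logistic truth $K = 6$ g/L, $r = 1$/day, $t_0 = 5$ day
  with Gaussian noise (0.1 g/L). Recovery studies fit three pooled
  replicate curves per run, matching how degradation curves are measured
  (three biological replicates); with a single 15-point curve the
  least-squares estimator already attains the Cramér-Rao bound
  ($\mathrm{sd}(\hat r) \approx 0.039$ at this noise), so a 95%-within-5%
  recovery target is only reachable with replicated data.
* **Determinism**: one seeded stream per public operation, derived from
  the master seed and an operation tag; seeds are recorded in output
  headers.

What the generator does **not** emulate: sequencing errors and quality
trimming, mappability artefacts, rRNA contamination, operon-level
transcription units spanning genes, 5'-UTR read-through (reads stop at
gene boundaries), strand-specific libraries, and biological replicate
structure for the expression matrix. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artefact of real libraries.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: a 200 kb / 200-gene
genome at ASD 20x for recovery and scan studies; 10 kb genomes for exact
brute-force oracles; 10,000 simulated null genes at library size $10^6$
(expected count 100) for test calibration; twenty 20 kb i.i.d. genomes for
motif false-positive calibration; 100 seeded three-replicate curves for
kinetics recovery; and a 160 kb / 150-gene end-to-end run executed twice
to verify byte-identical reproduction. These sizes were chosen so each
study estimates its quantity with comfortable Monte-Carlo margin while the
whole suite stays interactive on a laptop.

Numerical conventions worth knowing: strict inequalities at every
published threshold (NTA > 1, ratio > 2, depth > 2); expression ratios and
floors evaluated on NTA, test statistics on counts; score discretisation
at 1/100 bit; correlation distance treats zero-variance profiles as
maximally distant; undefined statistics (both counts zero, constant
profiles, all-tied growth) are flagged in the output rather than raised.

## Limitations

Genome-wide census quantities for the real organism (fraction of the
genome transcribed, region counts, DEG totals) require the underlying raw
sequencing reads, which are not publicly retrievable; those quantities are
therefore exercised on synthetic data only. The GenBank reader covers the flat-file subset
needed for bacterial records (simple and complement locations; multi-part
locations collapse to their span). Operon inference is a gap-and-strand
heuristic, not a transcription-unit model, and the enrichment module works
on flat term tables without ontology-graph propagation.
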