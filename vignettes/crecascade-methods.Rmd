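---
title: "Methods: screen simulation, pseudobulk NB testing, and enhancer prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen simulation, pseudobulk NB testing, and enhancer prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crecascade` analyzes paired CRISPRi screens in primary CD4+ T cells: a
targeted (TAP-seq style) CRE screen that reads a candidate gene panel per
perturbed CRE, and a genome-wide promoter screen that reads the whole
transcriptome. This vignette documents the statistical model, the synthetic
data generator that stands in for raw screen data, the parameter choices,
and the numerical details a maintainer would want to know.

# The count model and its assumptions

Counts for cell $i$ and gene $g$ are negative binomial,

$$y_{ig} \sim \mathrm{NB}\!\left(\mu_{ig},\ \alpha_g\right),\qquad
\mu_{ig} = s_i\, d(\mathrm{donor}_i, g)\, q_g\, 2^{\beta(t_i, g)},$$

where $s_i$ is a lognormal library-size factor (CV 0.3 by default), $d$ a
gene-wise lognormal donor multiplier (sdlog 0.15, three donors), $q_g$ the
baseline mean, $\beta(t_i,g)$ the log2 effect of cell $i$'s perturbation
target on gene $g$, and $\alpha_g$ a gene-wise dispersion (uniform on
[0.2, 0.8] in the generator). Donor is the only batch axis modeled; the DE
design absorbs it exactly because fits are gene-wise. Assumptions worth
stating: effects are multiplicative and cell-autonomous, gRNAs of one
target share one effect (an optional per-gRNA activity flag relaxes this),
and there is no ambient RNA, doublet structure, or cell-state covariance —
passing tests on this generator therefore says nothing about those
real-data artifacts.

# Differential expression on pseudobulks

Cells are summed into (perturbation × donor) columns; groups under 10 cells
are dropped. Size factors are DESeq-style median-of-ratios over genes with
all-positive counts (library-size ratios as a flagged fallback), rescaled to
geometric mean one. Per gene and perturbation we fit an NB log-link GLM on
`perturbation + donor` with log size-factor offsets against the pooled
non-targeting columns, and read a two-sided Wald p from the perturbation
coefficient. BH correction is applied per perturbation across its tested
genes (panel genes in CRE mode; top-N variable genes, default scaled to the
run size, in promoter mode), with failed fits excluded from the BH
denominator. The default significance gate is FDR 0.1 with no |log2FC|
threshold at link calling.

Two numerical choices matter for calibration:

- **Cell-count-aware variance.** A pseudobulk column summing $n_c$ cells of
  cell-level dispersion $\alpha$ has variance $\mu + (\alpha/n_c)\mu^2$.
  Using a single column-level dispersion underestimates the variance of
  small perturbation groups relative to a large control pool and visibly
  inflates the null (we measured raw $p<.05$ fractions near 0.10). The IRLS
  fitter therefore uses the column-specific variance function; with it, the
  null fraction sits at 0.05.
- **Dataset-wide dispersion.** $\alpha_g$ is estimated once per gene across
  *all* pseudobulk columns under the full `donor + perturbation` design
  (every perturbation absorbed by its own coefficient), by Pearson-χ²
  matching: $\alpha$ solves $\sum_c (y_c-\hat\mu_c)^2 / (\hat\mu_c +
  (\alpha/n_c)\hat\mu_c^2) = \mathrm{df}$, bisected on $[0, 50]$ with a
  Poisson pilot fit supplying $\hat\mu$. This yields tens of residual df per
  gene instead of the 2 available within one contrast. The estimate is then
  shrunk toward a robustly fitted trend $\alpha(\mu) = a_0 + a_1/\mu$
  (weighted average, trend weight 0.75 by default; outliers beyond 10× the
  trend are dropped and the trend refit once). Dispersions are clamped to
  $[10^{-8}, 50]$; trend coefficients to be nonnegative.

IRLS runs to a $10^{-9}$ relative coefficient tolerance with a 50-iteration
cap and $\eta$ clamped to $\pm 30$; non-convergence flags the gene with
`p = NA`. With dispersion forced to zero the Wald statistic reproduces the
Poisson GLM, and on matched inputs estimates track DESeq2 closely (r > 0.98
in the cross-check test) — DESeq2 is used only as an independent reference,
never as the implementation.

# Classification and enhancer prioritization

All internal coordinates are 0-based half-open; 1-based inclusive inputs are
converted at the I/O boundary only, which keeps the 1.5 kb proximity rule
free of off-by-one ambiguity. A CRE is *promoter* context if its interval
overlaps any TSS ± 1,500 bp; else *intragenic* if its center lies in a gene
body; else *intergenic* (precedence resolves overlaps). Distance is unsigned,
from the CRE center to the nearest annotated TSS of the paired gene; strand
enters only when a TSS must be inferred (body start on +, last base on −).
A target under 1,500 bp away is *proximal*. Because any CRE that close to a
TSS is promoter context by construction, intergenic-proximal cannot occur
and exactly five classes partition the same-chromosome links.

Link calling excludes control-promoter perturbations and cross-chromosome
associations from the cis set (kept in an audit table with reasons), then
the enhancer refinement applies, in order: significance, distal position,
the proximal-mediation filter (a CRE with *any* significant proximal link
has all of its distal links removed), and a hard 1 Mb distance cut
(configurable off) motivated by the empirical indistinguishability of
longer-range candidates from non-significant elements. Negative log2FC
under CRISPRi labels an enhancer, positive a silencer. Chromatin signals
are reported descriptively per distance bin (half-open bins at 1.5 kb,
10 kb, 100 kb, 1 Mb, with only the closest-TSS link per CRE entering bin
summaries) rather than used as hard filters; optional thresholds can be
layered on via the prioritized table. Hi-C evidence is distance-matched by
bin identity — deterministic and faithful to a binned presentation — with a
two-sided rank-sum test per bin; TAD co-localization (no boundary strictly
between CRE center and TSS) is tested with Fisher's exact test on the 2×2
of significance × same-TAD.

The mediation filter removes only *proximally* mediated effects. A distal
effect mediated through another distal target is undetectable by this rule;
the synthetic decoys used in the acceptance experiment are therefore
planted exclusively on promoter-context CREs, which is also the regime the
filter is designed for.

# Enrichment layer

All 2×2 statistics share one code path: exact conditional p-values from the
hypergeometric distribution on the *uncorrected* table, and a cross-ratio
odds ratio with a flagged Haldane–Anscombe +0.5 correction only when a cell
is zero (finite log ORs are needed downstream). The eQTL universe defaults
to tested pairs predicted by at least one source — the a-priori prioritized
set — since untested or unpredictable pairs carry no information about the
catalogs; `universe = NULL` uses all tested pairs, and ORs are not
distance-stratified by default (a per-bin view can be assembled from the
prioritized table). TF-target enrichment keeps TFs with ≥ 50 annotated
targets and ≥ 5 DEGs (adjusted p < 0.1, |log2FC| > 0.5), tests one-sided,
and splits DEG-targets into concordant / discordant / unsigned by comparing
the observed sign against the annotated direction with the knockdown sign
convention (silencing an activating TF should lower its targets). Gene-set
tests are upper-tail hypergeometric with BH across sets, enriched at
adjusted p < 0.05; no GO-DAG structure is modeled.

# Cascades and disease programs

Hop-1 edges are the promoter-screen DEGs of CRE target genes, hop-2 the
DEGs of hop-1 genes, with self-edges removed and layer membership assigned
at first reach (BFS semantics); edges that point back into earlier layers
stay in the edge list. Two published gates are both legitimate — adjusted
p < 0.1 with |log2FC| ≥ 0.2 for the sparse map and ≥ 0.1 for dense views —
so the gate is an explicit parameter with 0.2 the default. Top-k truncation
per source (e.g. 20) exists for plot exports and is off in analysis mode.
Disease programs aggregate CRE targets and hop-1 genes per disease label;
hop 2 is excluded from programs by default (it feeds the cascade map only),
a reading that keeps programs local to directly attributable regulation. A
term is *shared* when enriched in more than `min_shared` (default 5)
diseases and *unique* when enriched in exactly one.

# What the generator emulates, and the sizes used

The generator plants: ~1.6 direct target genes per CRE with a 27% silencer
(upregulated) fraction; weak enhancer effects (|log2FC| uniform on
[0.05, 0.3] — the screen's observable regime, with single examples near
−0.07); strong promoter knockdowns (1–2.5 log2 units); 8 gRNAs per CRE and
3 per gene; ~80% uniquely assigned cells with half of the remainder
doublets; an acyclic trans network (mean out-degree 1) whose one-hop
propagation scales edge effects by the fractional knockdown of the mediator;
TAD-tiled chromosomes with enhancer CREs placed inside their anchor's TAD
75% of the time; chromatin signals from class-conditional lognormals
(promoter-like H3K4me3-high; enhancer-like H3K27ac/H3K4me1-high,
H3K4me3-low) with hyperbolic distance decay; power-law Hi-C contacts
boosted within TADs and on true links; and eQTL catalogs / prediction
sources as true-link samples plus pair noise at catalog-specific rates.
Where the study conditions fix a number we use it; remaining rates are
one-time choices a practitioner would call realistic and are exposed in
`default_regulatory_params()`.

Problem sizes in the test suite and acceptance script are chosen as
desk-scale analogues of the study design: null calibration at 20
perturbations × 2,000 genes × ~400 cells per perturbation (three donors);
promoter recovery at log2FC −1 with the same cell counts; weak-enhancer
recovery at log2FC −0.15 with ~900 cells per CRE; the mediation experiment
at 50 CREs (half promoter-context) with decoys on 40% of them; and the
end-to-end run at ~20,000 cells × 2,000 genes across both screens. The
headline counts of the full-scale study (hundreds of cis links, millions of
cells) are functions of library size and cell number and are not
reproducible at these sizes; the tests therefore check operating
characteristics — calibration, power, bias, sign accuracy, oracle
equivalence — rather than any published tally.

# Known limitations

- Wald tests with plug-in dispersion; no likelihood-ratio or exact NB test,
  and no empirical-Bayes posterior shrinkage of effect sizes.
- The mediation filter is all-or-none per CRE and blind to distal-mediated
  chains (see above); CRISPRi spreading and transcriptional roadblocks are
  handled only through it and the class exclusions, not modeled.
- Hi-C contacts are consumed pre-normalized; no ICE/KR normalization, and
  matching is by distance-bin identity rather than nearest neighbor.
- The generator's donor effect is a static gene-wise multiplier; real donor
  variation includes composition and state shifts the design cannot absorb.
- Panels are single-batch: the library-panel pairing of a real TAP-seq
  design (and control pooling within pairs) collapses to one panel here,
  with controls pooled globally.
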