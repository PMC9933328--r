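---
title: "Models and methods in desiccatR"
author: "desiccatR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in desiccatR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

desiccatR implements the computational arms of a desiccation-tolerance study
design on natural fly populations: survival assays scored at periodic
checks, climate/environment association, ordered-gene-list (transcriptogram)
differential expression, PPI hub ranking, tRNA-fragment target prediction,
transposable-element proximity enrichment, and physiology plus
cuticular-hydrocarbon statistics. This vignette is the package's own account
of the models, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. The companion synthetic
generators define a study-shaped world with known truth; every claim below
about recovery or calibration is the one the test suite and
`scripts/acceptance.R` actually compute.

## Survival: interval-censored probit lethal times

Mortality is recorded as cumulative deaths at checkpoint times (every 4 h
until hour 12, then shorter intervals). The canonical estimator treats the
data exactly as collected: with linear predictor
$\eta(t) = a + b \log_{10} t$, the newly dead in $(t_{k-1}, t_k]$ are
multinomial with probability $\Phi(\eta(t_k)) - \Phi(\eta(t_{k-1}))$ and a
right-censored cell for survivors past the last check. The MLE is found by
BFGS from Finney-style starting values; $\mathrm{LT}_{50} = 10^{-a/b}$ and
its standard error follows by the delta method from the observed
information. Design notes:

* **Log10 time.** Time enters the predictor on the log10 scale, the
  standard probit-analysis convention for lethal-time data; the slope `b`
  has units of probits per log10 hour.
* **Pooling.** Replicates are pooled within strain for the headline LT50
  (one estimate per strain); `pool = FALSE` returns per-replicate fits for
  diagnostics, because which pooling the classic Probit programs used is
  ambiguous. `mode = "finney"` provides the textbook cumulative-proportion
  regression (unweighted, with 1/(2n) clipping) as a documented
  compatibility mode.
* **Non-identifiability is loud.** Zero deaths, or complete mortality at
  the first check, yields `converged = FALSE` and `NA` estimates with a
  warning — never a silently extrapolated number.
* **LT100 is empirical**, the mean over replicates of the first check at
  which every assayed fly is dead; a single censored replicate makes it
  undefined. This matches the attrition pattern of real assays, where a
  few retained strains never complete mortality before monitoring ends.
* **Exclusion rule.** A strain is dropped when pooled control mortality is
  strictly above 10% (a control at exactly 10% is retained), or when it has
  no control data at all; injured flies (dead before the first check) are
  removed from all denominators. The operation is idempotent.

Environment association follows the field's standard sequence — Shapiro–Wilk
first, then one-way ANOVA by climate zone with Tukey HSD (singleton zones
excluded with a warning), Spearman rank correlation (one-tailed by default),
VIF pruning of collinear covariates (drop the largest VIF while any is at or
above 5; ties broken by column order; a perfectly collinear column is
reported as infinite and removed first), and OLS with an
altitude × evaporation interaction.

## Transcriptogram: windowed differential expression on an ordered gene list

The transcriptogram idea is that genes whose products interact sit near each
other on a one-dimensional order, so window averages of expression measure
the activity of functional neighbourhoods. The pipeline:

1. **Filter** genes at CPM > 0.5 in at least *k* samples (*k* = smallest
   group size).
2. **Normalise** with TMM (via edgeR, as practitioners do; an independently
   coded textbook TMM is the cross-check in the test suite), then take
   log2(CPM + 0.5).
3. **Order** genes by simulated annealing on the PPI graph, minimising the
   quadratic edge-length cost with pairwise swaps and geometric cooling.
   The accepted radii are 50, 80 and 125; **125 is the default**, and
   windows truncate at the list ends because the order is linear, not
   circular.
4. **Test** each position with a two-sample Welch t on the smoothed
   replicate profiles, BH-adjusted across positions at q < 0.01, and call
   maximal runs of significant positions as clusters (member genes are the
   window centres; direction is the majority sign).

Two choices deserve explanation:

* **Median-of-differences centering** (`centerProfiles = TRUE`). When most
  regulated genes move in one direction (stress responses are often
  predominantly down), the composition shift drags library scaling: the
  trimmed mean under-corrects because the regulated minority contaminates
  the asymmetric trim, and the log(CPM + 0.5) offset makes the residual
  depth effect slightly expression-dependent. Window averaging then has so
  little noise that this residual offset would dominate the test. We
  therefore estimate the between-group profile offset as an iteratively
  trimmed median of the per-position group difference — valid exactly when
  most windows are unchanged — and subtract it from the test group.
* **Unpaired by default.** A paired (within-strain) contrast is available
  (`paired = TRUE` on strain means), but with three strains per phenotype
  the paired t has two degrees of freedom, whose heavy tails make BH at
  q < 0.01 across thousands of positions unstable; the Welch test across
  replicate profiles is the default.

Cluster-gene membership uses window centres only (not every gene covered by
any significant window); the per-window statistic is a plain Welch t rather
than the original tool's moderated statistic — a documented variance-model
substitution. Enrichment is plain hypergeometric over-representation with BH
(q < 0.005 for gene sets) or Bonferroni (α = 0.001 across tissues, with
"highly expressed" meaning RPKM strictly above 51).

## Hubs: maximal clique centrality

On the PPI graph filtered at combined score ≥ 800 (scores stay on the
0–1000 integer scale to avoid float thresholds),
$\mathrm{MCC}(v) = \sum_{C \ni v}(|C|-1)!$ over maximal cliques; an
isolated node contributes $0! = 1$. Hubs are the top 30% by MCC with a
ceiling count and a deterministic tie-break by node id. Clique enumeration
is delegated to igraph's Bron–Kerbosch implementation; the test suite
checks exact agreement with exhaustive subset enumeration on graphs of up
to 12 nodes. Whether the 30% applies to all network nodes or only to DEG
nodes is ambiguous in the field's usage, so `hubDegs()` provides both.

## tRFs: seed-anchored duplex energy and differential targeting

Fragments of mature tRNAs are classified by position: `five_prime` starts
at the 5′ end, `cca` ends at the 3′ end including the post-transcriptional
CCA, `three_prime` ends exactly 3 nt before it; anything else is internal
and excluded. Only the 5′ class enters target prediction by default, with
the first 12 nt as the seed query.

`duplexMFE()` is an intermolecular hybridisation dynamic program:
antiparallel duplexes over Watson–Crick and GU pairs, nearest-neighbour
stack energies, bulges and internal loops capped at one nucleotide per
side, no intramolecular structure, and a single best site per
(query, target). The parameter set is pinned and shipped as a plain-text
versioned file (`extdata/duplex_stacks_v1.tsv`): Turner-2004-derived stacks,
duplex initiation +4.09 kcal/mol, terminal AU/GU penalty +0.45 per helix
end, bulge-1 penalty +3.81 with the flanking stack retained, and a constant
+1.50 for 1×1 loops. The tandem-GU entries are approximate constants kept
self-consistent under strand-flip symmetry; pinning the table is what makes
energies reproducible, which matters more here than decimal fidelity to any
particular published table.

The stringent −30 kcal/mol cutoff is the default for reported hits, with
−20 as the explored compatibility mode. A genuine tension is documented
here: a 12-nt query can only reach −30 kcal/mol for extreme G-rich
sequences under any nearest-neighbour table, so analyses that report
12-nt-seed hits at −30 must have benefited from flanking context. The
synthetic-world recovery analyses therefore run at the −20 mode.

A transcript is *targeted* in a (phenotype, condition) state when it has a
predicted site and the summed reads of its hitting fragments are at least
10 in **every** replicate of that state (a per-fragment alternative mode is
provided). Gain = targeted under stress only; loss = targeted under control
only; the two sets are disjoint by construction and swap exactly when the
condition labels swap.

## TE proximity

Coordinates are 0-based half-open on disk (BED) and 1-based closed
internally (GRanges). The distance between non-overlapping intervals is the
gap length, 0 for overlap or book-ended neighbours, signed negative when
the TE is upstream on the reference strand (strand is ignored for
proximity). "Within 1 kb" means gap ≤ 1000 inclusive — the convention of
the standard interval tools. TEs shorter than 120 bp are discarded before
anything else. The DEG-status × TE-proximity 2×2 table is tested by Pearson
chi-square without continuity correction (df = 1; correction available),
and per-cell standardized residuals
$Z = (O-E)/\sqrt{E(1-p_{row})(1-p_{col})}$ get two-sided normal p-values
with Bonferroni correction over the 4 cells — the implied critical |Z| at
α = 0.05 is 2.497705.

## Physiology and cuticular hydrocarbons

Water content is wet − dry mass (fraction of wet mass); water loss is
expressed relative to the group-mean water fraction because content and
loss are measured on different flies (a per-fly total-mass denominator is
the alternative mode). Group comparisons use the rank-sum (Mann–Whitney)
form of the Wilcoxon test — the groups are independent strains — with exact
enumeration for small untied samples; a paired signed-rank mode exists.

Respiration is modelled on the stable window of readings (minutes 60–119 by
default; flies need about an hour to settle) with nested linear mixed
models fit by ML (not REML): random intercepts for strain and for replicate
within strain, and fixed condition, phenotype and (in the full model) their
interaction. The LRT is $2\Delta\log L$ on 1 df. Singular random-effect
fits are recorded, not errors. One caution the package's own calibration
exposed: the adaptive ML Yeo–Johnson transform, applied to data that are
already normal, can bend additive group effects into spurious interaction
(null rejection far above nominal); the transform is for genuinely skewed
respirometry traces, and the LRT's null calibration is checked on the
untransformed scale.

CHC peaks are quantified against the internal standard (200 ng tridecane —
20 µl at 10 ng/µl — per 5-fly sample, so a compound with the IS's area is
40 ng/insect), indexed by linear interpolation on a C7–C30 alkane ladder
(the Cn alkane indexes exactly 100n), summarised by the balance ratio
$(D-S)/(D+S)$ over desaturated and saturated amounts, and ordinated by PCA
of log-transformed composition (the zero offset is half the smallest
positive value unless given; constant compounds are dropped with a
warning).

## The synthetic world: what it emulates and what it does not

All generators draw from named child streams of one root seed
(`childSeed(seed, stream)`), so adding a generator never perturbs another's
draws, and identical configurations give identical output. Defaults encode
the study conditions: 74 strains, 15 flies × 3 replicates, checks every 4 h
to hour 12 then every 2 h, true LT50 uniform on 12–30 h, probit slope 6 per
log10 hour; an RNA-seq design of 3 tolerant + 3 sensitive strains × 2
conditions × 3 replicates with 10% DE genes at |log2FC| = 2, 90% down;
water fractions 0.45 vs 0.50 and loss fractions 0.10 vs 0.15; a C7–C30
ladder with 13 compound peaks at the chain lengths (C23–C29) seen in fly
cuticle profiles.

Deliberate structure worth knowing about:

* Planted DE genes occupy **contiguous blocks** of the gene order — the
  premise of the ordered-list method is that co-responding functional
  modules are neighbours. Replicate-level biological noise includes a
  log-normal activity factor shared by 50-gene co-expression modules;
  without it, window-averaged profiles would be unrealistically
  noise-free and any residual normalisation bias would masquerade as
  signal. Recovery is scored at the resolution the statistic has:
  sensitivity is gene-level (planted genes at significant positions), while
  a false discovery is a called position whose window contains no planted
  gene; because an FDR is an expected proportion, it is averaged over
  generator seeds.
* Planted tRF seeds are rejection-sampled to form stable perfect duplexes
  (≤ −25 kcal/mol), and decoy transcripts are rejection-sampled to contain
  no non-planted site at the −20 threshold, so the planted
  differential-targeting truth is exactly recoverable at any seed from
  noiseless counts.
* TE placement picks a host gene uniformly and lands near it with a
  probability scaled by the enrichment factor for DE-labelled genes;
  factor 1 gives exact independence (the chi-square null), and genes are
  spaced so that a "far" placement is genuinely more than 1 kb from every
  gene.
* The generators do **not** simulate raw reads, alignment artifacts,
  GC-MS spectra, batch effects, or strain-specific genome sequence. Passing
  recovery tests therefore demonstrates the correctness of the estimators
  under the stated statistical structure, not robustness to upstream
  processing errors in real data.

## Problem sizes and numerical choices

The shipped checks use desk-scale worlds chosen to exercise every code
path: 2000-gene expression matrices, 1000-gene TE genomes, 10 tRNAs × 20
transcripts, 20 strains × 100 flies for LT50 recovery (50 simulations), 500
null simulations for the chi-square and LRT calibrations and 1000 for the
rank test. Optimiser details: BFGS with Finney starting values for the
probit; a 51-point grid with golden-section refinement for the Yeo–Johnson
lambda; geometric cooling with pairwise swaps for the annealer (the
returned order never costs more than the initial one, and `nSteps = 0`
returns the input order). Probability cells are floored at 1e-12 inside the
probit likelihood; BH and Bonferroni adjustments are capped at 1.

## Known limitations

* The duplex energy model omits dangling ends, coaxial stacking, longer
  loops and intramolecular structure; energies are comparable within this
  package, not against other tools' absolute values.
* The annealing order is a heuristic; only for structured graphs (paths,
  disjoint cliques) is the global optimum known and asserted.
* The mixed-model LRT uses the asymptotic chi-square reference; with few
  strains its fixed-effect inference is approximate (the package's own
  null calibration bounds the error at the shipped design sizes).
* DAVID-style composite enrichment scores, STRING/GO retrieval, TE
  annotation itself, read alignment, and GC-MS deconvolution are out of
  scope; inputs enter as tables, sequences and interval sets.
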