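---
title: "Reading bone-marrow activity from cell-free mRNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading bone-marrow activity from cell-free mRNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmarrow)
library(SummarizedExperiment)
```

# The problem

Plasma carries messenger RNA released by cells throughout the body,
including cells that never enter circulation — most notably the
hematopoietic progenitors resident in bone marrow. Sequencing this
cell-free mRNA (cf-mRNA) therefore offers a window on marrow activity
without a biopsy: marrow ablation, transplant engraftment and lineage
reconstitution all leave signatures in the circulating transcriptome.
`cfmarrow` implements the computational machinery for this readout:

* **signatures** — which genes are specific to which tissue or cell type,
  derived from reference expression atlases;
* **deconvolution** — what mixture of cell types explains a bulk cf-mRNA
  profile, by unsupervised factorization and by constrained regression;
* **timecourse** — how lineage-specific transcripts move through ablation
  and reconstitution;
* **repertoire** — whether one immunoglobulin clonotype dominates the Ig
  transcript pool (the signature of a malignant plasma-cell clone) and
  when that dominance is lost after therapy;
* **chimerism** — how allele frequencies of expressed SNPs shift from the
  host's genotype to the donor's after an allogeneic transplant;
* **compare** — paired-compartment contrasts (cf-mRNA against whole blood
  or buffy coat) with rank-sum inference.

Every module is exercised end to end on synthetic data with known ground
truth, generated by the package itself.

# Cell-type signatures

A gene is called **specific** to an entity (tissue or cell type) when its
expression there strictly exceeds a fold threshold times its expression in
every other entity of the reference — equivalently, times the runner-up.
The conventional threshold is 20-fold. Two design choices close gaps the
rule alone leaves open:

* `minTopExpression` (default 1 TPM) — an expression floor; without it,
  genes at trace levels everywhere produce unstable calls. Set it to 0 for
  the bare rule.
* Ties for the top entity yield no call: the rule requires a unique top.

The strict comparison is evaluated in product form (`top > threshold *
runnerUp`) rather than as a ratio. The two are mathematically identical,
but the product form is exact at constructed fold boundaries where the
floating-point ratio `(20 * x) / x` can land a few ulps above 20.

Pairwise **enrichment** between two transcriptomes (e.g. bone marrow vs
whole blood) uses the same strict logic at a 5-fold default, with a
pseudocount (default 0.1 TPM) keeping ratios defined at zero denominators;
pseudocount 0 reproduces the strict behavior with infinite folds.

# Deconvolution

## Constrained least squares

Given an entity-by-gene signature matrix $S$ restricted to specific genes
and a sample vector $x$ (TPM over those genes), tissue fractions solve

$$\min_p \; \lVert x - S^\top p \rVert^2 \quad \text{s.t.}\; p \ge 0,\;
\textstyle\sum_i p_i = 1 .$$

Because TPM renormalization fixes each sample's column sum at $10^6$
regardless of the signature's row scales, the raw problem is not
scale-consistent. The solver is therefore scale-free: an unconstrained
non-negative least-squares pass (Lawson–Hanson, via `pracma::lsqnonneg`)
estimates the sample's scale on the signature; the sample is rescaled; the
simplex constraint is then enforced through an augmented all-ones row
weighted at $10^3$ times the mean signature magnitude; and the result is
renormalized to sum exactly 1. On noiseless consistent mixtures this
recovers the generating proportions to machine precision, and it is
invariant to jointly rescaling sample and signature. Rank-deficient
signatures (collinear entities) are flagged with a warning and solved
with a tiny ridge ($10^{-5}$ relative) so the active-set solver stays
away from singular subproblems; the returned estimate is then one of the
non-unique minimizers. By default only signature genes detected in the
sample (> 0 TPM) enter the fit.

## NMF

The unsupervised route max-normalizes each retained gene (genes below 20
TPM in all samples are dropped; each row is divided by its maximum, so
factorization sees shape, not level) and factorizes the result into
non-negative loadings and activities. Design choices:

* **Updates**: HALS (hierarchical alternating least squares) — each
  factor column is an exact coordinate minimizer, so the Frobenius
  objective is non-increasing per sweep; this is asserted in the tests on
  every run. Sweeps are wrapped in objective-guarded extrapolation:
  a momentum step is accepted only if it further decreases the objective,
  preserving monotonicity while cutting the iteration count severalfold
  on slowly converging (ill-conditioned) problems.
* **Initialization**: deterministic NNDSVD (non-negative double SVD),
  with its structural zeros filled by small seeded uniform draws so
  multiplicative structure cannot pin them at zero. Identical seeds give
  bitwise-identical decompositions.
* **Stopping**: `maxIter = 30000` sweeps (each costs a few matrix
  products of size genes x samples x rank, well under a millisecond at
  the scales used here), a relative objective-change tolerance of
  `1e-12`, and a relative-residual floor of `1e-7` at which iteration
  stops early. Exact low-rank inputs converge to that floor; noisy inputs
  stop on the change tolerance. Non-convergence sets a flag rather than
  erroring.
* **Rank**: decompositions of whole transcriptomes conventionally use
  8–12 components. `nmfSelectRank()` chooses within a candidate set by
  holding out a random 10% of matrix entries, fitting a masked
  (weighted multiplicative-update) NMF on the rest, and scoring held-out
  squared error.

Components are annotated by majority vote of their top-loading genes
(default: top 25; label assigned when one entity holds a strict plurality
above half of them; the per-component vote tables are kept as evidence).
Per-sample contributions push each loading column's mass into the
activities, normalize within sample, and aggregate by annotation label —
so contributions sum to 1 per sample by construction.

# Time courses

Genes enter the temporal analysis when their maximum across time points
exceeds 50 TPM and their max/min ratio exceeds 5. The ratio uses a 1-TPM
pseudocount by default so it stays finite at zero minima (pseudocount 0
restores the bare rule). Selected genes are max-normalized and clustered
by seeded k-means (default k = 8, best of 10 restarts) or hierarchical
clustering (Euclidean distance, average linkage, tree cut at the same k);
the field's practice names no k, so it is an explicit parameter.

`lineageTrajectory()` summarizes a lineage gene set as the per-gene ratio
to its value at a reference day, averaged across genes per day.
Choices made where convention is silent: the average is the arithmetic
mean of per-gene ratios (a geometric option is provided); genes undetected
at the reference day are excluded and reported (or given pseudocount 1 on
request); an optional TPM cap (preset 5000) excludes very abundant genes
the way trajectory figures conventionally do.

The synthetic time course models lineage activity as a pre-ablation
plateau, log-linear decay from the ablation day to a nadir at the
recovery-start day, then exponential recovery capped at the pre-ablation
level. A nadir of exactly 0 is absorbing — there is no exponential path
out of 0 — so complete ablation with recovery should use a small positive
nadir. These shapes reproduce the qualitative behavior of
ablation/reconstitution transcript panels (collapse after conditioning,
recovery preceding blood-count recovery) with five parameters per lineage.

# Immunoglobulin repertoire

Relative abundance of an Ig segment is its read count over the total Ig
reads in scope. The default scope is per class (heavy-variable separate
from kappa-variable, and so on), matching how repertoire panels are
normalized; an all-Ig scope is available. A segment is **dominant** when
its fraction strictly exceeds 0.5 *or* exceeds 5 times the second-ranked
segment of its class, provided the class has at least 100 reads — the
last guard prevents dominance calls from shot noise. No published
formalization of "dominant" exists for this assay, so both triggers are
explicit parameters and each call records which trigger fired.
`trackClone()` reports the loss-of-dominance day as the first observed
day after which dominance never recurs.

The synthetic Ig generator is a symmetric-share multinomial: a planted
clone receives fraction $c$ of expected reads, and the remainder is
shared uniformly by *all* segments — so at $c = 0$ the clone segments are
indistinguishable from background, with expected relative abundance
$1/n_\text{segments}$. Ground truth records the resulting effective clone
fraction $c + (1 - c)\,n_\text{clone}/n_\text{segments}$.

# Chimerism

Reference-allele frequency at an expressed SNP is `ref / (ref + alt)`;
zero-depth entries are `NA`, flagged, never imputed. Genotypes are called
hom-ref at frequency ≥ 0.9, hom-alt at ≤ 0.1, het between, and ambiguous
below 10 reads. These thresholds are package choices (no published
calling rule exists for this assay); at depth 30 with a 1% per-read
miscall rate the exact binomial miscall probability is
$2.2\times10^{-4}$ per homozygote draw and $8\times10^{-6}$ per het draw,
i.e. calling is near-error-free at routine depths. A $10^{-9}$ tolerance
at both thresholds keeps the two homozygote bands exact mirror images
despite floating-point rounding of `1 - 0.9`, which the ref/alt swap
symmetry of the module requires.

Transitions are labelled per SNP from the pre-transplant consensus
(majority over informative pre-transplant days; ties ambiguous) to the
post-transplant consensus, defined as the terminal stable call — the
genotype held from some day through the end of the series for at least 2
consecutive informative days. The persistence requirement suppresses
single-day flips at variable cf-mRNA depth, and anchoring on the terminal
run tolerates the legitimate intermediate calls seen while the donor
fraction ramps (a hom-ref to hom-alt replacement passes through a het
band). The transition day is the first day of that terminal run.
Averaged trajectories over SNPs sharing a label are arithmetic means with
standard errors, with uninformative days flagged.

The generator draws reference reads binomially with
$p = (1-m)f_\text{host} + m f_\text{donor}$, where $m$ is the per-day
donor fraction and $f$ maps hom-ref/het/hom-alt to 1/0.5/0, adjusted for
a symmetric miscall rate $e$ as $p(1-e) + (1-p)e$.

# Paired-compartment comparison

Fold changes between matched compartments are per-subject ratios with a
0.1-TPM pseudocount, averaged per gene; genes below 1 TPM in every
subject of both compartments are excluded and listed. Two gene
populations (e.g. marrow-specific vs blood-specific) are compared through
their mean log2 compartment ratios with a two-sided Wilcoxon rank-sum
test.

The rank-sum implementation reports the Mann–Whitney $U$ of the first
group together with the signed standardized statistic
$z = (U - n_1 n_2/2)/\sigma$ using the tie-corrected variance and a 0.5
continuity correction; compartment-comparison figures in this field print
statistics on the $z$ scale (values like 3.22 or −3.40), and both numbers
are returned so neither convention is forced. When both groups have at
most 8 observations the two-sided p-value is computed by exact
enumeration of all $\binom{n_1+n_2}{n_1}$ rank assignments, conditional
on the observed (possibly tied) ranks:
$p = P(|W - E W| \ge |w - E W|)$. Fully tied data give $z = 0$, $p = 1$.
Calibration is verified empirically: the type-I error at nominal 5% lies
in [0.03, 0.07] over 2000 null simulations, and null p-values are
uniform by a Kolmogorov–Smirnov check across 200 seeds.

# The synthetic generator: what it does and does not emulate

The generators exist so that every stage has inputs with known ground
truth. They emulate the *structure* the methods rely on: log-normal
background expression (σ = 0.5 on the natural log scale) with planted
exact-fold markers; Dirichlet(1) mixture proportions when none are given;
multinomial read sampling at a configurable depth (TPM-renormalized);
piecewise lineage trajectories; symmetric-share clone composition;
binomial allele counts under a mixing ramp. One global seed expands into
fixed per-operation substreams, so identical configurations are
bitwise-reproducible and individual stages can be regenerated
independently.

They deliberately do **not** emulate: read-level artifacts (no FASTQ, no
alignment or duplication structure), fragment-length or GC bias, gene
length effects, batch effects, correlated biological variation between
genes beyond mixture structure, or realistic noise magnitudes for the
cf-mRNA assay — no public estimates exist, so the defaults are
placeholders meant for sensitivity exploration. Passing tests therefore
demonstrate correctness of the computations under a known generative
model, not performance on real plasma sequencing.

# Numerical choices and degenerate inputs

* Fold-rule comparisons in product form (exact at constructed
  boundaries); strict inequalities throughout, as the rules are printed.
* NNLS core: Lawson–Hanson active set; simplex constraint via weighted
  augmented row (weight $10^3\times$ mean signature magnitude, giving
  constraint violations far below the $10^{-6}$ validity tolerance
  before the final exact renormalization).
* NMF determinism: NNDSVD + seeded zero-fill; sample-order permutation
  changes component order only.
* All-zero rows cannot be max-normalized and error explicitly; zero Ig
  class totals give flagged `NA` fractions, never silent zeros; zero-depth
  SNP days are flagged `NA`.
* k-means ties and restarts are controlled by a derived substream of the
  one seed; hierarchical clustering is deterministic.
* Test and acceptance problem sizes — 1000 genes, 6 cell types, 30
  markers per type, 24 mixture samples, 21-day time courses, 52 Ig
  segments at $10^4$ reads/day, 50-SNP panels at depth 200, 2000 null
  simulations for test calibration — were chosen as the smallest scales
  at which every property is comfortably identifiable; the whole suite
  runs in about a minute.

# Known limitations

* NMF annotation automates only the expression-based evidence stream;
  functional-enrichment evidence (the other stream practitioners consult)
  is out of scope, and ambiguous components stay `"unannotated"`.
* The dominance rule and genotype thresholds are explicit stand-ins for
  judgments the field makes manually; they are parameters, not claims.
* `estimateFractions` assumes the signature's entities span the sample's
  true composition; unmodelled tissues are absorbed into the modelled
  fractions rather than reported as residual mass (the residual norm is
  returned for diagnostics).
* The rank-sum exact path enumerates up to $\binom{16}{8} = 12870$
  subsets; beyond size 8 per group the tie-corrected normal approximation
  is used, which at 8/8 already agrees with exact enumeration within
  0.02.
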