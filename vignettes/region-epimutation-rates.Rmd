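---
title: "Region-level epimutation rates from bisulfite counts in selfing pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level epimutation rates from bisulfite counts in selfing pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirate)
```

## The problem

Plant DNA methylation is heritable across generations, yet it also changes
spontaneously: an unmethylated cytosine cluster can gain methylation and a
methylated one can lose it, independently of any DNA sequence mutation.
These *epimutations* accumulate in mutation-accumulation (MA) lines —
lineages propagated from a single founder by repeated single-seed-descent
selfing — where selection is minimal and every heritable change is
essentially a clock tick. `epirate` estimates the per-generation gain rate
$\alpha$ and loss rate $\beta$ of methylation at the level of *regions*
(clusters of cytosines), in the three plant sequence contexts CG, CHG and
CHH, from whole-genome bisulfite sequencing (WGBS) counts collected across
such pedigrees.

The pipeline has five stages, each usable on its own: genome segmentation,
region status calling, pairwise divergence, inheritance-model fitting, and
annotation-stratified estimation. A seeded synthetic-data generator
produces every input the pipeline consumes with known ground truth, so each
stage — and the whole chain — is validated by recovery experiments rather
than by eyeballing.

## Segmentation: seed-and-merge with a 185 bp cap

Every cytosine is assigned to exactly one region of its context. Seeds are
the tightest possible units: a strand-symmetric CG dyad (`+C` at $p$, `-C`
at $p+1$, span 2), a symmetric CHG triad (span 3), and a single cytosine
for CHH, which is not strand-symmetric. CHG sites of the CCG/CGG type have
no symmetric partner and form singleton seeds. Merging then iterates the
inter-cluster gap $d$ upward: at each $d$, adjacent clusters whose gap
(bases strictly between the spans) equals $d$ are merged left to right,
provided the merged span stays within 185 bp; the scan repeats at a given
$d$ until no merge applies. The 185 bp cap is the nucleosome-scale distance
at which methylation autocorrelation collapses; it is a tunable parameter
(`max_span`) with 185 as the default.

Two conventions are worth stating because the verbal description of the
algorithm leaves them open:

* **The distance loop starts at gap 0.** Adjacent same-context clusters
  with zero bases between them exist (e.g. `CGCG` yields two dyads at gap
  0); starting the loop above 0 would leave them unmergeable forever, which
  contradicts both the intent ("closest cytosines first") and the observed
  region-size distributions. Gap-0 pairs are simply the closest case.
* **Region spans are anchored at cytosine positions** (first member C to
  last member C + 1), not at context-motif ends. The alternative differs by
  at most 2 bp and would only rescale densities marginally.

The merge result is provably order-insensitive apart from span blocking,
and the test suite checks it against an independent brute-force
implementation that repeatedly merges the globally closest admissible pair.
A pair blocked by the span cap is skipped, not frozen: each member may
still merge on its other side. Blocking is permanent in effect because
spans only grow — which also makes the procedure idempotent, another tested
invariant.

At chromosome 3' ends (per strand) the trinucleotide context is undefined,
so trailing cytosines are skipped; for CG the mirrored member of a boundary
dyad is skipped too, keeping dyads whole. Fixed-width 100 bp bins
(`bin_genome()`) are provided as the baseline segmentation used by typical
DMR callers, for comparison of region characteristics.

## Status calling: a three-component binomial mixture

Counts are summed over a region's member cytosines, both strands. Two
filters mirror standard practice: a region must have strictly more than 3
reads per cytosine on average in *every* sequenced sample of the pedigree,
and (after classification) a maximum posterior probability of at least
0.99 in every sample. Regions failing either are dropped from the pedigree
analysis.

Classification itself uses a three-component binomial mixture over region
counts, fitted per context by EM: component success probabilities
$p_U < p_I < p_M$ (initialized at 0.01 / 0.5 / 0.95) and free mixing
weights, convergence at a log-likelihood improvement below $10^{-8}$ or 500
iterations, components relabelled by sorted success probability. The
posterior for a region–sample cell is proportional to
$w_k \,\mathrm{Binom}(m; t, p_k)$, the call is the maximum-posterior state
with ties broken toward I (the conservative middle state, contributing 0.5
rather than 1 to divergence). When the EM degenerates — a mixing weight
collapsing to zero, as happens when the data hold fewer than three real
components — the fixed initialization parameters are used with a warning.

A positional hidden-Markov classifier over single cytosines would add
nothing here: once the unit of analysis is a whole region, transitions
between neighbouring units carry no information about the within-region
emission, so an emission-driven mixture is the natural reduction. The
replacement can shift borderline I calls relative to an HMM-based caller;
the retention filter at 0.99 removes most of that borderline mass.

## Divergence and the selfing inheritance model

For two plants $i, j$ and region $n$, the divergence contribution
$d_{ij,n}$ is 1 for discordant homozygous calls (M vs U), 0.5 when exactly
one call is intermediate and they differ, and 0 for identical calls;
$D_{ij}$ is the mean over the $N$ retained regions. Divergence time
$\Delta t$ is the number of independent selfing generations through the
most recent common ancestor, a pure graph distance on the pedigree —
sequenced siblings are explicit nodes, so the sibling-vs-propagation
subtlety is handled by correct pedigree construction, not special-casing.

Inheritance is a Markov chain on $k \in \{0, 1, 2\}$ methylated epialleles
(observed as U / I / M). One generation is selfing segregation $S$ followed
by per-allele epimutation $E$:

$$T = S(s)\,E(\alpha, \beta)$$

Homozygotes breed true; the heterozygote segregates $\tfrac14 : \tfrac12 :
\tfrac14$, reweighted under selection — ABmm weights $(1-s, 1-s/2, 1)$
against losses, ABuu $(1, 1-s/2, 1-s)$ against gains — and renormalized.
$E$ applies $u \to m$ with probability $\alpha$ and $m \to u$ with
probability $\beta$ independently per allele. ABnull is the identity (no
accumulation). Applying $E$ before $S$ instead would differ at order
$O(\alpha\beta)$ per generation, far below anything estimable here; the
$S$-then-$E$ order is the package's convention. The expected divergence
between descendants at branch lengths $t_i, t_j$ from a common ancestor in
equilibrium is

$$E[D] = c + \sum_a \pi_a \sum_{x,y} (T^{t_i})_{a,x} (T^{t_j})_{a,y}\, w(x,y)$$

with the same $w$ weights and an intercept $c$ absorbing measurement noise
(divergence between technical replicates at $\Delta t = 0$).

### Identifiability: why the fit is anchored by the methylation level

$E[D]$ is *exactly* invariant under swapping $\alpha \leftrightarrow
\beta$: relabelling states $0 \leftrightarrow 2$ mirrors $\pi$ and $T$ and
leaves $w$ unchanged. Divergence curves alone therefore cannot tell gains
from losses. What breaks the tie in practice is the genome's methylation
level: under the equilibrium assumption the stationary unmethylated
fraction $\pi_0(\alpha, \beta, s)$ must match the observed proportion of U
calls, and at low rates $\pi_2/\pi_0 \approx \alpha/\beta$. `fit_model()`
therefore accepts `p_u`, the observed unmethylated-region proportion among
retained calls, and solves $\beta$ from $\alpha$ (and $s$) on each
objective evaluation via the closed-form stationary distribution (derived
symbolically and verified against the eigendecomposition to $10^{-12}$).
Without `p_u` the unconstrained fit is still available, with the caveat
that the $(\alpha, \beta)$ labels of the two mirror solutions are
arbitrary — a property the test suite demonstrates rather than hides.

Fitting minimizes the residual sum of squares over all sequenced pairs by
bounded L-BFGS-B on $\log \alpha$ (rates bounded in $[10^{-12}, 0.1]$, $s
\in [0, 0.99]$, $c \in [0, 1]$) with multi-start (first start at fixed
defaults, the rest log-uniform; 20 starts by default). Branch lengths
$(t_i, t_j)$ enter individually rather than as $\Delta t$, since $E[D]$
depends on both when they differ. All pairs are used, treated as
independent observations in the objective — the estimator this induces is
consistent; what it breaks is naive uncertainty quantification, which is
why intervals come from the region bootstrap below. ABnull is fitted in
closed form ($c = \bar D$).

### Uncertainty: region bootstrap, not residual bootstrap

The $\binom{k}{2}$ pair records share one realization of the inheritance
process across a handful of samples, so residuals around the fitted curve
carry almost none of the replicate-level noise: in calibration runs the
residual bootstrap produced intervals two orders of magnitude too narrow
(half-width $\sim$0.02% of the estimate against a true replicate spread of
$\sim$1.6%). The independent sampling units are *regions*.
`bootstrap_rates()` therefore resamples regions — via their joint status
patterns across the sequenced samples, multinomially — rebuilds every pair
divergence and the `p_u` anchor from each resample, and refits with a warm
start. In repeated-simulation calibration (50 replicates, MA1_1 design,
$5\times 10^4$ regions) the resulting 95% percentile intervals cover the
true rates in ~97% of replicates. `fit_model()` retains an optional
residual bootstrap for genuinely iid records.

### Model comparison and its limits

Nested F-tests on RSS compare ABnull (1 parameter) against ABneutral (3),
and ABneutral against each selection model (4), at the 0.05 level;
ABneutral is reported unless a selection model significantly improves on
it, and ABnull wins when ABneutral does not improve on flat divergence.
The parameter counts refer to the unconstrained parameterizations; with the
`p_u` anchor the effective dimensions are one lower, making the tests
mildly conservative — a deliberate choice, as the cost of a false selection
verdict exceeds that of a missed one here.

A structural caveat the package documents rather than obscures: because
heterozygotes are transient under selfing, segregation-level selection
mostly rescales the effective rates and the equilibrium — both absorbed by
$(\alpha, \beta, c)$ and the anchor. A noise-free ABuu curve at $s = 0.5$
is matched by ABneutral to RSS $\sim 10^{-11}$, five orders of magnitude
below the sampling noise floor at $10^5$ regions. Power to *detect*
selection of this form from divergence curves is therefore negligible at
realistic problem sizes, and simulation studies show the correct selection
model winning only a minority of the time. This mirrors the empirical
finding that the neutral model fits MA-line methylomes essentially
everywhere; claims of selection from such fits deserve suspicion.

## Stratification

Regions are labelled by annotation overlap: a region receives a feature's
label when the overlap covers at least 40% of the *region* span (regions
are the analysis unit, hence the region-relative denominator); regions with
no label are intergenic; multiple labels are allowed. Promoters are 1.5 kb
upstream of each TSS, truncated at chromosome bounds. Gene regions split
into gbM (gene-body-methylated) and non-gbM by a supplied gene-id list — a
consumed input, not recomputed. CG regions are also classed as duplets
(exactly one symmetric dyad) versus multiplets, with multiplets split
dense/sparse at median density 0.105 and short/long at median span 104 bp
(genome-wide medians of the reference segmentation; ties go to the lower
class; both recomputable from data via `recompute = TRUE`). Chromosome
zones (arm / pericentromere / centromere) are assigned by the region
midpoint — regions are at most 185 bp against zones of megabase scale, so
the midpoint rule cannot misassign by more than a boundary sliver.
`stratified_rates()` refits the models per stratum with a per-stratum
`p_u`, flagging strata below a configurable region count as unstable
rather than reporting spuriously precise rates.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, and every stage is deterministic under an explicit seed.

* **Genome**: iid bases at A/C/G/T = 0.32/0.18/0.18/0.32 with alternating
  gene-like (2 kb) and TE-like (1.5 kb) blocks over intergenic gaps; gene
  blocks optionally CG-enriched (default 0.02 planted dinucleotides per
  bp) to mimic genic CG density; UTR ends on genes; an
  arm/pericentromere/centromere partition around each chromosome middle.
* **Pedigrees**: presets mirror the four published MA designs — 12
  branches sampled at generations 3/31/32 (MA1_1), 7 branches at 3/31
  (MA1_2), one branch at nine generations (MA1_3), two branches at five
  generations (MA2_3). Branch counts and sampled generations follow the
  published designs; where the exact sampled generations of the densely
  sampled lines are not pinned down, they are spaced evenly over 3–31 and
  fixed once. Sequenced plants are sibling leaves of the propagation
  chain, matching single-seed descent.
* **Methylomes**: founder states drawn from the model equilibrium (the
  stated assumption of the estimation model), one transition-matrix draw
  per pedigree edge, regions independent — matching how the estimator
  treats them. Real methylomes violate this with linked epialleles and
  context interactions; recovery results therefore certify the estimator
  under its own assumptions, not robustness to linkage.
* **Reads**: per-cytosine totals from a negative binomial (default mean
  10, size 5), methylated counts binomial with status-conditional
  probabilities 0.02 / 0.5 / 0.9 for U / I / M — matching the observed
  region-level methylation level distributions, with bisulfite
  non-conversion folded into the U emission. Depth presets of mean 5 and
  5.5 (size 3) emulate the low- and high-depth pedigrees; under the strict
  all-samples coverage filter they reproduce the 35–75% retention range
  seen in the reference data.

What passing recovery tests do show: the segmentation is exactly correct
(oracle-verified), the caller is calibrated on mixture data, and the rate
estimator recovers planted genome-wide rates within a few percent at
$5\times 10^4$ regions with honestly calibrated intervals. What they do
not show: robustness to linkage between regions, to coverage biases
correlated with methylation, or to misspecified emission families.

## Numerical choices and problem sizes

Stationary distributions use a closed form (verified against eigen);
matrix powers are cached per fit; the equilibrium constraint is solved by
bisection on $\log \beta$ to $10^{-9}$. EM uses log-sum-exp throughout.
Degenerate inputs error early and explicitly: empty genomes, absorbing
chains ($\alpha = 0$ or $\beta = 0$) when an equilibrium is requested,
regions with no cytosines in the coverage filter, strata that are empty
after filtering.

The shipped analysis scripts and tests run at deliberately desk-scale
sizes — 120–200 kb genomes (~1.3k CG regions), $10^4$–$10^5$ simulated
regions for estimator calibration, 50 recovery replicates with 200
bootstrap draws — chosen so the full suite certifies every claim in
minutes on one CPU while leaving the statistical conclusions unchanged at
larger sizes (errors scale as $N^{-1/2}$ and were spot-checked at
$5\times10^4$ regions throughout).

## Known limitations

* Rates are region-level; no per-cytosine rates are estimated, and
  comparisons with single-site rates inherit the region definition.
* The equilibrium anchor assumes the founder methylome is stationary; a
  founder far from equilibrium biases $\beta/\alpha$ toward the founder's
  state composition.
* Selection coefficients of the segregation-reweighting form are nearly
  unidentifiable from divergence data (see above); the ABmm/ABuu machinery
  is provided for completeness and hypothesis tests, not for estimating
  $s$.
* The intercept $c$ soaks up measurement noise but also any true
  divergence at $\Delta t \to 0$; with few distinct $\Delta t$ values
  (e.g. a two-timepoint design) $c$ and the rates are weakly separable and
  intervals widen accordingly.
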