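---
title: "Binned GBS genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned GBS genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binGBS)
```

# The problem

Genotyping-by-sequencing (GBS) of a large F2 intercross trades coverage
for marker count: with hundreds of multiplexed individuals per lane, each
fish sees each SNP at roughly 1--2 reads. No individual SNP can be
genotyped reliably at that depth — a single read cannot distinguish a
heterozygote from either homozygote, reads carry allele errors, and
individual SNPs suffer mapping bias and coverage pathologies. The binned
strategy implemented here recovers reliable genotypes by pooling: when
grandparents of the cross come from two divergent populations (a marine
and a freshwater stickleback population in the motivating design), the
tens of thousands of SNPs at which the grandparents are homozygous for
different alleles are all phased *a priori*. Allele reads from every SNP
in a scaffold window can then be summed into one high-coverage "binned
marker" (~150x from ~100 SNPs at 1.5x), good enough for confident
genotype calls, dense linkage maps, assembly curation and QTL mapping.

This vignette records the models behind each stage, the tunable
parameters with their defaults and rationale, and the design decisions
taken where more than one construction was defensible.

# The SNP sieve

For each phased SNP the package pools reads over all F2s, normalised by
each fish's total mapped reads, scaled to reads per million mapped
(RPMM). The default "weighted average" is the pooled ratio

$$\mathrm{RPMM}_a = 10^6 \cdot \frac{\sum_i c_{a,i}}{\sum_i T_i},$$

the $T_i$-weighted mean of per-fish normalised counts: low-count fish get
the weight their data deserve. An unweighted mean of per-fish $10^6
c_{a,i}/T_i$ is available (`sieve_config(weighted = FALSE)`) but inflates
the influence of poorly sequenced fish.

A SNP passes the sieve when its pooled freshwater allele fraction lies in
[0.2, 0.8] (equivalently a marine/freshwater ratio between 4:1 and 1:4 —
only the fraction form is implemented since the two rules are the same
constraint) and its total RPMM lies in [0.2, 3.0]. The lower coverage
bound discards barely-sequenced sites; the upper bound discards
over-covered sites that are typically collapsed repeats. Bounds are read
inclusively; the choice is essentially immaterial for continuous
statistics but is pinned down in tests.

**Skew rescue.** Real crosses contain genuinely distorted regions (meiotic
drive, genotype-class lethality) whose allele fractions sit legitimately
away from 0.5. A sieve that kept only ~0.5-fraction SNPs would delete
them; one that kept everything would keep artefacts. The rule: a
sieve-passing SNP is called *skewed* when a two-sided exact binomial test
of its pooled counts against 0.5 rejects at `skew_test_alpha` (default
0.001); a skewed SNP is kept only if one of its nearest flanking
sieve-passing SNPs within `skew_window` (default 1 Mb) is skewed in the
same direction. True distortion is regional and produces runs of
same-direction skew; artefacts are isolated. Both parameters are
package decisions: α = 0.001 keeps the false-skew rate near one per
thousand SNPs so the rescue rule is exercised only where the signal is
real, and 1 Mb comfortably spans the SNP spacing of any GBS design this
package targets. The rescue can only widen the *fraction* criterion;
a SNP that failed on coverage grounds is never rescued.

# Binning and genotype calling

Scaffolds are cut into equal spans: one bin under 100 kb, two bins from
100 kb to 1 Mb, and `floor(L / 500 kb) + 1` bins at or above 1 Mb —
reproducing the published series (three bins for 1--1.5 Mb, four for
1.5--2 Mb, and so on) and guaranteeing bins of at most 500 kb on large
scaffolds. Equal spans keep markers comparable between crosses genotyped
against the same assembly.

Pooled bin counts $(m, f)$ are called with binomial likelihoods: the
freshwater-read probability is $\epsilon$ under MM, $1/2$ under MF and
$1-\epsilon$ under FF, combined with the Mendelian 1:2:1 prior. Defaults:

* `epsilon = 0.02` — the effective per-read wrong-allele rate
  (sequencing error plus residual mismapping). It is deliberately set
  slightly above a pure base-error rate; an optimistic $\epsilon$ makes
  homozygote likelihoods overconfident at high pooled depth.
* `call_posterior = 0.95` — posterior mass required for a hard call.
  When no single state reaches it but an *adjacent* pair does (MM,MF) or
  (MF,FF), the composite calls `MM/MF` / `MF/FF` are emitted. These occur
  almost exclusively in bins spanning a recombination breakpoint, where
  the pooled counts genuinely mix two genotypes; keeping them as partial
  observations (rather than missing) preserves linkage information at
  exactly the positions where recombination happens. The non-adjacent
  pair (MM,FF) is never composite — a bin cannot mix two homozygotes
  without passing through a double crossover that the flanking data
  would flag.
* `min_reads = 3` — below three pooled reads even the prior barely
  moves; such bins are missing.

**QC order.** Fish with more than 50% missing markers are dropped first,
then markers missing in at least 20% of the remaining fish, then markers
whose hard-call counts fail a 1:2:1 chi-square test at α = 0.001 —
unless an adjacent marker on the same scaffold is skewed in the same
direction (the marker-level analogue of the SNP rescue). Fish first: a
few bad libraries otherwise inflate every marker's missingness and
cascade into marker drops. The thresholds "more than 50%" (strict) and
"at least 20%" (inclusive) follow the published wording.

# Sex calling

The sex chromosome is X-hemizygous in males: XY fish carry one X, so
their sex-chromosome depth is half their autosomal depth, while XX fish
show equal depth. The statistic is reads per SNP site on the sex
chromosome over reads per SNP site on autosomes, which cancels per-fish
sequencing effort exactly — the call is invariant to global coverage
rescaling, so low-coverage fish separate as cleanly as deep ones until
counting noise takes over. Calls: XY below 0.65, XX above 0.85, unknown
in between or below `min_reads = 200` total sex-chromosome reads. The
dead zone plus read floor mean the caller abstains rather than guesses;
in simulation at 0.3x genome coverage the abstention rate is a fraction
of a percent and no called fish is wrong. XY fish are then re-called on
the sex chromosome under a two-state haploid model (M or F, uniform
prior); balanced read counts are inconsistent with haploidy and go
missing rather than being forced into a state.

# Linkage maps

**Two-point estimation.** For a marker pair in an F2, each fish carries
two independently transmitted gametes, each parental with probability
$1-r$ or recombinant with probability $r$. Every observation class —
including the composite calls, treated as partial observations whose
likelihood sums over compatible states — reduces to three integers
$(a, b, c)$: the number of compatible ordered gamete-pair configurations
with 0, 1 and 2 recombinant gametes. Class probability is
$(a u^2 + b u r + c r^2)/4$ with $u = 1-r$, and the EM update is the
classical expected-recombinant-count ratio. The same sufficient-statistic
decomposition lets `rf_matrix()` run the EM simultaneously for all
marker pairs as dense matrix arithmetic, which is what makes ~1000-marker
maps practical in plain R. LOD is the log10 likelihood ratio against
$r = 0.5$.

**Grouping** is single-linkage over edges with LOD ≥ 6 and $\hat r$ ≤
0.35. The LOD threshold is conservative for ~350-fish crosses (adjacent
binned markers reach LOD in the tens); the $\hat r$ cap stops spurious
long-range edges in the presence of segregation distortion.

**Ordering** is seriation: minimise the sum of adjacent $\hat r$ by
greedy nearest-neighbour chains (best over all start markers for groups
up to 80 markers) polished with 2-opt reversals, deterministic with ties
broken by marker index. Multipoint maximum-likelihood ordering is out of
scope; at bin-scale marker spacing (~1–2 cM) adjacent-$\hat r$ seriation
recovers orders with Kendall τ ≥ 0.95 against truth in simulation. A
map's left-to-right direction is intrinsically arbitrary; orders are
normalised against physical coordinates where known.

**Distances** use Haldane by default, $d = -50\ln(1-2r)$ — matching the
no-interference meiosis model of the simulator, so simulated map lengths
have a closed-form expectation — with Kosambi available for real data
where interference is expected.

**Marey profiles** place each mapped marker at its strand-aware physical
midpoint on the revised assembly and report per-interval cM/Mb. Runs of
at least `min_run = 3` consecutive zero-cM intervals are flagged as
recombination-suppression candidates; heterozygous inversions produce
exactly this signature.

# Assembly revision

Scaffold orientation is the sign of the Spearman correlation between
marker bp (within scaffold) and cM; fewer than two distinct cM values
leave orientation unknown, which is the expected fate of single-bin
scaffolds. Each linkage group inherits the chromosome name of the
majority of its previously anchored scaffolds, and each chromosome's map
direction is normalised against the prior scaffold order so orientations
are comparable with the prior. Ranks come from median marker cM with
ties broken by prior rank then scaffold id (deterministic). The change
list distinguishes newly anchored scaffolds, reorientations, and
rearrangements; within-chromosome moves are isolated as the scaffolds
outside the longest increasing subsequence of prior ranks, the minimal
set whose relocation explains the order change.

Consensus between two crosses accepts agreements, takes single-cross
placements on single-cross evidence, and reports chromosome conflicts
rather than resolving them (the motivating study observed none).
Scaffolds too small to map by genotype calls are placed by the
read-correlation method: Pearson correlation across F2s between a bin's
genotype dosage (posterior mean, 0–1 scale) and every placed marker,
assigned to the best marker's position when the correlation reaches 0.5
and beats the best marker on any other chromosome by 0.1. Thresholds are
package decisions; on simulation they place >90% of hidden 2-Mb
scaffolds on the correct chromosome within ~5 cM.

The revised sequence model uses fixed 1000-bp inter-scaffold gaps,
recorded identically in the AGP writer and the liftover table so
coordinate round-trips are exact and strand-aware.

# Breakpoint fine-mapping

The three-state HMM runs on raw per-SNP counts, not binned calls, so its
resolution is SNP spacing rather than bin size. Transitions between SNPs
at distance $d$ use the Haldane per-meiosis recombination probability
$r = (1 - e^{-2\rho d})/2$ in the standard F2 two-gamete matrix;
emissions are the same binomial model as genotype calling; zero-read
SNPs contribute flat emissions automatically. $\rho$ is taken per
chromosome from the linkage map (total cM / total Mb) rather than fitted
per fish — at 1.5x a per-fish estimate would be dominated by noise.
Decoding is exact forward–backward and Viterbi in log space, verified in
tests against exhaustive enumeration over all $3^{12}$ paths of 12-SNP
chromosomes.

Breakpoint intervals follow the Viterbi path's state changes; the bounds
are the last SNP before the change with posterior ≥ τ for the departing
state and the first SNP after it with posterior ≥ τ for the arriving
state (default τ = 0.95). Each flank is thus individually calibrated at
τ, so joint truth-containment is approximately $1 - 2(1-\tau)$: ~90% at
the default, ~95% at τ = 0.975 — simulation reproduces both figures, and
users wanting nominal 95% intervals should set `tau = 0.975`. Close
double crossovers (two breakpoints within 1 Mb) and two-copy jumps
(MM↔FF) are flagged rather than suppressed: at 1.5x they are usually
artefacts, but deleting them silently would bias recombination counts.

`minimal_qtl_interval()` turns recombinant fish into interval
constraints: a fish whose phenotype class matches its left-side genotype
forces the causal locus left of its interval's right bound, and
symmetrically; the intersection is the maximal interval on which
genotype perfectly correlates with phenotype, with contradictions
reported explicitly (listing the offending fish) instead of silently
returning an empty interval.

# QTL scans

Phenotypes are optionally log-transformed, regressed on standard length
and/or sex, and re-centred at the grand mean; covariates that are
constant in a given cross are dropped automatically. Scans are
Haley–Knott: phenotype on expected additive dosage and heterozygosity
probability per marker, LOD $= (n/2)\log_{10}(\mathrm{RSS}_0 /
\mathrm{RSS}_1)$. Genotype probabilities come from the calling
posteriors; missing and composite entries are replaced by HMM posteriors
computed across each linkage group at marker resolution. Probabilities
are not interpolated between markers: at ~1 marker/cM, pseudomarkers
would add evaluation points well inside the support interval width and
nothing else.

Significance uses genome-wide permutation thresholds (default 1000
permutations, α = 0.05), computed by a projection identity that
evaluates all markers × all permutations as two matrix products — the
same code path scans 200 null traits against per-trait thresholds in
seconds, which is how the type-I error calibration test runs at full
size. Percent variance explained is $100(1 - 10^{-2\,\mathrm{LOD}/n})$,
the $R^2$ implied by the LOD; reported class means use hard calls only,
while scans use all fish through their probabilities. Conditioned scans
subset to a hard-called class at a conditioning marker (refusing under
10 fish, warning under 30) and rerun scan plus permutations within the
subset — the design that exposes modifier loci hiding under a
near-Mendelian major locus. Multiple-QTL model selection is deliberately
out of scope.

# The simulator: what it emulates, and what it does not

`simulate_cross()` generates the full observable layer from known truth:
Haldane (no-interference) meioses, phased SNPs Poisson-placed at a
chosen density, Poisson read depth per SNP scaled by per-fish sequencing
effort (Gamma(10,10), so total mapped reads and SNP coverage co-vary as
they do across barcodes in a real library), per-read allele error,
X-hemizygous males with halved sex-chromosome depth, regional
segregation distortion at a chosen gamete frequency, assembly scrambling
with an edit log, and QTL with additive/dominance effects plus covariate
structure. Defaults emulate the motivating design: ~1.5x per-SNP
coverage, ~100 SNPs/Mb, 3.5 cM/Mb (a realistic genome-wide figure for a
~460-Mb fish genome with a ~1600-cM map), 350-fish crosses.

It deliberately does **not** model: read sequences or alignment
(reference bias, mismapping hotspots), restriction-site dropout and the
resulting clustered SNP coverage, allele-specific amplification,
crossover interference, gene conversion, or Y-linked sequence. Passing
tests therefore demonstrate that the *algorithms* behave as designed
under their stated noise model — not that real libraries are free of the
artefacts the sieve and QC stages exist to catch; on real data those
stages work harder than they do here.

Truth breakpoints are recorded at exact crossover positions where
visible (a crossover between two SNPs with no intervening marker, or a
cancelling pair, is invisible by construction); distortion-boundary
transitions are recorded at flanking-SNP midpoints.

# Numerical choices and degenerate inputs

* All coordinates are 1-based with inclusive spans (AGP/GFF convention),
  asserted in the IO round-trip tests.
* The EM for $r$ runs from 0.25 with a 1e-10 convergence tolerance and
  clamps to [0, 0.5]; $r = 0.5$ distances are refused (markers must be
  grouped first). Degenerate likelihoods are floored at 1e-300 before
  logs.
* Forward–backward runs in log space with per-step rescaling; posteriors
  renormalise to row sums of 1 (tested at 1e-12).
* Zero-coverage SNPs emit flat likelihoods; zero-read bins are missing;
  fish with zero mapped totals are excluded from RPMM sums with a
  warning.
* Ties everywhere (seriation starts, rank ties, max.col) break by first
  index / prior order / scaffold id, making every stage deterministic
  for a fixed seed.
* Tests and the acceptance script run at reduced problem sizes chosen as
  the package's own test design: e.g. 350-fish crosses on 4–40 scaffolds
  of 1.2–24 Mb, ~1000 markers for threshold calibration, 12-SNP
  chromosomes for exhaustive HMM verification — large enough for every
  statistical claim tested, small enough to build fixtures in code.

# Known limitations

* JoinMap-style multipoint regression mapping is not reproduced; the EM +
  seriation approach is transparent and testable but will differ in
  marker-order details on real, noisy groups.
* The aberrant-ratio marker test, skew test, sex-chromosome sieving
  parameters and genotype-calling constants are package decisions where
  the published pipeline's supplementary detail was not available to this
  implementation; all are exposed as configuration.
* `estimate_rf` assumes intercross (codominant) markers; dominant-only
  markers are out of scope.
* The permutation threshold assumes exchangeable fish under the null;
  family structure beyond the F2 design would violate it.
* PVE from a single-marker LOD understates the variance explained by a
  QTL whose causal variant sits between markers, and class means use
  hard calls only.
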