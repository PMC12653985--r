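---
title: "Microsatellite population genetics for clonal insects: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite population genetics for clonal insects: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepop)
```

## The problem

Aphids such as the peach–potato aphid (*Myzus persicae*) reproduce by
cyclic parthenogenesis: long runs of clonal (apomictic) generations
punctuated by a single sexual generation in autumn. A field sample from
such a population is therefore a mixture of repeated copies of a modest
number of clonal lineages, each founded by one overwintered fundatrix.
This structure has three statistical signatures that ordinary
population-genetic workflows mishandle:

* the number of distinct multilocus genotypes (MLGs) is far below the
  number of samples (MLG/N « 1);
* heterozygote excess accumulates within lineages (negative F~IS~),
  because clonal propagation never rehomogenises genotype frequencies;
* loci appear strongly associated (elevated r̄~D~) even when physically
  unlinked, because whole multilocus genotypes are copied together.

`clonepop` implements the full analysis chain for multiplexed
microsatellite (SSR) panels on such populations — genotype QC, sex
inference from X-linked hemizygosity, clonal diversity, linkage
disequilibrium, and structure — together with a synthetic-population
generator so that every stage runs, and is testable, without access to
field data.

## The synthetic population generator

`sim_config()` / `simulate_population()` emulate the sampling design of a
two-locality, one-season trap survey of a cyclically parthenogenetic
population:

* **Lineages.** `n_lineages` founder genotypes (default 97) are drawn per
  locus from Dirichlet-distributed allele frequencies on a contiguous
  repeat-count grid. The default abundance distribution is strongly
  skewed: five dominant lineages at 112, 39, 34, 28 and 25 copies, the
  remaining 127 samples spread over 92 minor lineages by geometric decay
  (ratio 0.95, largest-remainder rounding). Only the dominant abundances
  are a documented study condition; the minor-lineage tail is this
  package's own choice, selected once as the simplest monotone scheme
  with the right support (most minor lineages singletons).
* **Heterozygote excess.** Founder genotypes are random unions of gametes,
  forced heterozygous with probability `het_excess`. The defaults
  (`allele_freq_prior = 0.5`, `het_excess = 0.2`) were calibrated once so
  that the sample-level mean inbreeding coefficient sits near −0.15, the
  level reported for real clonal *M. persicae* samples; they are study
  conditions, not tuning knobs.
* **Noise channels.** Stepwise mutation (±1 repeat on one random allele),
  heterozygote dropout (a heterozygote read as one of its alleles twice),
  allele miscall (±1 repeat on read), and per-cell missingness. All
  default to zero and are switched on explicitly; dropout, miscall and
  missingness accept per-locus vectors because real panels concentrate
  error in a few stutter-prone loci. A `truth_record` logs every event,
  lineage id, pre-error genotype and true sex, enabling parameter-recovery
  tests.
* **Sex.** A configurable fraction of samples are X0 males, which carry a
  single X allele reported as a homozygote at every X-linked locus —
  exactly the hemizygosity signal the sex-inference module looks for.

What the generator does **not** emulate: explicit multi-generation life
cycles (egg diapause, host alternation), selection, linkage on physical
chromosomes, null alleles and stutter-ratio artefacts, or relatedness
*between* founder lineages. The last point matters when interpreting
tests: simulated founders are independent draws, so clone correction
removes essentially all linkage disequilibrium (post-correction r̄~D~ ≈ 0),
whereas real fundatrices share sexual ancestry and retain LD after clone
correction. Passing tests therefore demonstrate correct estimator
behaviour under clonal copying, not the full ancestry structure of field
data.

## Genotype model and QC

Genotypes are unordered diploid allele pairs (fragment sizes or repeat
counts); homozygotes store the value twice, matching single-peak
capillary-electrophoresis reporting. A single non-missing allele is read
as a homozygote by default (`single_peak = "half_missing"` keeps the
second slot open for dropout-sensitivity analyses). `"NA"`, `"0"` and
empty fields are accepted as missing on input; only `"NA"` is written.

Allele binning (`bin_alleles()`) snaps calls to a per-plate allelic ladder
within a tolerance (default 0.5 bp, required to be below half the minimum
ladder gap so binning is unambiguous and idempotent); calls beyond
tolerance are kept but flagged off-ladder rather than silently altered.
`size_to_repeats()` converts fragment sizes to repeat counts via a
per-locus flanking offset, by default calibrated so the modal allele maps
to the panel's reference repeat count.

Replicate-based error rates follow the per-allele / per-locus /
per-profile hierarchy: e~a~ counts mismatched alleles over compared
alleles with **multiset** matching (so `{120,123}` vs `{123,120}` is
concordant), e~l~ counts discordant single-locus genotypes, and e~obs~
counts replicate pairs with at least one discordant compared locus. Pairs
with a missing genotype at a locus are excluded from that locus's
denominators, and the denominators are retained in the report so the
choice is auditable. The error-prone designation is always analyst input:
`error_rates()` reports a ranking by e~l~ to suggest candidates, and
`stepwise_exclude_error_prone()` recomputes the full report after each
exclusion, but nothing is dropped automatically.

Threshold comparisons are strict as worded: samples with *no more than*
four missing markers are retained; loci with MAF *below* 0.01 are removed
(MAF = frequency of the second most common allele). The pipeline order is
fixed: error-prone locus drop → per-sample missing filter → MAF filter →
sex inference → statistics before clone correction → clone correction →
statistics after → distances/ordination/network. Applying MAF before
clone correction is a deliberate choice (the alternative order is
defensible; this one keeps the locus panel constant across the B~cc~ and
A~cc~ analyses).

## Sex inference

Males are hemizygous (X0), so every typed X-linked marker is homozygous.
`infer_sex()` calls a sample male-consistent only when it is homozygous at
**all** typed X loci *and* at least `min_typed` (default 6, a majority of
an 11-locus X panel) are typed; fewer typed loci give `undetermined`.
The minimum-typed rule is this package's explicit decision — a handful of
homozygous loci is weak evidence, and missing data would otherwise
manufacture false males. `female_false_male_prob()` quantifies the rule's
error under panmixia as the product over X loci of expected homozygosity
Σp²; under clonality genotypes are correlated across loci, so this
product is an optimistic lower bound, and it is documented as such.

## Clonal population genetics

Per-locus statistics use gene diversity H~Exp~ = 1 − Σp² (the plain
estimator by default; the unbiased 2n/(2n−1) variant is a flag, since
which one a given reference analysis used is often unstated), observed
heterozygosity, F~IS~ = 1 − H~Obs~/H~Exp~ (flagged undefined at
monomorphic loci), and a Nei-style F~ST~ = (H~T~ − H~S~)/H~T~ with
unweighted group means — chosen over Weir–Cockerham because it reuses the
heterozygosity quantities already computed; third-decimal differences
against variance-component estimators are expected.

HWE is tested per locus two ways: a χ² test on all k(k+1)/2 genotype
categories (df = k(k−1)/2) and a Monte-Carlo exact test that pools the 2n
alleles and re-pairs them (default 10,000 draws), with the permutation
p-value convention (1 + hits)/(B + 1) so p is never exactly zero. On the
global scale, per-locus (H~Exp~ − H~Obs~) differences are tested with a
paired t-test and a Wilcoxon signed-rank test (zero differences
discarded), plus a Shapiro–Wilk normality check; when the differences are
constant the t-test degenerates and the floor p-value is reported
directly. No multiple-testing correction is applied by default, matching
the convention of reporting raw per-locus HWE significance counts.

MLG assignment groups samples by exact profile equality with missing as
its own token — deterministic and order-independent. The contracted mode
(samples merged when they agree on all mutually non-missing loci, closed
under single linkage) is available but non-default, because chaining can
merge distinct genotypes. Clone correction keeps the first sample of each
MLG and is idempotent.

Diversity indices over MLG abundances: Shannon–Weaver H = −Σp ln p,
Stoddart–Taylor G = 1/Σp², Simpson λ = 1 − Σp², evenness
E~5~ = (G − 1)/(e^H^ − 1) (1 for a single MLG by the limit convention).
Uniform abundances force G = n~MLG~ and E~5~ = 1 exactly, which is why the
after-clone-correction values of a 97-MLG table are H = ln 97 ≈ 4.57,
λ = 1 − 1/97 ≈ 0.99, G = 97, E~5~ = 1 regardless of the underlying
genotypes.

The standardized index of association r̄~D~ is computed from per-locus
pairwise sample distances d~j~ ∈ {0, 1, 2} (multiset allele differences):
with D the per-pair sum over loci, V~O~ = var(D) and V~E~ = Σ~j~ var~j~,

r̄~D~ = (V~O~ − V~E~) / (2 Σ~j<k~ √(var~j~ var~k~)),  I~A~ = V~O~/V~E~ − 1.

Zero-variance loci are excluded (flagged), and pairs with any missing
genotype among the analysed loci are dropped so all variances share one
pair basis. The permutation test shuffles genotype columns independently
per locus, which breaks between-locus association while preserving each
locus's genotype composition; p-values use (1 + hits)/(n~perm~ + 1). The
pairwise matrix contains the two-locus version
cov~jk~/√(var~j~ var~k~) for every locus pair.

## Structure analysis

**Bruvo distance** implements the stepwise-mutation-aware metric: per
allele pair 1 − 2^−|Δrepeats|^, per locus the minimum over the two perfect
matchings of the allele pairs, per genotype the mean over mutually typed
loci. Missing loci are handled by locus-wise deletion rather than the
genome-addition/loss imputation models of the original formulation — a
simpler, deterministic choice that is adequate after QC has capped
missingness below ~9% per sample, and documented as a divergence.

**Binary Jaccard / PCoA.** The allele-count table is expanded to
presence/absence columns per (locus, allele); the distance is
√(1 − a/(a+b+c)). The square-root form is used by default because it is
Euclidean-embeddable, keeping the classical-scaling eigenvalues
non-negative (the raw 1 − similarity dialect is a flag). PCoA is classical
metric scaling (double-centring via `cmdscale`), reporting all
eigenvalues but coordinates only on positive-eigenvalue axes.

**Minimum spanning network.** Kruskal's algorithm with lexicographic
tie-breaking gives a deterministic MST; every non-tree edge whose weight
is within `tie_tolerance` (default 10⁻⁸, i.e. exact ties only) of the
heaviest tree edge on the path between its endpoints is added back, so
equally good alternatives are visible rather than arbitrarily resolved.
Nodes are clone-collapsed MLGs sized by abundance. Cluster delimitation on
the PCoA plane is never inferred silently: `cluster_share()` takes
explicit labels, and the analysis driver that assigns samples to
dominant-lineage centroids does so as a visible, configured step.

## Numerical and degenerate-input conventions

* Permutation and Monte-Carlo p-values are never exactly 0 ((1+hits)/(1+B)).
* Monomorphic loci: H~Exp~ = 0, F~IS~ and HWE tests flagged `NA`, excluded
  from r̄~D~ (zero variance) and from error-rate panel means when no pair
  was compared.
* A replicate pair with all loci missing contributes to no denominator;
  a genotype pair sharing no typed locus has undefined Bruvo distance
  (flagged, not imputed).
* Binning tolerance must be < half the minimum ladder gap, making the
  nearest-allele map single-valued and binning idempotent.
* All stochastic steps (simulation, replicate noise, Monte-Carlo HWE,
  r̄~D~ permutations) are seeded; a pipeline rerun with the same seed is
  byte-identical.

## Problem sizes used in the shipped analyses

The numbered drivers under `analysis/` and the test suite run the full
365-sample × 45-locus design for deterministic statistics (MLG
assignment, diversity, distances, MSN, PCoA) and scale the permutation
machinery to the precision actually needed for their checks: 199
permutations for r̄~D~ in the drivers (the statistic itself is
deterministic; 199 permutations bound p at 0.005), 1,000 Monte-Carlo
draws per locus for the exact HWE test, 1,000 null replicates for the
χ²-calibration check, and 10⁴ allele comparisons for error-rate recovery.
These sizes are the package's own choices for its reference analyses;
all entry points accept larger values.

## Known limitations

* The contracted MLG mode is O(n²) per locus and intended for
  moderate sample sizes; the strict default is linear.
* r̄~D~ permutations recompute all pairwise distances per replicate;
  at 365 samples each replicate costs about a second, so very large
  permutation counts are better run on the clone-corrected table.
* F~ST~ is a Nei-style heterozygosity decomposition, not a
  variance-component estimator; values differ in the third decimal from
  Weir–Cockerham on balanced designs and more on unbalanced ones.
* The SSR scanner reports forward-strand motifs only; reverse-strand
  motifs appear as their forward-strand reading. Motifs are deliberately
  not canonicalised across rotations or complements, so AT and TA count
  separately, matching how marker-mining summaries are usually reported.
* Partial trailing repeats are truncated (integer repeat counts), and
  nested periodicities are resolved by a smallest-period rule; other
  scanners may tie-break differently at compound repeats.
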