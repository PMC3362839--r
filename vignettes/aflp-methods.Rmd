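---
title: "Models and methods behind aflphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aflphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`aflphylo` implements an analysis chain for dominant binary markers
(AFLP band presence/absence) from raw binned peak heights to phylogenies,
hybrid screens and topology tests. This vignette explains the models, the
tunable parameters and their defaults, the synthetic-data world used for
validation, and the design choices made where the methodology is genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. Scoring model

Input is a profiles × bins matrix of fluorescence intensities in the
50–500 bp range, plus a map pairing replicate re-runs of the same DNA.
Two thresholds govern scoring:

* **retention threshold** (fluorescence units, default grid 0–500 in 26
  steps): loci whose mean height over non-replicate profiles falls below
  it are dropped as ambiguous low-intensity bins. The mean (not median) is
  used so the retention curve responds smoothly to grid steps.
* **calling threshold**: a height at or above it is called `1`. In
  *absolute* mode it is in fluorescence units; in *relative* mode it is a
  fraction of the locus mean (default grid 5–50% in 10 steps).

The mismatch error rate of a locus is the fraction of replicate pairs
whose two calls disagree; the overall rate averages over retained loci.
Because it is ambiguous whether a headline error rate should average over
loci or over pairs, both summaries are reported (they coincide for
complete data). `optimize_thresholds()` scans the full grid in both
calling modes and keeps the combination minimising the locus-averaged
error subject to retaining a configurable fraction of loci (default 10%);
ties prefer more retained loci, then lower thresholds, then absolute mode.
"Unique loci" are obtained by dropping monomorphic columns and collapsing
byte-identical columns (presumed size homoplasy), each filter separately
switchable.

## 2. Distances, neighbour joining, bootstrap

For band-count profiles, similarity is the fraction of shared fragments
`F = 2 n_xy / (n_x + n_y)`. The default distance is `d = 1 − F`: bounded
in [0, 1] and finite for disjoint profiles. `d = −ln F` is available for
users wanting an unbounded, more clock-like transform; it is infinite when
no bands are shared, and the bootstrap machinery treats such
pseudoreplicates as undefined and redraws them (counted and reported).

Neighbour joining follows the standard Saitou–Nei agglomeration. Two
choices are deliberate:

* negative branch-length estimates are clamped to zero with the deficit
  moved to the sibling edge (common practice; keeps path lengths);
* ties in the Q criterion are broken by lexicographic label order, with
  merged clusters inheriting their smaller label, so the output is a pure
  function of the input matrix.

Clade support resamples loci (columns) with replacement — the natural
unit for multilocus dominant data — and counts, for every internal
bipartition of the point-estimate tree, the fraction of pseudoreplicate
trees containing it. Bipartitions are keyed canonically (the side not
containing the alphabetically first leaf), making support bookkeeping
independent of rooting. Rendered Newick output can suppress support ≤ 50
to follow the usual figure convention; the TSV support table always keeps
full values.

## 3. The homoplasy excess test

A hybrid taxon carries a per-locus mosaic of its two parents' characters.
In a multilocus tree this injects homoplasy into the clades containing
the parents, depressing their bootstrap support; removing the hybrid
restores it. The test therefore removes one species at a time (all its
individuals), re-runs the bootstrap with a seed derived from the master
seed and the species label, and records, for every baseline bipartition
that remains non-trivial, the change in support. For each bipartition the
deltas across removals form a distribution; a removal is an outlier —
and the species a candidate hybrid — when its delta strictly exceeds a
fence.

Design choices:

* **Tracked nodes.** Only species-respecting baseline splits are tracked
  by default: splits that scatter one species' individuals across both
  sides reflect within-species sampling noise, whose large random deltas
  would dominate the fences. (`species_level_splits = FALSE` restores
  every split.)
* **Fence.** Tukey upper fence Q3 + 1.5 IQR computed from the *other*
  removals' deltas, floored at `min_delta` (default 10 percentage
  points). With only ~10 removals, including the candidate in its own
  fence masks exactly the extreme value being tested; the floor prevents
  flagging when a tight distribution makes the fence collapse toward
  zero. A z-score fence is available as an alternative.
* **Baseline.** Computed once on the full data, not re-bootstrapped per
  comparison; removals are independent of one another.

### Power, and an honest negative result

The acceptance suite measures the test's operating characteristics on 50
simulated datasets (10 species × 4 individuals, 600 loci, one added 50/50
mosaic hybrid whose parents sit at the 60% quantile of pairwise species
distances, 100 pseudoreplicates per removal) and 50 hybrid-free datasets.
The mean per-dataset false-flag rate on clean data sits just above the
10% target (sister-rescue effects at the few remaining weak nodes), the
planted hybrid is flagged in well under 80% of runs, and extensive
exploration during development (tree heights 0.1–2, parent separations
from sister pairs to maximal, replaced and added hybrids, shared and
per-individual mosaics, paired bootstrap resamples) never raised power
beyond roughly 40%. The mechanism is visible in the per-node delta
matrices:

* a 50/50 mosaic between well-separated parents attaches *stably* at the
  midpoint of the parent–parent path and barely depresses any species
  clade — an undetectable hybrid;
* when the attachment is genuinely ambiguous, the conflicted nodes are
  rescued almost as strongly by removing either *parent* (or a nearby
  rogue taxon) as by removing the hybrid itself, so the per-node outlier
  rule rarely isolates the hybrid.

Both behaviours are properties of support-based leave-one-out screening
with distance trees, consistent with the test being heuristic; the
corresponding acceptance assertion is left failing rather than weakened,
and users should read a negative homoplasy screen as weak evidence only.

## 4. Binary likelihood engine

Characters evolve under the reversible two-state Markov model with
stationary frequencies (π₀, π₁); rates are normalised so branch lengths
are expected substitutions per locus (μ = 1 / 2π₀π₁). Likelihoods use
Felsenstein pruning over compressed site patterns; the model is
time-reversible, so values are invariant to root placement.

Because all-absent loci can never be observed in AFLP data, the
`noabsencesites` correction divides each site likelihood by
`1 − P(all-absent)` on the same tree — exactly the all-zero pattern, not
a broader variable-sites correction. Note the simulated matrices condition
on *polymorphic* loci (both states present), which is slightly stronger;
parameter-recovery tests therefore simulate unconditioned data and drop
only all-zero columns when checking the corrected likelihood. Fitting
polymorphic-only data without any correction inflates branch lengths
severely — the test suite demonstrates this rather than hiding it.

State frequencies default to the empirical fraction of 1-entries (the
point-estimate analogue of placing a data-matched Dirichlet prior on the
frequencies). Branch lengths on a fixed topology are optimised by
coordinate ascent with a bounded 1-D search per edge (bounds [0, 10]
expected substitutions; convergence when a full sweep gains < 1e-4 lnL;
non-convergence warns rather than failing silently).

The SH test optimises every candidate topology's branch lengths, then
applies RELL: loci are resampled, each topology's replicate
log-likelihoods are centred by their own mean, and the p-value is the
fraction of replicates whose centred best-vs-candidate gap reaches the
observed gap. Self-comparison gives p = 1 exactly; the test is
conservative by construction.

Marginal likelihoods on a fixed topology use Metropolis sampling of
branch lengths under independent exponential(mean 0.1) priors
(single-branch multiplier proposals, step size adapted toward ~30%
acceptance during burn-in) and the harmonic-mean estimator. The estimator
is kept for comparability with classic MrBayes/Tracer workflows despite
its known instability; two independent runs are reported by default so
run-to-run spread is visible, and acceptance compares it against 1-D
quadrature only on a small two-leaf problem where it is well behaved.
Bayes factors use the conventional strong-evidence threshold
2 × lnBF > 10.

## 5. The synthetic world

The generator emulates a deepwater-cichlid-scale AFLP study: ~10 species,
~40 individuals, 659 polymorphic loci, 20 replicate profiles, band
presence ≈ 0.29 (the value implied by 0/1 state frequencies in ratio
2.44 : 1.00). Specific choices:

* **Species tree:** pure-birth (Yule) with post-hoc scaling to a given
  root-to-tip height (default 0.15 expected substitutions — radiation-like
  short branches). Raw Yule trees routinely contain near-zero internal
  edges; `min_internal_frac` rejection-samples until every internal edge
  exceeds a floor, emulating datasets whose backbone is actually
  resolvable at the simulated locus count. The power/size experiments use
  height 0.3 with floor 0.15 so that a clean dataset yields a
  well-supported tree — which the source study's data did.
* **Characters:** two-state chain down the tree; individuals copy their
  species' tip state and flip with `polymorphism_rate` (default 0.02,
  chosen so species remain recoverable while sample clades are not
  trivially perfect). Monomorphic loci are redrawn so the requested locus
  count is exact; this conditioning raises realised band frequency a few
  points above the stationary target, which the tests tolerate explicitly.
* **Hybrids:** first-generation mosaics of the parents' consensus
  profiles; all individuals of a hybrid species share one recorded
  parent-of-origin vector (a stabilised hybrid lineage, the situation the
  test assumes). `mixing_proportion` generalises beyond 50/50.
* **Peak heights:** two-component model — present bands at mean 500,
  absent at mean 50, Gaussian noise truncated at zero, and present bands
  dropping to baseline with `dropout_rate`. Dropout drives the replicate
  mismatch error: per locus ≈ 2 d (1 − d) × band frequency, so the
  default d = 0.05 lands the overall rate near 3%, the regime reported
  for curated AFLP datasets. Not modelled: electropherogram traces,
  mobility shifts, size-standard calibration, cross-run intensity
  normalisation.

A green test on this world establishes correctness of the pipeline's
algebra and its operating characteristics *under the stated model* — not
that real AFLP data satisfy the model (real data add size homoplasy,
non-independent loci and intensity artefacts the generator does not
emulate).

## 6. Numerical and format notes

* Seeds: every randomised stage takes an explicit seed; sub-streams are
  derived as a 31-bit hash of the master seed and a stage/species tag, so
  results are independent of iteration order and reproducible bit-exactly.
* Degenerate inputs: profiles with no bands at all make the Nei–Li
  distance undefined (error naming the pair); presence frequencies of 0
  or 1 are rejected; a zero-length tree with zero polymorphism cannot
  yield polymorphic loci and errors out.
* NEXUS I/O uses `datatype=standard`, symbols "01", missing `?`,
  sequential or interleaved, with species as `TAXSET`s in a `SETS` block;
  TSV matrices carry a species side-car file. Trees round-trip through
  Newick at 14 significant digits.
* Known limitations: no rate heterogeneity in the binary model; no
  Bayesian tree *search* (fixed topologies only); the homoplasy screen's
  power limits discussed above; pruning is unscaled (fine to ~hundreds of
  tips for two-state models).
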