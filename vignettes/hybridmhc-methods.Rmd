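---
title: "Models and methods behind hybridmhc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridmhc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmhc)
```

# The analysis chain

`hybridmhc` implements the computational chain used to characterise
expressed MHC class IIB (*DAB*) diversity in two hybridizing cyprinoid
fish species and their F1 hybrids, and to relate that diversity to
ectoparasite communities:

1. **Genotyping** — validate true alleles from per-amplicon read-variant
   tallies under explicit artifact rules.
2. **Diversity** — allele counts, trans-species sharing partitions,
   expression summaries, Kruskal–Wallis group comparisons.
3. **Selection** — random-site codon models (M0, M1a, M2a, M3, M7, M8) on
   the allele alignment, likelihood-ratio tests, and Bayes empirical
   Bayes (BEB) detection of positively selected sites (PSS).
4. **Supertyping** — K-means clustering of alleles in a physicochemical
   descriptor space restricted to the PSS, with a BIC scan over the
   number of clusters, DAPC membership probabilities, and a
   run-to-run consistency filter.
5. **Co-inertia** — covariance between the MHC presence/absence matrix
   and the parasite abundance matrix, summarised by the RV coefficient
   with a Monte-Carlo permutation test.
6. **Association screens** — AICc backward-stepwise GLMs of parasite
   richness, abundance and prevalence on season, host group, allele
   counts, and individual allele or supertype presences.

A synthetic-data generator reproduces the statistical structure of every
input, so the full chain runs and is tested without any external data.

# The synthetic-data generator

`simulation_config()` fixes the study conditions. The defaults mirror the
field system the pipeline targets:

* **Host groups**: 109 bream-like, 97 roach-like, 88 F1 hybrids.
* **Allele pools**: 6 DAB1 + 24 DAB3 alleles for the less diverse
  species, 16 + 49 for the more diverse one; a `shared_fraction` of 0.15
  of each lineage's smaller pool is trans-species shared; hybrids can
  carry a small number of hybrid-only DAB3 alleles (default 6),
  reflecting that a noticeable minority of hybrid alleles is observed in
  neither parent.
* **Expression**: 1–5 expressed alleles per fish, drawn per lineage from
  truncated Poisson counts (λ = 0.7 for DAB1, 1.2 for DAB3) so DAB3
  dominates, matching the observed per-lineage ranges. Hybrid alleles
  come from the maternal pool with probability `maternal_bias`
  (default 0.55 — a slight maternal bias).
* **Amplicons**: two PCR replicates per specimen at read depth 300, with
  per-allele Dirichlet amplification skew (concentration 1.5) so that
  genuine alleles can sit at low within-amplicon frequency; each
  template read acquires one random base substitution with probability
  0.01 and becomes a single-breakpoint chimera of two co-amplified
  alleles with probability 0.02; 6.5% of specimens fail amplification
  entirely. Depth and error rates are not published for the original
  MiSeq data, so these are the package's own choices of a realistic
  amplicon regime, and all are configuration fields.
* **Parasites**: negative-binomial counts with log-scale structure —
  per-taxon, per-group autumn means patterned on the published
  infection table (host-specific monogeneans for each species plus
  generalist crustaceans, digeneans and an acanthocephalan), a spring
  multiplier (3 for ectoparasites, 1.5 for endoparasites; spring is the
  high-infection season) and dispersion 0.5. Named alleles can carry
  log-scale effects on named taxa (two defaults, one negative and one
  positive) so that the association screens have a recoverable ground
  truth.

Chimeras are single-breakpoint recombinants with the breakpoint uniform
over internal positions — the simplest mechanism that matches the
artifact class the genotyping rules target. All randomness flows from
one top-level seed through named substreams (`substream_seed()`), so each
stage is independently byte-reproducible.

**What the generator does not emulate**: read-level base qualities,
primer/adapter structure, chimeras spanning more than one breakpoint,
PCR-cycle-dependent error accumulation, linkage between loci, year
effects on parasites, and any population-genetic history of the hybrid
zone. Passing tests therefore demonstrate correctness of the algorithms
under the stated stochastic model, not robustness to every property of
real MiSeq data.

# Genotyping rules

For every distinct sequence variant the package computes the **maximum
per-amplicon frequency (MPAF)** — the highest share of any single
amplicon's reads the variant attains. The rule set, applied in order:

1. Amplicons under `min_coverage` reads (default 100) are dropped. The
   source workflows require "sufficient coverage" without quantifying
   it, so the floor is exposed as configuration.
2. Variants whose length differs from the reference length by a
   non-multiple of 3 (frameshift indels), variants with exactly one read
   in the whole data set (global singletons), and variants containing
   ambiguity codes are artifacts outright.
3. Variants with MPAF ≥ 5% are accepted.
4. A low-MPAF variant is checked per amplicon for two artifact
   mechanisms: a **1-bp substitution** derivative (an equal-length
   variant at Hamming distance exactly 1 at *strictly higher*
   within-amplicon frequency) and a **PCR chimera** (a single-breakpoint
   concatenation of two equal-length, strictly more abundant variants of
   the same amplicon).

The acceptance sentence for low-MPAF variants is grammatically ambiguous
in the literature this workflow derives from. The default reading
(`acceptance_rule = "fraction_unexplained"`) accepts a variant when it is
unexplainable as an artifact in at least 50% of the amplicons containing
it; the alternative (`"read_share"`) weights that fraction by the
variant's reads. Both are implemented; the default matches the
amplicon-replication logic of the workflow's ancestry (a real allele
recurs unexplained across amplicons, an artifact does not).

Further conventions: sequences are uppercased and U→T normalised before
comparison; frequency *ties never explain* a variant (conservative);
Hamming distance requires equal length, so 1-bp indels are not
substitution artifacts; chimera breakpoints are reported 1-based as the
last position inherited from the first parent. Raising the MPAF
threshold can only move variants from "accepted outright" into the
checked pool, so it never converts an artifact into a true allele.

# Diversity summaries

Allele "frequency" is **carrier frequency among expressing individuals**
(an expression data set cannot resolve copy number), with the
whole-group denominator available as an option. Per-individual
allele-count distributions are computed only over fish that expressed at
least one allele. The sharing partition classifies each allele by the
exact set of groups it occurs in; the identity
`total(g) = private(g) + pairwise-exclusive(g) + all-shared` is
fuzz-tested. Group comparisons use the tie-corrected Kruskal–Wallis H
test with Dunn's pairwise z comparisons; Bonferroni adjustment is the
default (the conventional companion when the post-hoc method is not
specified), with any `p.adjust` method accepted.

# Random-site codon models

The substitution process is GY94: single-nucleotide codon changes at
rate `pi_j * kappa^[transition] * omega^[nonsynonymous]`, reversible with
respect to the codon frequencies. Codon frequencies default to **F3x4**
(position-specific nucleotide frequencies), with Fequal, F1x4 and
empirical modes available — the conventional default where the original
setting is unstated, and a setting that materially affects PSS counts,
hence exposed.

Model structure: M0 (one ω), M1a (ω₀ < 1, ω₁ = 1), M2a (adds ω₂ ≥ 1),
M3 with K = 3 free classes, M7 (10 equal-probability beta categories,
category means), M8 (the same 10 beta categories plus one ω_s ≥ 1 class —
11 site classes in total). LRT pairs are M0/M3 (df 4), M1a/M2a (df 2)
and M7/M8 (df 2), with the statistic clamped at zero.

**Tree handling.** The fits take any user tree; `build_nj_tree()`
provides a neighbour-joining tree from Jukes–Cantor distances when none
is supplied (Bayesian tree inference is out of scope). Relative branch
lengths are fixed and a single tree-scale factor is estimated jointly
with the model parameters — full per-branch optimisation is deliberately
not attempted, trading a small likelihood loss for speed and stable
parameter recovery at these alignment sizes. Identical sequences remain
in the tree on zero-length branches. Rate matrices are normalised
PAML-style by the class-proportion-weighted mean rate, so relative rates
*between* site classes are preserved and branch lengths read as expected
substitutions per codon site under the fitted mixture.

**Numerics.** The pruning recursion is compiled (RcppArmadillo), with
per-node rescaling against underflow; transition probabilities come from
the eigendecomposition of the symmetrised generator (exact for a
reversible process), with negative rounding debris clamped and rows
renormalised. Alignment columns are compressed to unique site patterns.
Optimisation is bounded quasi-Newton (`nlminb`) on transformed
parameters — log for κ, ω and the tree scale, stick-breaking logistic for
class proportions — with a fixed default start plus seeded random
restarts (default 5), relative tolerance 1e-9, and transformed bounds at
±15. `m2a_init_from_m1a()` seeds the M2a start at the M1a optimum plus a
small positive class, roughly halving M2a cost in replicated
calibrations.

**BEB.** Site posteriors integrate over a uniform grid prior on the
mixture parameters with κ and branch lengths fixed at their MLEs
(the Yang–Wong–Nielsen scheme), 10 midpoints per dimension by default.
For M2a the grid covers the (p₀, p₁) simplex, ω₀ ∈ (0, 1) and
ω₂ ∈ (1, 11); for M8 it covers p₀ ∈ (0, 1), the beta shapes p, q ∈ (0, 2]
and ω_s ∈ (1, 11). Grid density is configurable; the exact published
settings are not printed in the sources this scheme descends from, so
the ranges above are the package's documented choice. PSS lists use
posterior probability 0.95 and 0.99; `PSS(0.99) ⊆ PSS(0.95)` by
construction. Per-group analyses are run on the pooled DAB1+DAB3 allele
set, with per-lineage runs available by subsetting.

# Supertyping

Alleles are encoded at the PSS positions by five z-scale physicochemical
descriptors per residue (hydrophilicity, steric bulk, polarity and two
electronic terms; table bundled and swappable), standardised by default —
whether the original workflow standardised is unstated, and
standardisation is the defensible default when descriptor scales differ.
K-means is scored by `BIC(k) = n·ln(W(k)/n) + k·d·ln(n)` (W = total
within-cluster sum of squares) because "change in BIC" is otherwise
ambiguous; the chosen k is the smallest k whose BIC decrease falls below
an elbow fraction (default 0.1) of the initial decrease. This penalty is
strong when the descriptor dimension is large relative to the number of
alleles — with few alleles the scan legitimately prefers small k — so
`supertype_alleles()` also accepts a fixed `k`. DAPC retains principal
components to 90% variance, then linear discriminant analysis yields
membership probabilities; a singular within-class scatter falls back to
a ridge-regularised equal-covariance classifier. Consistency across
repeated seeded K-means runs (labels aligned by greedy maximal overlap,
adequate and deterministic at k ≤ 15) removes alleles below 0.9
agreement. Supertype letters A, B, C… map to clusters by descending
size, ties broken by centroid lexicographic order, so downstream output
is invariant to K-means label permutations.

# Co-inertia analysis

The MHC presence/absence table is analysed by correspondence analysis
(chi-square metric on the doubly centred relative-frequency table); the
parasite abundance table by PCA **using the CA row weights**, centred
and by default unscaled (a correlation-metric option exists; abundances
enter untransformed by default, with `log1p` available, since no
transformation is specified in the workflow this mirrors). Co-inertia is
the SVD of the weighted cross-covariance of the two triplets; axis
eigenvalues are squared singular values and the RV coefficient is the
total co-inertia normalised by each table's self-co-structure norm, so
RV(X, X) = 1 and RV ∈ [0, 1].

The permutation test permutes **rows of the parasite table** while the
row weights stay attached to the MHC rows — the choice that preserves
the CA triplet — with `p = (1 + #(RV* ≥ RV)) / (n_perm + 1)` and 999
permutations by default. Presets restrict MHC columns to alleles carried
by at least 5 individuals and drop parasite taxa at or below 2%
prevalence in both parental groups. The implementation is verified in
the test suite against brute-force dense-matrix oracles and against the
independent `ade4` reference implementation.

# Association screens

Families follow the response type: Poisson for richness, negative
binomial (ML dispersion) for abundance, Bernoulli for prevalence. A
taxon is modelled as prevalence when its prevalence is ≤ 30% (a strict-<
mode exists because the two published statements of the rule disagree on
the boundary). Presence predictors require strictly more than 7 carriers
in the analysed group. Two deliberate simplifications replace the
original mixed-model machinery and are the package's documented
approximation: sampling **year enters as a fixed factor** instead of a
random intercept, and the **negative-binomial family replaces
observation-level random effects** as the overdispersion device. Tests
therefore target sign and retention recovery on synthetic data, not the
original coefficient values.

Backward selection drops, at each step, the removable term (interactions
before their main effects) with the lowest AICc, accepting the removal
when the reduced model's AICc is lower than or within 2 of the current
model's — the simpler model wins near-ties. A likelihood-ratio p value
accompanies every accepted removal as a supplementary, non-binding
criterion. Candidate ties within 1e-9 AICc resolve by larger p, then
lexicographically, for determinism. Bernoulli separation is detected
(divergent coefficients or non-convergence) and coefficients are then
re-estimated under a small ridge penalty, flagged in the output. A
Benjamini–Hochberg-adjusted p column is appended per series as a clearly
supplementary aid; the primary outputs are unadjusted, matching the
screening character of the analysis.

# Validation design

The test suite validates each stage against independent oracles: the
pruning likelihood against exhaustive enumeration of internal-node
states on 4-taxon, 5-codon instances (tolerance 1e-8 in log space, with
transition probabilities from `Matrix::expm` rather than the package's
eigen path); the chimera classifier against exhaustive breakpoint
enumeration; CA inertia against the direct chi-square formula; weighted
PCA against dense eigendecomposition; co-inertia against both a dense
SVD oracle and `ade4`; Kruskal–Wallis against the hand rank formula.

Calibration and recovery runs use problem sizes chosen to keep the whole
suite comfortably within a desktop coffee break while leaving no
tolerance slack to chance: ω recovery on 16 taxa × 500 codons (M0 within
±0.05, M2a positive-class ω within ±1.0 and proportion within ±0.05);
null calibration of the M1a-vs-M2a LRT on 200 replicates of 6 taxa × 50
codons (the mixture null sits on the parameter boundary, so the χ²
reference is conservative and the check is one-sided); RV null
calibration on 500 replicates of 50 × 6 vs 50 × 5 tables with 99
permutations each; genotyping precision and recall ≥ 0.95 on 200
specimens at depth 300 with substitution rate 0.01 and chimera rate
0.02; stepwise retention of a planted effect (log rate ratio 0.6,
n = 300, five noise predictors) across 200 replicates.

Two benchmark checks compare per-group M8 PSS counts and the BIC-optimal
supertype number against the published values for the deposited allele
set; they require the GenBank sequences (accessions MW737269–MW737373),
which the package neither redistributes nor downloads, and report a
clear failure message until a user supplies the FASTA under
`inst/extdata/genbank/`. The acceptance script runs the same machinery
on the synthetic stand-in pools, labelled as such.

# Known limitations

* Branch models, branch-site models, clade models, model averaging and
  recombination detection are out of scope.
* The fixed-topology, single-scale branch-length treatment understates
  uncertainty relative to full joint optimisation; PSS counts on real
  data are sensitive to the tree and the codon-frequency mode, so the
  package exposes both.
* The GLM screens are fixed-effect approximations of the original GLMMs
  (see above); with a single sampling year the year term drops out
  automatically.
* The BEB grids are the package's documented ranges; posterior
  probabilities near the 0.95 boundary can shift slightly with grid
  density.
* The supertype BIC penalty makes the elbow choice conservative for
  small allele sets in high descriptor dimensions.
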