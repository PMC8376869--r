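# hybridmhc

Analysis toolkit for expressed **MHC class IIB (*DAB*) amplicon data in a
two-species fish hybrid system** — two hybridizing cyprinoid species
(a bream-like and a roach-like host) and their F1 hybrids — and for
relating MHC diversity to ectoparasite communities. It is aimed at
molecular ecologists who genotype MHC by deep amplicon sequencing and
want the downstream statistics in one tested, scriptable package.

The pipeline covers:

* **Allele validation** from per-amplicon read-variant tallies. For each
  variant the *maximum per-amplicon frequency* MPAF = max over amplicons
  of (variant reads / amplicon reads) is computed; frameshift-length
  variants and global singletons are excluded; variants with MPAF ≥ 5%
  are accepted; lower-frequency variants must be unexplainable as 1-bp
  substitution or single-breakpoint PCR-chimera derivatives of more
  abundant variants in the same amplicon.
* **Diversity**: per-group allele totals, private/pairwise/all-shared
  trans-species sharing partitions, carrier frequencies, expression
  classes, and tie-corrected Kruskal–Wallis tests with Dunn post-hoc
  comparisons.
* **Positive selection**: random-site codon models on the allele
  alignment under the GY94 process
  (q<sub>ij</sub> = π<sub>j</sub>·κ<sup>[transition]</sup>·ω<sup>[nonsynonymous]</sup>),
  models M0, M1a, M2a, M3, M7 and M8 (10 beta categories + 1 positive
  class), likelihood-ratio tests (M0/M3, M1a/M2a, M7/M8), and Bayes
  empirical Bayes posterior probabilities identifying positively
  selected sites (posterior mean ω > 1).
* **Supertyping**: alleles encoded by five z-scale physicochemical
  descriptors at the selected sites, K-means with a BIC scan over k,
  DAPC membership probabilities, and a clustering-consistency filter.
* **Co-inertia analysis**: correspondence analysis of the MHC
  presence/absence table, row-weighted PCA of the parasite table, SVD of
  the weighted cross-covariance, and the RV coefficient
  (RV ∈ [0, 1], RV(X, X) = 1) with a 999-permutation Monte-Carlo test.
* **Association screens**: Poisson / negative-binomial / Bernoulli GLMs
  of parasite richness, abundance and prevalence with AICc backward
  stepwise selection (ΔAICc < 2 prefers the simpler model).
* A **synthetic-data generator** that emulates every input — species
  allele pools with trans-species sharing, maternally biased F1
  genotypes, error- and chimera-contaminated amplicons, and seasonal
  negative-binomial parasite communities — so the whole chain runs
  without external data.

## Worked example

```r
library(hybridmhc)

cfg   <- simulation_config(seed = 2026)   # the default study conditions
study <- simulate_mhc_study(cfg)

geno <- validate_alleles(study$amplicons$amplicons,
                         roster = unique(study$genotypes$individual))
geno
#> <mhc_genotyping> 77 true alleles / 3567 variants; 275 specimens
#> genotyped; 19 without amplification

allele_counts(study$genotypes)$per_individual
#> # A tibble: 3 × 6
#>   group      n  mean    sd   min   max
#> 1 bream    109  2.27  1.07     1     5
#> 2 hybrid    88  2.15  1.12     1     5
#> 3 roach     97  2.21  1.08     1     5

kruskal_allele_counts(study$genotypes, lineage = "DAB3")
#> Kruskal-Wallis H = 0.9852  df = 2  p = 0.611

coia <- mhc_parasite_coinertia(study$genotypes, study$parasites,
                               n_perm = 999, seed = 2026)
coia
#> <mhc_coinertia> 280 individuals, 41 MHC columns x 9 parasite taxa
#>   RV = 0.0779  p = 0.009  ( 999 permutations )
```

Reading the output: the generator contaminated 275 amplifiable
specimens' reads with 1-bp PCR errors and chimeras, and the MPAF rule
set recovered 77 true alleles out of 3,567 observed variants. Allele
counts per fish are statistically indistinguishable between groups here
(H ≈ 0.99, p ≈ 0.6) because the default generator draws all groups from
the same count distribution. The co-inertia RV of 0.078 is small but
significant (permutation p ≈ 0.009): host-specific parasite taxa and
species-specific alleles covary across the two parental species, which
is exactly the co-structure the default simulation plants.

Site-model scans work the same way on any codon alignment:

```r
tr  <- simulate_tree(16, seed = 1)
sim <- evolve_codon_alignment(tr,
         data.frame(prop = c(0.9, 0.1), omega = c(0.2, 4)),
         n_codons = 300, seed = 1)
f7  <- fit_site_model(sim$aln, tr, "M7")
f8  <- fit_site_model(sim$aln, tr, "M8")
lrt(f7, f8)                      # 2Δℓ, df = 2, p
beb <- beb_site_posteriors(f8)   # per-site P(positive), mean ω, PSS lists
autoplot(beb)
```

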