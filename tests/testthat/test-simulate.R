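# Synthetic-data generator: structure, truth closure, determinism.

test_that("simulate_tree produces valid deterministic trees", {
  expect_error(simulate_tree(2), "at least 3")
  t3 <- simulate_tree(3, seed = 1)
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(t3$Nnode, 1)

  a <- ape::write.tree(simulate_tree(20, seed = 1))
  b <- ape::write.tree(simulate_tree(20, seed = 1))
  expect_identical(a, b)
  tr <- simulate_tree(20, seed = 2)
  expect_true(is.finite(sum(tr$edge.length)) && sum(tr$edge.length) > 0)
  expect_true(ape::is.binary(tr))
})

test_that("codon evolution respects class structure", {
  tr <- simulate_tree(10, seed = 2, mean_branch = 0.3)
  # degenerate case: zero codons
  empty <- evolve_codon_alignment(tr, data.frame(prop = 1, omega = 1),
                                  n_codons = 0, seed = 1)
  expect_equal(empty$aln$n_codons, 0L)

  expect_error(evolve_codon_alignment(
    tr, data.frame(prop = c(0.5, 0.4), omega = c(1, 2)), n_codons = 5),
    "sum to 1")

  # neutral single class: syn/nonsyn single-step difference counts along
  # one short branch match the matrix-exponential expectation (counting
  # estimator of dN/dS = 1 once normalised by the neutral flux ratio)
  aa <- translate_codons(sense_codons())
  codons <- sense_codons()
  pi_u <- rep(1 / 61, 61)
  P <- as.matrix(Matrix::expm(codon_rate_matrix(2, 1, pi_u) * 0.05))
  nonsyn <- outer(aa, aa, "!=")
  nt_diff <- function(a, b) sum(strsplit(a, "")[[1]] !=
                                  strsplit(b, "")[[1]])
  D1 <- outer(codons, codons, Vectorize(nt_diff)) == 1
  theory <- sum((pi_u * P)[D1 & nonsyn]) / sum((pi_u * P)[D1 & !nonsyn])
  star <- ape::read.tree(text = "(a:0.05,b:0.0001,c:0.0001);")
  simn <- evolve_codon_alignment(star, data.frame(prop = 1, omega = 1),
                                 kappa = 2, n_codons = 20000, seed = 3)
  cm <- simn$aln$codons
  ia <- which(simn$aln$taxa == "a"); ib <- which(simn$aln$taxa == "b")
  syn <- nsyn <- 0
  for (s in which(cm[ia, ] != cm[ib, ])) {
    if (D1[cm[ia, s], cm[ib, s]]) {
      if (aa[cm[ia, s]] == aa[cm[ib, s]]) syn <- syn + 1 else {
        nsyn <- nsyn + 1
      }
    }
  }
  expect_gt(nsyn / syn, 0.8 * theory)
  expect_lt(nsyn / syn, 1.2 * theory)

  # two classes: high-omega sites accumulate more nonsynonymous difference
  sim2 <- evolve_codon_alignment(
    tr, data.frame(prop = c(0.9, 0.1), omega = c(0.1, 4)),
    kappa = 2, n_codons = 500, seed = 4)
  cm2 <- sim2$aln$codons
  nonsyn_per_site <- vapply(seq_len(ncol(cm2)), function(s) {
    states <- cm2[, s]
    prs <- utils::combn(length(states), 2)
    mean(apply(prs, 2, function(p) {
      states[p[1]] != states[p[2]] &&
        aa[states[p[1]]] != aa[states[p[2]]]
    }))
  }, numeric(1))
  hi <- nonsyn_per_site[sim2$site_class == 2]
  lo <- nonsyn_per_site[sim2$site_class == 1]
  expect_gt(mean(hi), mean(lo) * 2)
})

test_that("allele pools encode the configured sharing structure", {
  cfg <- small_config(seed = 5)
  pools <- simulate_allele_pools(cfg)
  # every allele belongs to at least one species or is hybrid-novel
  expect_true(all(pools$bream | pools$roach | pools$hybrid_novel))
  expect_true(all(pools$lineage %in% c("DAB1", "DAB3")))

  for (ln in c("DAB1", "DAB3")) {
    nb <- cfg$pool_sizes$bream[[ln]]; nr <- cfg$pool_sizes$roach[[ln]]
    n_shared <- round(cfg$shared_fraction * min(nb, nr))
    p <- pools[pools$lineage == ln, ]
    expect_equal(sum(p$bream & p$roach), n_shared)
    expect_equal(sum(p$bream), nb)
    expect_equal(sum(p$roach), nr)
    expect_equal(sum(p$hybrid_novel), cfg$hybrid_novel[[ln]])
  }

  # shared fraction zero: pools fully private
  cfg0 <- small_config(seed = 5, shared_fraction = 0)
  p0 <- simulate_allele_pools(cfg0)
  expect_equal(sum(p0$bream & p0$roach), 0)

  # determinism
  expect_identical(simulate_allele_pools(cfg)$sequence, pools$sequence)
})

test_that("genotypes respect count ranges, pools and maternal bias", {
  cfg <- small_config(seed = 6)
  pools <- simulate_allele_pools(cfg)
  g <- simulate_genotypes(pools, cfg)
  counts <- table(g$individual)
  expect_true(all(counts >= cfg$allele_count_range[1] &
                    counts <= cfg$allele_count_range[2]))

  # parental alleles come from the right pool; hybrids from the union
  for (grp in c("bream", "roach")) {
    al <- unique(g$allele[g$group == grp])
    expect_true(all(al %in% pools$allele[pools[[grp]]]))
  }
  hyb <- unique(g$allele[g$group == "hybrid"])
  expect_true(all(hyb %in% pools$allele))

  # range (1,1) forces singleton genotypes
  cfg1 <- small_config(seed = 6, allele_count_range = c(1, 1))
  g1 <- simulate_genotypes(simulate_allele_pools(cfg1), cfg1)
  expect_true(all(table(g1$individual) == 1))

  # maternal bias: at weight 0.5 the maternal share is ~0.5 (binomial MC)
  cfg5 <- simulation_config(
    n_individuals = c(bream = 1, roach = 1, hybrid = 2000),
    pool_sizes = list(bream = c(DAB1 = 20, DAB3 = 20),
                      roach = c(DAB1 = 20, DAB3 = 20)),
    hybrid_novel = c(DAB1 = 0, DAB3 = 0), hybrid_novel_rate = 0,
    maternal_bias = 0.5, seq_length_codons = 20, seed = 7)
  g5 <- simulate_genotypes(simulate_allele_pools(cfg5), cfg5)
  mat <- g5$maternal_copy[g5$group == "hybrid"]
  n <- length(mat)
  expect_gt(n, 2000)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(mat) - 0.5), 5 * se)
})

test_that("amplicons carry labelled artifacts with valid provenance", {
  cfg <- small_config(seed = 8)
  pools <- simulate_allele_pools(cfg)
  g <- simulate_genotypes(pools, cfg)
  sim <- simulate_amplicons(g, pools, cfg)
  expect_true(all(sim$truth$provenance %in%
                    c("true", "substitution_error", "chimera")))
  # truth closure: every emitted variant has exactly one provenance row
  expect_equal(anyDuplicated(sim$truth$variant_id), 0)
  expect_true(all(sim$amplicons$variant_id %in% sim$truth$variant_id))

  # chimeric variants reconstruct from two co-amplified true variants
  chim <- sim$truth$sequence[sim$truth$provenance == "chimera"]
  expect_gt(length(chim), 0)
  amp_split <- split(sim$amplicons,
                     paste(sim$amplicons$specimen,
                           sim$amplicons$replicate))
  checked <- 0
  for (cs in utils::head(chim, 5)) {
    for (a in amp_split) {
      if (cs %in% a$sequence && nrow(a) >= 3) {
        truth_here <- a[a$sequence %in%
                          sim$truth$sequence[sim$truth$provenance ==
                                               "true"], ]
        found <- FALSE
        L <- nchar(cs)
        for (p1 in truth_here$sequence) {
          for (p2 in truth_here$sequence) {
            if (p1 == p2) next
            for (b in seq_len(L - 1)) {
              if (paste0(substr(p1, 1, b),
                         substr(p2, b + 1, L)) == cs) {
                found <- TRUE; break
              }
            }
            if (found) break
          }
          if (found) break
        }
        if (found) checked <- checked + 1
        break
      }
    }
  }
  expect_gt(checked, 0)

  # zero error rates: observed variant set equals the carried allele set
  cfg0 <- small_config(seed = 8, substitution_rate = 0,
                       chimera_rate = 0, no_amplification_rate = 0)
  pools0 <- simulate_allele_pools(cfg0)
  g0 <- simulate_genotypes(pools0, cfg0)
  s0 <- simulate_amplicons(g0, pools0, cfg0)
  expect_setequal(unique(s0$amplicons$sequence),
                  unique(pools0$sequence[pools0$allele %in% g0$allele]))

  # byte-level determinism
  s0b <- simulate_amplicons(g0, pools0, cfg0)
  expect_identical(s0$amplicons, s0b$amplicons)
})

test_that("parasite counts carry the configured seasonal and NB structure", {
  cfg <- small_config(seed = 9)
  g <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  p <- simulate_parasites(g, cfg)
  taxa <- attr(p, "taxa")
  expect_true(all(vapply(taxa$taxon, function(tx) {
    all(p[[tx]] >= 0 & p[[tx]] == round(p[[tx]]))
  }, logical(1))))

  # all-zero means give an all-zero matrix
  taxa0 <- taxa
  taxa0$mean_bream <- taxa0$mean_roach <- taxa0$mean_hybrid <- 0
  cfg0 <- small_config(seed = 9, parasite_taxa = taxa0)
  p0 <- simulate_parasites(g, cfg0)
  expect_true(all(as.matrix(p0[, taxa0$taxon]) == 0))

  # spring/autumn ratio recovery by NB GLM refit at large n
  cfgbig <- simulation_config(
    n_individuals = c(bream = 500, roach = 1, hybrid = 1),
    pool_sizes = list(bream = c(DAB1 = 4, DAB3 = 8),
                      roach = c(DAB1 = 4, DAB3 = 8)),
    allele_effects = tibble::tibble(allele = character(),
                                    taxon = character(),
                                    beta = numeric()),
    seq_length_codons = 20, seed = 10)
  pb <- simulate_parasites(simulate_genotypes(
    simulate_allele_pools(cfgbig), cfgbig), cfgbig)
  fit <- MASS::glm.nb(Argulus_gen ~ season,
                      data = pb[pb$group == "bream", ])
  spring_ratio <- exp(-coef(fit)[["seasonspring"]])  # autumn baseline
  mult <- attr(pb, "taxa")$spring_multiplier[
    attr(pb, "taxa")$taxon == "Argulus_gen"]
  expect_lt(abs(log(1 / spring_ratio) - log(mult)), 0.35)

  # method-of-moments dispersion recovery at n = 1000
  cfgd <- simulation_config(
    n_individuals = c(bream = 1000, roach = 1, hybrid = 1),
    pool_sizes = list(bream = c(DAB1 = 4, DAB3 = 8),
                      roach = c(DAB1 = 4, DAB3 = 8)),
    allele_effects = tibble::tibble(allele = character(),
                                    taxon = character(),
                                    beta = numeric()),
    seq_length_codons = 20, seed = 11)
  pd <- simulate_parasites(simulate_genotypes(
    simulate_allele_pools(cfgd), cfgd), cfgd)
  aut <- pd$Ergasilus_gen[pd$group == "bream" & pd$season == "autumn"]
  m <- mean(aut); v <- var(aut)
  size_hat <- m^2 / (v - m)
  expect_lt(abs(size_hat - 0.5), 0.2)
})

test_that("the full study simulation is reproducible end to end", {
  cfg <- small_config(seed = 12)
  a <- simulate_mhc_study(cfg)
  b <- simulate_mhc_study(cfg)
  expect_identical(a$pools, b$pools)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$amplicons$amplicons, b$amplicons$amplicons)
  expect_identical(a$parasites, b$parasites)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(shared_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(allele_count_range = c(0, 5)),
               "within \\[1, 5\\]")
  expect_error(simulation_config(bogus_field = 1), "unknown configuration")
  taxa <- hybridmhc:::.default_parasite_taxa()
  taxa$dispersion <- 0
  expect_error(simulation_config(parasite_taxa = taxa), "dispersion")
})
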