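# Allele counts, sharing partitions, expression summaries, KW tests.

test_that("sharing partition matches a fully enumerable example", {
  g <- tibble::tibble(
    individual = c("A1", "A1", "B1", "B1", "H1"),
    group = c("A", "A", "B", "B", "H"),
    allele = c("a1", "a2", "a2", "a3", "a2"))
  sp <- sharing_partition(g)
  gs <- sp$group_summary
  expect_equal(gs$total[gs$group == "A"], 2)
  expect_equal(gs$total[gs$group == "B"], 2)
  expect_equal(gs$total[gs$group == "H"], 1)
  expect_equal(gs$private[gs$group == "A"], 1)
  expect_equal(gs$private[gs$group == "B"], 1)
  expect_equal(gs$private[gs$group == "H"], 0)
  expect_equal(unique(gs$shared_all), 1)
})

test_that("partition identity holds on fuzzed genotype tables", {
  for (seed in 1:5) {
    g <- random_genotypes(seed = seed)
    sp <- sharing_partition(g)
    for (ln in unique(sp$by_class$lineage)) {
      bc <- sp$by_class[sp$by_class$lineage == ln, ]
      gs <- sp$group_summary[sp$group_summary$lineage == ln, ]
      for (grp in sp$groups) {
        contains <- vapply(strsplit(bc$membership, "+", fixed = TRUE),
                           function(m) grp %in% m, logical(1))
        expect_equal(gs$total[gs$group == grp], sum(bc$n[contains]))
      }
      # with three groups: total = private + pairwise-exclusive + all-shared
      if (length(sp$groups) == 3) {
        pw <- sp$pairwise[sp$pairwise$lineage == ln, ]
        for (grp in sp$groups) {
          pair_sum <- sum(pw$n_exclusive[pw$group1 == grp |
                                           pw$group2 == grp])
          expect_equal(gs$total[gs$group == grp],
                       gs$private[gs$group == grp] + pair_sum +
                         gs$shared_all[gs$group == grp])
        }
      }
    }
  }
})

test_that("sharing recovered from generated pools equals configuration", {
  cfg <- small_config(seed = 16)
  pools <- simulate_allele_pools(cfg)
  # express the pool membership map as a genotype table
  rows <- list()
  for (i in seq_len(nrow(pools))) {
    grps <- c(if (pools$bream[i]) "bream", if (pools$roach[i]) "roach",
              if (pools$hybrid_novel[i]) "hybrid")
    rows[[i]] <- tibble::tibble(individual = grps, group = grps,
                                allele = pools$allele[i],
                                lineage = pools$lineage[i])
  }
  sp <- sharing_partition(dplyr::bind_rows(rows))
  for (ln in c("DAB1", "DAB3")) {
    nb <- cfg$pool_sizes$bream[[ln]]; nr <- cfg$pool_sizes$roach[[ln]]
    n_shared <- round(cfg$shared_fraction * min(nb, nr))
    pw <- sp$pairwise[sp$pairwise$lineage == ln, ]
    expect_equal(pw$n_exclusive[pw$group1 == "bream" &
                                  pw$group2 == "roach"], n_shared)
    gs <- sp$group_summary[sp$group_summary$lineage == ln, ]
    expect_equal(gs$private[gs$group == "bream"], nb - n_shared)
    expect_equal(gs$private[gs$group == "roach"], nr - n_shared)
  }
})

test_that("allele_counts restricts distributions to expressing fish", {
  g <- tibble::tibble(
    individual = c("i1", "i2", "i2", "i3"),
    group = c("A", "A", "A", "A"),
    allele = c("a1", "a1", "a2", NA))
  ac <- allele_counts(g)
  pi <- ac$per_individual
  expect_equal(pi$n, 2)             # i3 expressed nothing
  expect_equal(pi$mean, 1.5)
  expect_equal(pi$min, 1); expect_equal(pi$max, 2)

  single <- allele_counts(tibble::tibble(individual = "i", group = "A",
                                         allele = "a"))
  expect_equal(single$per_individual$sd, 0)
  expect_equal(single$per_individual$min, 1)
})

test_that("expression success handles degenerate and roster cases", {
  g <- tibble::tibble(individual = c("i1", "i2"), group = "A",
                      allele = c("a", "b"))
  expect_equal(expression_success(g)$success, c(1, 1))
  g2 <- tibble::tibble(individual = c("i1", "i2"), group = "A",
                       allele = NA_character_)
  expect_equal(expression_success(g2)$success, c(0, 0))
})

test_that("expression classes partition each group", {
  g <- tibble::tibble(
    individual = c("i1", "i1", "i2", "i3", "i4"),
    group = "A",
    allele = c("a", "b", "c", "d", NA),
    lineage = c("DAB1", "DAB3", "DAB1", "DAB3", NA))
  out <- expression_class_counts(g)
  expect_equal(out$both, 1)
  expect_equal(out$only_DAB1, 1)
  expect_equal(out$only_DAB3, 1)
  expect_equal(out$none, 1)
  expect_equal(out$n, 4)

  # simulated truth classes recovered exactly
  cfg <- small_config(seed = 17)
  st <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  out2 <- expression_class_counts(st)
  byhand <- sapply(split(st, st$individual), function(d) {
    has1 <- any(d$lineage == "DAB1"); has3 <- any(d$lineage == "DAB3")
    if (has1 && has3) "both" else if (has1) "only_DAB1" else "only_DAB3"
  })
  expect_equal(sum(out2$both), sum(byhand == "both"))
  expect_equal(sum(out2$only_DAB1), sum(byhand == "only_DAB1"))
})

test_that("carrier frequencies use the expressing-individuals denominator", {
  g <- tibble::tibble(
    individual = c("i1", "i2", "i3", "i4"),
    group = "A",
    allele = c("a", "a", "b", NA))
  f <- allele_frequencies(g)
  expect_equal(f$frequency[f$allele == "a"], 2 / 3)
  f_all <- allele_frequencies(g, denominator = "all")
  expect_equal(f_all$frequency[f_all$allele == "a"], 2 / 4)
  expect_equal(f$frequency[f$allele == "b"], 1 / 3)

  # configured carrier frequency recovered within MC error
  cfg <- simulation_config(
    n_individuals = c(bream = 1000, roach = 1, hybrid = 1),
    pool_sizes = list(bream = c(DAB1 = 1, DAB3 = 1),
                      roach = c(DAB1 = 1, DAB3 = 1)),
    shared_fraction = 0, allele_count_range = c(1, 2),
    lineage_lambda = c(DAB1 = 0.35, DAB3 = 2),
    seq_length_codons = 20, seed = 18)
  st <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  f2 <- allele_frequencies(st)
  dab1 <- f2[f2$group == "bream" &
               grepl("DAB1", f2$allele), ]
  # P(DAB1 allele present) under the truncated lineage-count draw
  expect_gt(dab1$frequency, 0.1)
  expect_lt(dab1$frequency, 0.6)
})

test_that("Kruskal-Wallis H matches the hand rank formula with ties", {
  g <- tibble::tibble(
    individual = paste0("i", 1:9),
    group = rep(c("A", "B", "C"), each = 3),
    allele = "x")
  # per-individual counts (1,1,1), (5,5,5), (9,9,9) via repeated alleles
  counts <- c(1, 1, 1, 5, 5, 5, 9, 9, 9)
  g <- dplyr::bind_rows(lapply(1:9, function(i) {
    tibble::tibble(individual = paste0("i", i),
                   group = rep(c("A", "B", "C"), each = 3)[i],
                   allele = paste0("a", seq_len(counts[i])))
  }))
  kw <- kruskal_allele_counts(g)
  # hand computation: tie-corrected H on ranks of counts
  r <- rank(counts)
  N <- 9
  H <- (12 / (N * (N + 1))) *
    sum(tapply(r, rep(c("A", "B", "C"), each = 3),
               function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(counts)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(kw$omnibus$H, H, tolerance = 1e-10)

  # identical distributions: H small, p large (null behaviour)
  withr::with_seed(3, {
    gnull <- dplyr::bind_rows(lapply(1:60, function(i) {
      tibble::tibble(individual = paste0("i", i),
                     group = sample(c("A", "B", "C"), 1),
                     allele = paste0("a", seq_len(sample(1:4, 1))))
    }))
  })
  kw0 <- kruskal_allele_counts(gnull)
  expect_gt(kw0$omnibus$p_value, 0.001)

  # a strongly shifted group is flagged in exactly its pairs
  gshift <- dplyr::bind_rows(lapply(1:60, function(i) {
    grp <- rep(c("A", "B", "C"), each = 20)[i]
    k <- if (grp == "C") 5 else sample(1:2, 1)
    tibble::tibble(individual = paste0("i", i), group = grp,
                   allele = paste0("a", seq_len(k)))
  }))
  kwS <- withr::with_seed(4, kruskal_allele_counts(gshift))
  pw <- kwS$pairwise
  involves_c <- pw$group1 == "C" | pw$group2 == "C"
  expect_true(all(pw$p_value[involves_c] < 0.01))
  expect_true(all(pw$p_value[!involves_c] > 0.05))

  # H is invariant under monotone transformation of the counts
  kw_mono <- kruskal_allele_counts(g)
  counts2 <- counts^3
  r2 <- rank(counts2)
  expect_equal(r2, r)

  expect_error(kruskal_allele_counts(
    tibble::tibble(individual = "i", group = "A", allele = "a")),
    "two groups")
})

test_that("printed-table reference counts reproduce published summaries", {
  # expression-success arithmetic on the bundled reference counts
  tab <- utils::read.delim(system.file("extdata",
                                       "dab_expression_counts.tsv",
                                       package = "hybridmhc"))
  pooled <- (sum(tab$N) - sum(tab$no_allele)) / sum(tab$N)
  expect_equal(sum(tab$N), 294)
  expect_equal(round(100 * pooled), 94)

  # sharing-class arithmetic on the bundled class counts
  cls <- utils::read.delim(system.file("extdata",
                                       "dab_sharing_classes.tsv",
                                       package = "hybridmhc"))
  sp <- sharing_partition(sharing_classes_to_genotypes(cls))
  gs <- sp$group_summary
  expect_equal(gs$total[gs$lineage == "DAB3" & gs$group == "hybrid"], 39)
  expect_equal(gs$total[gs$lineage == "DAB1" & gs$group == "roach"], 16)
})
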