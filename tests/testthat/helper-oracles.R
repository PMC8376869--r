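# Shared fixtures and independent oracles used across test files.

# brute-force codon-alignment log-likelihood by exhaustive enumeration of
# internal-node states (matrix-exponential transition probabilities via
# Matrix::expm, independent of the package's eigen path)
brute_force_loglik <- function(aln, tree, kappa, omega, freqs,
                               scale = 1) {
  tree <- stats::reorder(ape::unroot(tree), "postorder")
  Q <- codon_rate_matrix(kappa, omega, freqs, scale = FALSE)
  mu <- attr(Q, "mean_rate")
  Pm <- lapply(tree$edge.length * scale / mu, function(t) {
    as.matrix(Matrix::expm(Q * t))
  })
  tips <- aln$codons[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  internals <- (n_tip + 1):max(tree$edge)
  sapply(seq_len(ncol(tips)), function(s) {
    grid <- do.call(expand.grid,
                    rep(list(seq_along(freqs)), length(internals)))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      asg <- integer(max(tree$edge))
      asg[seq_len(n_tip)] <- tips[, s]
      asg[internals] <- as.integer(unlist(grid[g, ]))
      pr <- freqs[asg[root]]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * Pm[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
      }
      tot <- tot + pr
    }
    log(tot)
  })
}

# exhaustive single-breakpoint chimera oracle
chimera_oracle <- function(sequence, amplicon) {
  amp <- amplicon
  amp$freq <- amp$reads / sum(amp$reads)
  own <- amp$freq[match(sequence, amp$sequence)]
  L <- nchar(sequence)
  cand <- amp$sequence[nchar(amp$sequence) == L & amp$freq > own &
                         amp$sequence != sequence]
  for (p1 in cand) {
    for (p2 in cand) {
      if (p1 == p2) next
      for (b in seq_len(L - 1)) {
        if (paste0(substr(p1, 1, b), substr(p2, b + 1, L)) == sequence) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# chi-square total inertia of a contingency table, direct formula
chisq_inertia_oracle <- function(x) {
  x <- as.matrix(x)
  P <- x / sum(x)
  r <- rowSums(P); c <- colSums(P)
  E <- r %o% c
  sum((P - E)^2 / E)
}

# small amplicon tibble builder
amp_tbl <- function(specimen, replicate, seqs, reads) {
  tibble::tibble(specimen = specimen, replicate = replicate,
                 sequence = seqs, reads = reads)
}

# small, fast simulation configuration shared by several tests
small_config <- function(seed = 42, ...) {
  simulation_config(
    n_individuals = c(bream = 25, roach = 25, hybrid = 20),
    pool_sizes = list(bream = c(DAB1 = 4, DAB3 = 10),
                      roach = c(DAB1 = 6, DAB3 = 14)),
    hybrid_novel = c(DAB1 = 0, DAB3 = 2),
    seq_length_codons = 60,
    seed = seed, ...)
}

# random tidy genotype table for fuzz tests
random_genotypes <- function(n_ind = 30, n_allele = 12, seed = 1) {
  withr::with_seed(seed, {
    groups <- sample(c("bream", "roach", "hybrid"), n_ind, replace = TRUE)
    rows <- lapply(seq_len(n_ind), function(i) {
      k <- sample(0:4, 1)
      if (k == 0) {
        return(tibble::tibble(individual = paste0("i", i),
                              group = groups[i], allele = NA_character_,
                              lineage = NA_character_))
      }
      al <- sample(paste0("a", seq_len(n_allele)), k)
      tibble::tibble(individual = paste0("i", i), group = groups[i],
                     allele = al,
                     lineage = ifelse(as.integer(sub("a", "", al)) %%
                                        2 == 0, "DAB3", "DAB1"))
    })
    dplyr::bind_rows(rows)
  })
}
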