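# Study-level synthetic data: two species-specific allele pools with
# partial trans-species sharing across two gene lineages, F1 genotypes with
# maternal bias, amplicon reads contaminated by 1-bp PCR errors and
# single-breakpoint chimeras, and seasonal, group-structured, negative-
# binomially dispersed parasite communities.

.default_parasite_taxa <- function() {
  tibble::tibble(
    taxon = c("Dactylogyrus_bre1", "Dactylogyrus_bre2",
              "Dactylogyrus_roa1", "Dactylogyrus_roa2",
              "Gyrodactylus_gen", "Ergasilus_gen", "Argulus_gen",
              "Diplostomum_gen", "Neoechinorhynchus_gen"),
    taxon_group = c(rep("Monogenea", 5), "Crustacea", "Crustacea",
                    "Digenea", "Acanthocephala"),
    host_specificity = c("bream", "bream", "roach", "roach", "generalist",
                         "generalist", "generalist", "generalist",
                         "generalist"),
    mean_bream = c(16.7, 16.3, 0, 0, 1.4, 4.3, 3.0, 1.1, 0.05),
    mean_roach = c(0, 0, 39.3, 7.8, 0.5, 0.24, 0.5, 0.85, 0.35),
    mean_hybrid = c(0.01, 0.01, 3.7, 2.0, 0.1, 7.6, 1.1, 1.4, 0.04),
    spring_multiplier = c(3, 3, 3, 3, 3, 3, 3, 1.5, 1.5),
    dispersion = 0.5)
}

.default_allele_effects <- function() {
  tibble::tibble(
    allele = c("Ruru-DAB1*01", "Ruru-DAB3*01"),
    taxon = c("Dactylogyrus_roa2", "Argulus_gen"),
    beta = c(-0.8, 0.8))
}

#' Configuration for the synthetic MHC study generator
#'
#' Defaults mirror the structure of the field study the pipeline targets:
#' three host groups of roughly a hundred fish each, species allele pools
#' of 6/24 (bream DAB1/DAB3) and 16/49 (roach) with partial trans-species
#' sharing, 1-5 expressed alleles per fish, a slight maternal expression
#' bias in F1 hybrids, two PCR replicates of depth 300 with 1-bp
#' substitution and chimera artifacts, and a seasonal, group-structured
#' negative-binomial parasite community with host-specific monogeneans and
#' generalist taxa.
#'
#' @param ... Named overrides of any default field.
#' @return A validated `mhc_sim_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_individuals = c(bream = 109, roach = 97, hybrid = 88),
    pool_sizes = list(bream = c(DAB1 = 6, DAB3 = 24),
                      roach = c(DAB1 = 16, DAB3 = 49)),
    shared_fraction = 0.15,
    hybrid_novel = c(DAB1 = 0, DAB3 = 6),
    hybrid_novel_rate = 0.15,
    allele_count_range = c(1, 5),
    lineage_lambda = c(DAB1 = 0.7, DAB3 = 1.2),
    maternal_bias = 0.55,
    allele_weight_concentration = 0.8,
    allele_weights = NULL,
    n_replicates = 2,
    read_depth = 300,
    substitution_rate = 0.01,
    chimera_rate = 0.02,
    skew_concentration = 1.5,
    seq_length_codons = 90,
    no_amplification_rate = 0.065,
    years = 1:3,
    parasite_taxa = .default_parasite_taxa(),
    allele_effects = .default_allele_effects(),
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  probs <- c(cfg$shared_fraction, cfg$maternal_bias, cfg$substitution_rate,
             cfg$chimera_rate, cfg$no_amplification_rate,
             cfg$hybrid_novel_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  if (cfg$shared_fraction >= 1) stop("shared_fraction must be < 1")
  r <- cfg$allele_count_range
  if (length(r) != 2 || r[1] < 1 || r[2] > 5 || r[1] > r[2]) {
    stop("allele_count_range must lie within [1, 5]")
  }
  if (any(cfg$parasite_taxa$dispersion <= 0)) {
    stop("negative-binomial dispersion must be positive")
  }
  if (any(unlist(cfg$pool_sizes) < 1)) {
    stop("allele pool sizes must be positive")
  }
  structure(cfg, class = "mhc_sim_config")
}

# random allele sequence: mutate an ancestor, avoiding stops and duplicates
.mutate_sequence <- function(ancestor, n_sub, existing) {
  tab <- .codon_tables()
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  repeat {
    s <- strsplit(ancestor, "")[[1]]
    pos <- sample.int(length(s), n_sub)
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    seq <- paste(s, collapse = "")
    cds <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
    if (!any(cds %in% stops) && !(seq %in% existing)) {
      return(seq)
    }
  }
}

#' Simulate species allele pools with trans-species sharing
#'
#' Each gene lineage (DAB1, DAB3) gets an ancestor sequence; alleles are
#' mutated copies. The shared-pool size per lineage is
#' `round(shared_fraction * min(pool sizes))`; shared alleles count toward
#' both species' pools and are named with the cross-species prefix
#' (`Arbr-`), private alleles with `Abbr-`/`Ruru-`. Hybrid-only alleles are
#' appended per `hybrid_novel`.
#'
#' @param config An `mhc_sim_config`.
#' @return Tibble: `allele`, `lineage`, `sequence`, logical membership
#'   columns `bream`, `roach`, `hybrid_novel`, and per-species sampling
#'   weights `weight_bream`, `weight_roach`.
#' @export
simulate_allele_pools <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mhc_sim_config"))
  .with_substream(config$seed, "pools", {
    tab <- .codon_tables()
    L <- config$seq_length_codons * 3
    rows <- list()
    for (lineage in c("DAB1", "DAB3")) {
      nb <- config$pool_sizes$bream[[lineage]]
      nr <- config$pool_sizes$roach[[lineage]]
      n_shared <- round(config$shared_fraction * min(nb, nr))
      n_novel <- config$hybrid_novel[[lineage]]
      ancestor <- paste(sample(tab$codons, config$seq_length_codons,
                               replace = TRUE), collapse = "")
      n_total <- (nb - n_shared) + (nr - n_shared) + n_shared + n_novel
      seqs <- character(0)
      for (i in seq_len(n_total)) {
        seqs <- c(seqs, .mutate_sequence(ancestor, max(2, rpois_min(L)),
                                         seqs))
      }
      kinds <- c(rep("shared", n_shared), rep("bream", nb - n_shared),
                 rep("roach", nr - n_shared), rep("novel", n_novel))
      prefix <- c(shared = "Arbr", bream = "Abbr", roach = "Ruru",
                  novel = "Arbr")
      num <- stats::ave(seq_along(kinds), kinds, FUN = seq_along)
      name <- sprintf("%s-%s*%02d", prefix[kinds], lineage,
                      ifelse(kinds == "novel", 50 + num, num))
      rows[[lineage]] <- tibble::tibble(
        allele = name, lineage = lineage, sequence = seqs,
        bream = kinds %in% c("shared", "bream"),
        roach = kinds %in% c("shared", "roach"),
        hybrid_novel = kinds == "novel")
    }
    pools <- dplyr::bind_rows(rows)
    # per-species carrier-frequency weights (Dirichlet draw or override)
    for (sp in c("bream", "roach")) {
      w <- rep(NA_real_, nrow(pools))
      idx <- which(pools[[sp]])
      if (!is.null(config$allele_weights[[sp]])) {
        w[idx] <- config$allele_weights[[sp]]
      } else {
        g <- stats::rgamma(length(idx), config$allele_weight_concentration)
        w[idx] <- g / sum(g)
      }
      pools[[paste0("weight_", sp)]] <- w
    }
    pools
  })
}

# helper: small positive Poisson-ish substitution count scaled to length
rpois_min <- function(L) stats::rpois(1, L * 0.04)

#' Simulate per-individual genotypes
#'
#' Parental fish draw alleles from their species pool (weighted, without
#' replacement); hybrids draw each allele from the maternal pool with
#' probability `maternal_bias`, otherwise the paternal pool, and may carry
#' hybrid-only alleles. Per-individual totals are constrained to
#' `allele_count_range`.
#'
#' @param pools Output of [simulate_allele_pools()].
#' @param config An `mhc_sim_config`.
#' @return Long tibble: `individual`, `group`, `season`, `year`,
#'   `maternal_line`, `allele`, `lineage`, `maternal_copy` (for hybrids,
#'   whether the allele came from the maternal pool).
#' @export
simulate_genotypes <- function(pools, config = simulation_config()) {
  stopifnot(inherits(config, "mhc_sim_config"))
  if (!nrow(pools)) stop("allele pools are empty")
  r <- config$allele_count_range
  if (r[1] > sum(config$hybrid_novel) +
        min(vapply(config$pool_sizes, sum, numeric(1)))) {
    stop("requested allele count exceeds pool size")
  }
  .with_substream(config$seed, "genotypes", {
    out <- list()
    for (group in names(config$n_individuals)) {
      n <- config$n_individuals[[group]]
      if (n == 0) next
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", group, i)
        season <- sample(c("spring", "autumn"), 1)
        year <- sample(config$years, 1)
        maternal <- if (group == "hybrid") {
          sample(c("bream", "roach"), 1)
        } else {
          group
        }
        # per-lineage counts, redrawn until the total is in range
        repeat {
          k <- vapply(c("DAB1", "DAB3"), function(ln) {
            stats::rpois(1, config$lineage_lambda[[ln]])
          }, numeric(1))
          if (sum(k) >= r[1] && sum(k) <= r[2]) break
        }
        recs <- list()
        for (ln in c("DAB1", "DAB3")) {
          if (k[[ln]] == 0) next
          if (group != "hybrid") {
            pool <- pools[pools[[group]] & pools$lineage == ln, ]
            kk <- min(k[[ln]], nrow(pool))
            if (kk == 0) next
            pick <- sample.int(nrow(pool), kk,
                               prob = pool[[paste0("weight_", group)]])
            recs[[ln]] <- tibble::tibble(allele = pool$allele[pick],
                                         lineage = ln,
                                         maternal_copy = NA)
          } else {
            paternal <- setdiff(c("bream", "roach"), maternal)
            chosen <- character(0); from_mat <- logical(0)
            for (j in seq_len(k[[ln]])) {
              use_mat <- stats::runif(1) < config$maternal_bias
              sp <- if (use_mat) maternal else paternal
              pool <- pools[pools[[sp]] & pools$lineage == ln &
                              !(pools$allele %in% chosen), ]
              if (!nrow(pool)) next
              pick <- sample.int(nrow(pool), 1,
                                 prob = pool[[paste0("weight_", sp)]])
              chosen <- c(chosen, pool$allele[pick])
              from_mat <- c(from_mat, use_mat)
            }
            if (length(chosen)) {
              recs[[ln]] <- tibble::tibble(allele = chosen, lineage = ln,
                                           maternal_copy = from_mat)
            }
          }
        }
        g <- dplyr::bind_rows(recs)
        # occasional hybrid-only allele
        if (group == "hybrid" && nrow(g) < r[2] &&
            any(pools$hybrid_novel) &&
            stats::runif(1) < config$hybrid_novel_rate) {
          nov <- pools[pools$hybrid_novel &
                         !(pools$allele %in% g$allele), ]
          if (nrow(nov)) {
            pick <- sample.int(nrow(nov), 1)
            g <- dplyr::bind_rows(g, tibble::tibble(
              allele = nov$allele[pick], lineage = nov$lineage[pick],
              maternal_copy = NA))
          }
        }
        if (!nrow(g)) next
        g$individual <- id; g$group <- group; g$season <- season
        g$year <- year; g$maternal_line <- maternal
        out[[id]] <- g
      }
    }
    dplyr::select(dplyr::bind_rows(out), "individual", "group", "season",
                  "year", "maternal_line", "allele", "lineage",
                  "maternal_copy")
  })
}

#' Simulate amplicon read-variant tallies
#'
#' For each specimen and PCR replicate, template reads are multinomial over
#' the specimen's true alleles with Dirichlet amplification skew; a
#' fraction of reads acquire one random base substitution and a fraction
#' become single-breakpoint chimeras of two co-amplified alleles. A
#' configurable fraction of specimens fails amplification entirely.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param pools Output of [simulate_allele_pools()].
#' @param config An `mhc_sim_config`.
#' @return List: `amplicons` (tibble `specimen`, `replicate`, `variant_id`,
#'   `sequence`, `reads`), `truth` (tibble `variant_id`, `sequence`,
#'   `provenance` in true/substitution_error/chimera), and
#'   `failed_specimens`.
#' @export
simulate_amplicons <- function(genotypes, pools,
                               config = simulation_config()) {
  stopifnot(inherits(config, "mhc_sim_config"), config$read_depth >= 1)
  seqs <- stats::setNames(pools$sequence, pools$allele)
  .with_substream(config$seed, "amplicons", {
    specimens <- unique(genotypes$individual)
    n_fail <- round(config$no_amplification_rate * length(specimens))
    failed <- if (n_fail > 0) sample(specimens, n_fail) else character(0)
    bases <- c("A", "C", "G", "T")
    var_seq <- character(0)          # global sequence -> id registry
    var_prov <- character(0)
    register <- function(sq, prov) {
      i <- match(sq, var_seq)
      if (is.na(i)) {
        var_seq <<- c(var_seq, sq)
        var_prov <<- c(var_prov, prov)
        i <- length(var_seq)
      } else if (prov == "true" && var_prov[i] != "true") {
        var_prov[i] <<- "true"
      }
      i
    }
    for (a in pools$allele) register(seqs[[a]], "true")

    rows <- list()
    for (sp in setdiff(specimens, failed)) {
      alleles <- genotypes$allele[genotypes$individual == sp]
      asq <- seqs[alleles]
      L <- nchar(asq[1])
      for (rep_i in seq_len(config$n_replicates)) {
        g <- stats::rgamma(length(alleles), config$skew_concentration)
        reads <- as.vector(stats::rmultinom(1, config$read_depth,
                                            g / sum(g)))
        tally <- new.env(parent = emptyenv())
        add <- function(sq, n) {
          if (n <= 0) return(invisible())
          k <- as.character(register(sq, "pending"))
          tally[[k]] <- (if (is.null(tally[[k]])) 0 else tally[[k]]) + n
        }
        for (ai in seq_along(alleles)) {
          r <- reads[ai]
          n_sub <- stats::rbinom(1, r, config$substitution_rate)
          n_chi <- if (length(alleles) >= 2) {
            stats::rbinom(1, r - n_sub, config$chimera_rate)
          } else {
            0
          }
          add(asq[ai], r - n_sub - n_chi)
          for (k in seq_len(n_sub)) {
            s <- strsplit(asq[ai], "")[[1]]
            p <- sample.int(L, 1)
            s[p] <- sample(setdiff(bases, s[p]), 1)
            sq <- paste(s, collapse = "")
            i <- register(sq, "pending")
            if (var_prov[i] == "pending") var_prov[i] <- "substitution_error"
            add(sq, 1)
          }
          for (k in seq_len(n_chi)) {
            cands <- setdiff(seq_along(alleles), ai)
            other <- cands[sample.int(length(cands), 1, prob = g[cands])]
            b <- sample.int(L - 1, 1)
            sq <- paste0(substr(asq[ai], 1, b),
                         substr(asq[other], b + 1, L))
            i <- register(sq, "pending")
            if (var_prov[i] == "pending") var_prov[i] <- "chimera"
            add(sq, 1)
          }
        }
        ks <- ls(tally)
        idx <- as.integer(ks)
        rows[[paste(sp, rep_i)]] <- tibble::tibble(
          specimen = sp, replicate = rep_i,
          sequence = var_seq[idx],
          reads = vapply(ks, function(k) tally[[k]], numeric(1)))
      }
    }
    var_prov[var_prov == "pending"] <- "substitution_error"
    ids <- sprintf("V%05d", seq_along(var_seq))
    amplicons <- dplyr::bind_rows(rows)
    amplicons$variant_id <- ids[match(amplicons$sequence, var_seq)]
    amplicons <- dplyr::select(amplicons, "specimen", "replicate",
                               "variant_id", "sequence", "reads")
    truth <- tibble::tibble(variant_id = ids, sequence = var_seq,
                            provenance = var_prov)
    # true alleles never observed are not part of the read universe
    observed <- truth$variant_id %in% amplicons$variant_id |
      truth$provenance == "true"
    list(amplicons = amplicons, truth = truth[observed, ],
         failed_specimens = failed)
  })
}

#' Simulate parasite abundance matrix
#'
#' Negative-binomial counts with log-scale group, season, and
#' allele-presence effects. Taxon means are autumn means; spring means are
#' multiplied by the taxon's `spring_multiplier`.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config An `mhc_sim_config`.
#' @return Wide tibble `individual`, `group`, `season`, `year`, then one
#'   abundance column per taxon. The attribute `"truth"` carries the
#'   generating coefficients, `"taxa"` the taxon metadata.
#' @export
simulate_parasites <- function(genotypes, config = simulation_config()) {
  stopifnot(inherits(config, "mhc_sim_config"))
  taxa <- config$parasite_taxa
  eff <- config$allele_effects
  meta <- dplyr::distinct(genotypes, .data$individual, .data$group,
                          .data$season, .data$year)
  .with_substream(config$seed, "parasites", {
    m <- matrix(0L, nrow(meta), nrow(taxa),
                dimnames = list(meta$individual, taxa$taxon))
    for (j in seq_len(nrow(taxa))) {
      base <- c(bream = taxa$mean_bream[j], roach = taxa$mean_roach[j],
                hybrid = taxa$mean_hybrid[j])[meta$group]
      mult <- ifelse(meta$season == "spring", taxa$spring_multiplier[j], 1)
      mu <- base * mult
      ej <- eff[eff$taxon == taxa$taxon[j], ]
      if (nrow(ej)) {
        for (k in seq_len(nrow(ej))) {
          carriers <- unique(
            genotypes$individual[genotypes$allele == ej$allele[k]])
          has <- meta$individual %in% carriers
          mu <- mu * exp(ej$beta[k] * has)
        }
      }
      cnt <- integer(nrow(meta))
      pos <- mu > 0
      cnt[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                                 size = taxa$dispersion[j])
      m[, j] <- cnt
    }
    out <- dplyr::bind_cols(meta, tibble::as_tibble(m))
    attr(out, "truth") <- eff
    attr(out, "taxa") <- taxa
    out
  })
}

#' Run the full synthetic study
#'
#' @param config An `mhc_sim_config`.
#' @return List with `pools`, `genotypes`, `amplicons` (list as returned by
#'   [simulate_amplicons()]), `parasites`, and `config`.
#' @export
simulate_mhc_study <- function(config = simulation_config()) {
  pools <- simulate_allele_pools(config)
  genotypes <- simulate_genotypes(pools, config)
  amplicons <- simulate_amplicons(genotypes, pools, config)
  parasites <- simulate_parasites(genotypes, config)
  list(pools = pools, genotypes = genotypes, amplicons = amplicons,
       parasites = parasites, config = config)
}
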