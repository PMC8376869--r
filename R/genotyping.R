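# Allele validation from per-amplicon read-variant tallies.
#
# An "amplicon" is one specimen x replicate read set. Artifact rules follow
# the amplicon-genotyping workflow for multi-locus MHC data: global
# singletons and frameshift-length variants are excluded outright; variants
# with a maximum per-amplicon frequency (MPAF) below the threshold must be
# unexplainable as 1-bp substitution or PCR-chimera derivatives of more
# abundant variants in the same amplicon to be accepted.

.normalize_seq <- function(x) chartr("Uu", "Tt", toupper(x))

.has_ambiguity <- function(x) grepl("[^ACGT]", x)

#' Tally variants and compute maximum per-amplicon frequency
#'
#' @param amplicons Tibble with columns `specimen`, `replicate`,
#'   `variant_id` (optional; derived from sequences when absent),
#'   `sequence`, `reads`.
#' @return Tibble with one row per distinct sequence: `variant_id`,
#'   `sequence`, `total_reads`, `n_amplicons`, `mpaf`.
#' @export
tally_and_mpaf <- function(amplicons) {
  stopifnot(all(c("specimen", "replicate", "sequence", "reads") %in%
                  names(amplicons)))
  amplicons$sequence <- .normalize_seq(amplicons$sequence)
  totals <- dplyr::summarise(
    dplyr::group_by(amplicons, .data$specimen, .data$replicate),
    amp_total = sum(.data$reads), .groups = "drop")
  if (any(totals$amp_total <= 0)) {
    bad <- totals[totals$amp_total <= 0, ]
    stop("empty amplicon(s): ",
         paste(bad$specimen, bad$replicate, sep = "/", collapse = ", "))
  }
  x <- dplyr::mutate(
    dplyr::group_by(amplicons, .data$specimen, .data$replicate),
    freq = .data$reads / sum(.data$reads))
  x <- dplyr::ungroup(x)
  rec <- dplyr::summarise(
    dplyr::group_by(x, .data$sequence),
    total_reads = sum(.data$reads),
    n_amplicons = dplyr::n(),
    mpaf = max(.data$freq), .groups = "drop")
  if ("variant_id" %in% names(amplicons)) {
    rec$variant_id <- amplicons$variant_id[match(rec$sequence,
                                                 amplicons$sequence)]
  } else {
    rec$variant_id <- sprintf("V%05d", seq_len(nrow(rec)))
  }
  dplyr::select(rec, "variant_id", "sequence", "total_reads",
                "n_amplicons", "mpaf")
}

#' Flag frameshift-length and global-singleton variants
#'
#' A variant is flagged `frameshift_indel` when its length differs from
#' the reference length by a non-multiple of 3, and `global_singleton`
#' when it carries exactly one read across the entire data set.
#'
#' @param records Output of [tally_and_mpaf()].
#' @param ref_length Reference sequence length defining the reading frame;
#'   defaults to the read-weighted modal variant length.
#' @return `records` with logical columns `frameshift_indel`,
#'   `global_singleton`, `ambiguous`.
#' @export
prefilter_variants <- function(records, ref_length = NULL) {
  len <- nchar(records$sequence)
  if (is.null(ref_length)) {
    w <- tapply(records$total_reads, len, sum)
    ref_length <- as.integer(names(w)[which.max(w)])
  }
  records$frameshift_indel <- (abs(len - ref_length) %% 3) != 0
  records$global_singleton <- records$total_reads == 1
  records$ambiguous <- .has_ambiguity(records$sequence)
  attr(records, "ref_length") <- ref_length
  records
}

# within-amplicon frequency table for one amplicon
.amp_freqs <- function(amplicon) {
  amplicon$freq <- amplicon$reads / sum(amplicon$reads)
  amplicon
}

#' One-base substitution artifact test
#'
#' A variant is explainable as a 1-bp substitution artifact in a given
#' amplicon when an equal-length variant at Hamming distance exactly 1
#' exists in the same amplicon at strictly higher within-amplicon
#' frequency. Frequency ties do not explain a variant.
#'
#' @param sequence The candidate variant's sequence.
#' @param amplicon Tibble of one amplicon's tallies (`sequence`, `reads`).
#' @return Logical scalar.
#' @export
classify_substitution_artifact <- function(sequence, amplicon) {
  sequence <- .normalize_seq(sequence)
  amp <- .amp_freqs(amplicon)
  amp$sequence <- .normalize_seq(amp$sequence)
  own <- amp$freq[match(sequence, amp$sequence)]
  if (is.na(own)) stop("variant not present in the amplicon")
  cand <- amp[nchar(amp$sequence) == nchar(sequence) &
                amp$freq > own & amp$sequence != sequence, ]
  if (!nrow(cand)) return(FALSE)
  v <- utf8ToInt(sequence)
  any(vapply(cand$sequence, function(s) {
    sum(utf8ToInt(s) != v) == 1L
  }, logical(1)))
}

# longest common prefix / suffix length of two equal-length strings
.lcp <- function(a, b) {
  d <- which(utf8ToInt(a) != utf8ToInt(b))
  if (!length(d)) nchar(a) else d[1] - 1L
}
.lcs <- function(a, b) {
  d <- which(rev(utf8ToInt(a)) != rev(utf8ToInt(b)))
  if (!length(d)) nchar(a) else d[1] - 1L
}

#' PCR-chimera artifact test
#'
#' A variant is explainable as a chimera in a given amplicon when two
#' equal-length variants P1, P2 of the same amplicon, each at strictly
#' higher within-amplicon frequency, concatenate as
#' `P1[1..b] + P2[b+1..L]` for some internal breakpoint `b`, with the
#' variant differing from both parents. Breakpoints are reported 1-based:
#' `b` is the last position inherited from P1.
#'
#' @param sequence The candidate variant's sequence.
#' @param amplicon Tibble of one amplicon's tallies (`sequence`, `reads`).
#' @return List: `is_chimera`, and when `TRUE` also `breakpoint`,
#'   `parent1`, `parent2` for one witness decomposition.
#' @export
classify_chimera <- function(sequence, amplicon) {
  sequence <- .normalize_seq(sequence)
  amp <- .amp_freqs(amplicon)
  amp$sequence <- .normalize_seq(amp$sequence)
  own <- amp$freq[match(sequence, amp$sequence)]
  if (is.na(own)) stop("variant not present in the amplicon")
  L <- nchar(sequence)
  cand <- amp[nchar(amp$sequence) == L & amp$freq > own &
                amp$sequence != sequence, ]
  if (nrow(cand) < 2) return(list(is_chimera = FALSE))
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(cand))) {
      if (i == j) next
      p1 <- cand$sequence[i]; p2 <- cand$sequence[j]
      k1 <- .lcp(sequence, p1)      # prefix shared with P1
      k2 <- .lcs(sequence, p2)      # suffix shared with P2
      lo <- max(1L, L - k2)
      hi <- min(k1, L - 1L)
      if (lo <= hi) {
        return(list(is_chimera = TRUE, breakpoint = lo,
                    parent1 = p1, parent2 = p2))
      }
    }
  }
  list(is_chimera = FALSE)
}

#' Validate true alleles and emit per-specimen genotypes
#'
#' Applies the full rule set: amplicons below `min_coverage` are dropped;
#' frameshift-length, global-singleton and ambiguity-containing variants
#' are artifacts; variants with MPAF at or above `mpaf_threshold` are true
#' alleles; lower-frequency variants are accepted under the configured
#' acceptance rule. With `acceptance_rule = "fraction_unexplained"`
#' (default) a variant is accepted when the fraction of amplicons
#' containing it in which it is *not* explainable as a substitution or
#' chimera artifact is at least `acceptance_fraction`. With
#' `"read_share"`, the fraction is computed over the variant's reads
#' rather than its amplicons.
#'
#' @param amplicons Tibble `specimen`, `replicate`, `sequence`, `reads`
#'   (optionally `variant_id`).
#' @param mpaf_threshold MPAF above which a variant is accepted outright.
#' @param acceptance_rule `"fraction_unexplained"` or `"read_share"`.
#' @param acceptance_fraction Minimum unexplained fraction for acceptance.
#' @param min_coverage Minimum amplicon read total.
#' @param ref_length Passed to [prefilter_variants()].
#' @param roster Optional character vector of all specimens submitted for
#'   genotyping; those without any covered amplicon are reported in
#'   `no_amplification`.
#' @return List of class `mhc_genotyping`: `variants` (records with flags
#'   and final `status`), `alleles` (accepted sequences), `genotypes`
#'   (tibble `specimen`, `replicate`, `allele`), and `no_amplification`.
#' @export
validate_alleles <- function(amplicons, mpaf_threshold = 0.05,
                             acceptance_rule = c("fraction_unexplained",
                                                 "read_share"),
                             acceptance_fraction = 0.5,
                             min_coverage = 100, ref_length = NULL,
                             roster = NULL) {
  acceptance_rule <- match.arg(acceptance_rule)
  amplicons$sequence <- .normalize_seq(amplicons$sequence)
  amp_tot <- dplyr::summarise(
    dplyr::group_by(amplicons, .data$specimen, .data$replicate),
    amp_total = sum(.data$reads), .groups = "drop")
  covered <- amp_tot[amp_tot$amp_total >= min_coverage, ]
  amp <- dplyr::inner_join(amplicons, covered,
                           by = c("specimen", "replicate"))
  if (!nrow(amp)) stop("no amplicon reaches min_coverage = ", min_coverage)

  rec <- prefilter_variants(tally_and_mpaf(amp), ref_length = ref_length)
  rec$status <- NA_character_
  rec$status[rec$frameshift_indel | rec$global_singleton |
               rec$ambiguous] <- "artifact"
  rec$status[is.na(rec$status) & rec$mpaf >= mpaf_threshold] <- "true_allele"

  low <- which(is.na(rec$status))
  if (length(low)) {
    amp_split <- split(amp, paste(amp$specimen, amp$replicate, sep = "\r"))
    # precompute per-amplicon frequency tables once
    amp_split <- lapply(amp_split, .amp_freqs)
    for (ix in low) {
      sq <- rec$sequence[ix]
      unexplained <- numeric(0)
      weight <- numeric(0)
      for (a in amp_split) {
        pos <- match(sq, a$sequence)
        if (is.na(pos)) next
        expl <- classify_substitution_artifact(sq, a) ||
          classify_chimera(sq, a)$is_chimera
        unexplained <- c(unexplained, as.numeric(!expl))
        weight <- c(weight, a$reads[pos])
      }
      frac <- if (acceptance_rule == "fraction_unexplained") {
        mean(unexplained)
      } else {
        sum(weight * unexplained) / sum(weight)
      }
      rec$status[ix] <- if (frac >= acceptance_fraction) {
        "true_allele"
      } else {
        "artifact"
      }
    }
  }

  allele_seqs <- rec$sequence[rec$status == "true_allele"]
  geno <- dplyr::distinct(
    dplyr::filter(amp, .data$sequence %in% allele_seqs),
    .data$specimen, .data$replicate, .data$sequence)
  geno <- dplyr::rename(geno, allele = "sequence")
  geno$allele_id <- rec$variant_id[match(geno$allele, rec$sequence)]

  no_amp <- character(0)
  if (!is.null(roster)) {
    has_cov <- unique(covered$specimen)
    no_amp <- setdiff(roster, has_cov)
  }
  structure(list(variants = rec,
                 alleles = tibble::tibble(
                   allele_id = rec$variant_id[rec$status == "true_allele"],
                   sequence = allele_seqs),
                 genotypes = geno,
                 no_amplification = no_amp,
                 mpaf_threshold = mpaf_threshold,
                 acceptance_rule = acceptance_rule),
            class = "mhc_genotyping")
}

#' @export
print.mhc_genotyping <- function(x, ...) {
  cat("<mhc_genotyping> ", nrow(x$alleles), " true alleles / ",
      nrow(x$variants), " variants; ",
      length(unique(x$genotypes$specimen)), " specimens genotyped",
      if (length(x$no_amplification)) {
        paste0("; ", length(x$no_amplification), " without amplification")
      } else {
        ""
      }, "\n", sep = "")
  invisible(x)
}

#' Replicate concordance of genotype calls
#'
#' @param genotypes Tibble `specimen`, `replicate`, `allele` (as produced
#'   by [validate_alleles()]).
#' @param threshold Specimens with mean pairwise Jaccard concordance below
#'   this value are flagged.
#' @return Tibble: `specimen`, `n_replicates`, `concordance` (NA for
#'   unreplicated specimens), `flagged`.
#' @export
replicate_concordance <- function(genotypes, threshold = 0.5) {
  out <- lapply(split(genotypes, genotypes$specimen), function(g) {
    reps <- split(g$allele, g$replicate)
    n <- length(reps)
    cc <- if (n < 2) {
      NA_real_
    } else {
      prs <- utils::combn(n, 2)
      mean(apply(prs, 2, function(p) {
        a <- unique(reps[[p[1]]]); b <- unique(reps[[p[2]]])
        length(intersect(a, b)) / length(union(a, b))
      }))
    }
    tibble::tibble(specimen = g$specimen[1], n_replicates = n,
                   concordance = cc)
  })
  out <- dplyr::bind_rows(out)
  out$flagged <- !is.na(out$concordance) & out$concordance < threshold
  out
}

#' Assign alleles to gene lineages by exemplar identity
#'
#' Each allele is labelled with the lineage of its highest-identity
#' exemplar; exact ties between lineages are reported as `"unresolved"`.
#' Identity is computed from edit distance, so exemplars need not be
#' length-matched.
#'
#' @param sequences Named character vector of allele sequences.
#' @param exemplars Named character vector of exemplar sequences.
#' @param exemplar_lineages Character vector of lineage labels, parallel to
#'   `exemplars`.
#' @return Tibble `allele`, `lineage`, `identity`.
#' @export
assign_lineage <- function(sequences, exemplars, exemplar_lineages) {
  if (!length(exemplars)) stop("at least one exemplar per lineage required")
  stopifnot(length(exemplars) == length(exemplar_lineages))
  sequences <- .normalize_seq(sequences)
  exemplars <- .normalize_seq(exemplars)
  lineages <- unique(exemplar_lineages)
  d <- utils::adist(sequences, exemplars)
  ml <- pmax(outer(nchar(sequences), nchar(exemplars), pmax), 1)
  ident <- 1 - d / ml
  best_by_lineage <- vapply(lineages, function(l) {
    apply(ident[, exemplar_lineages == l, drop = FALSE], 1, max)
  }, numeric(length(sequences)))
  best_by_lineage <- matrix(best_by_lineage, nrow = length(sequences),
                            dimnames = list(NULL, lineages))
  lab <- apply(best_by_lineage, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1) "unresolved" else lineages[top]
  })
  tibble::tibble(allele = names(sequences) %||% as.character(sequences),
                 lineage = as.character(lab),
                 identity = apply(best_by_lineage, 1, max))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
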