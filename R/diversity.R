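# Allele counts, trans-species sharing partitions, expression summaries
# and nonparametric group comparisons.
#
# The tidy genotype format used throughout: one row per individual x
# allele, columns `individual`, `group`, `allele`, optionally `lineage`
# and further metadata. Individuals that expressed no allele appear with
# `allele = NA` so rosters stay complete.

.geno_check <- function(genotypes) {
  need <- c("individual", "group", "allele")
  miss <- setdiff(need, names(genotypes))
  if (length(miss)) {
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  genotypes
}

#' Trans-species allele sharing partition
#'
#' Classifies every allele by the exact set of groups it occurs in and
#' accumulates, per group (and lineage when available): the total allele
#' count, the private count, pairwise-exclusive shared counts, and the
#' all-groups shared count. The partition identity
#' `total(g) = sum of membership classes containing g` holds by
#' construction and is exposed for testing.
#'
#' @param genotypes Tidy genotype tibble (see package overview).
#' @return List of class `sharing_partition`: `by_class` (lineage,
#'   membership, n, alleles), `group_summary` (lineage, group, total,
#'   private, shared_all), `pairwise` (lineage, group1, group2,
#'   n_exclusive).
#' @export
sharing_partition <- function(genotypes) {
  g <- .geno_check(genotypes)
  g <- g[!is.na(g$allele), ]
  if (!"lineage" %in% names(g)) g$lineage <- "all"
  groups <- sort(unique(g$group))
  occ <- dplyr::distinct(g, .data$lineage, .data$allele, .data$group)
  by_allele <- dplyr::summarise(
    dplyr::group_by(occ, .data$lineage, .data$allele),
    membership = paste(sort(unique(.data$group)), collapse = "+"),
    .groups = "drop")
  by_class <- dplyr::summarise(
    dplyr::group_by(by_allele, .data$lineage, .data$membership),
    n = dplyr::n(), alleles = list(sort(.data$allele)), .groups = "drop")

  in_class <- function(cls, grp) grp %in% strsplit(cls, "+", fixed = TRUE)[[1]]
  gs <- do.call(rbind, lapply(unique(by_class$lineage), function(ln) {
    bc <- by_class[by_class$lineage == ln, ]
    do.call(rbind, lapply(groups, function(grp) {
      contains <- vapply(bc$membership, in_class, logical(1), grp = grp)
      data.frame(lineage = ln, group = grp,
                 total = sum(bc$n[contains]),
                 private = sum(bc$n[bc$membership == grp]),
                 shared_all = sum(bc$n[bc$membership ==
                                         paste(groups, collapse = "+")]))
    }))
  }))
  pw <- if (length(groups) < 2) {
    data.frame(lineage = character(), group1 = character(),
               group2 = character(), n_exclusive = numeric())
  } else {
    do.call(rbind, lapply(unique(by_class$lineage), function(ln) {
    bc <- by_class[by_class$lineage == ln, ]
    cmb <- utils::combn(groups, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      key <- paste(sort(cmb[, i]), collapse = "+")
      data.frame(lineage = ln, group1 = cmb[1, i], group2 = cmb[2, i],
                 n_exclusive = sum(bc$n[bc$membership == key]))
    }))
    }))
  }
  structure(list(by_class = tibble::as_tibble(by_class),
                 group_summary = tibble::as_tibble(gs),
                 pairwise = tibble::as_tibble(pw),
                 groups = groups),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat("<sharing_partition> groups:", paste(x$groups, collapse = ", "), "\n")
  print(x$group_summary)
  invisible(x)
}

#' Per-group allele counts and per-individual diversity
#'
#' Totals and private counts per group (overall and per lineage) plus the
#' per-individual allele-count distribution, computed only over
#' individuals expressing at least one allele.
#'
#' @param genotypes Tidy genotype tibble.
#' @return List of class `allele_counts`: `group_totals` (group, lineage,
#'   total, private), `per_individual` (group, n, mean, sd, min, max).
#' @export
allele_counts <- function(genotypes) {
  g <- .geno_check(genotypes)
  sp <- sharing_partition(g)
  expressed <- g[!is.na(g$allele), ]
  per_ind <- dplyr::summarise(
    dplyr::group_by(expressed, .data$group, .data$individual),
    k = dplyr::n_distinct(.data$allele), .groups = "drop")
  dist <- dplyr::summarise(
    dplyr::group_by(per_ind, .data$group),
    n = dplyr::n(), mean = mean(.data$k),
    sd = stats::sd(.data$k), min = min(.data$k), max = max(.data$k),
    .groups = "drop")
  dist$sd[is.na(dist$sd)] <- 0
  structure(list(group_totals = sp$group_summary,
                 per_individual = dist,
                 sharing = sp),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  print(x$group_totals)
  print(x$per_individual)
  invisible(x)
}

#' Genotyping / expression success rate
#'
#' @param genotypes Tidy genotype tibble in which failed specimens appear
#'   with `allele = NA` (or are listed in `roster` without genotype rows).
#' @param roster Optional character vector of all specimens; specimens
#'   absent from `genotypes` count as failures.
#' @return Tibble with one row per group plus a pooled row: `group`, `n`,
#'   `n_expressed`, `success`.
#' @export
expression_success <- function(genotypes, roster = NULL) {
  g <- .geno_check(genotypes)
  ind <- dplyr::summarise(
    dplyr::group_by(g, .data$group, .data$individual),
    expressed = any(!is.na(.data$allele)), .groups = "drop")
  if (!is.null(roster)) {
    extra <- setdiff(roster, ind$individual)
    if (length(extra)) {
      ind <- dplyr::bind_rows(ind, tibble::tibble(
        group = "unknown", individual = extra, expressed = FALSE))
    }
  }
  per <- dplyr::summarise(
    dplyr::group_by(ind, .data$group),
    n = dplyr::n(), n_expressed = sum(.data$expressed),
    success = mean(.data$expressed), .groups = "drop")
  pooled <- tibble::tibble(group = "pooled", n = sum(per$n),
                           n_expressed = sum(per$n_expressed),
                           success = sum(per$n_expressed) / sum(per$n))
  dplyr::bind_rows(per, pooled)
}

#' Expression-class counts per group
#'
#' Counts of specimens expressing no allele, only DAB1 alleles, only DAB3
#' alleles, or alleles of both lineages. The four classes partition each
#' group exactly.
#'
#' @param genotypes Tidy genotype tibble with a `lineage` column.
#' @return Tibble: `group`, `none`, `only_DAB1`, `only_DAB3`, `both`, `n`.
#' @export
expression_class_counts <- function(genotypes) {
  g <- .geno_check(genotypes)
  if (!"lineage" %in% names(g)) stop("lineage labels are required")
  cls <- dplyr::summarise(
    dplyr::group_by(g, .data$group, .data$individual),
    has1 = any(.data$lineage == "DAB1", na.rm = TRUE),
    has3 = any(.data$lineage == "DAB3", na.rm = TRUE), .groups = "drop")
  cls$class <- dplyr::case_when(
    cls$has1 & cls$has3 ~ "both",
    cls$has1 ~ "only_DAB1",
    cls$has3 ~ "only_DAB3",
    TRUE ~ "none")
  out <- tidyr::pivot_wider(
    dplyr::count(cls, .data$group, .data$class),
    names_from = "class", values_from = "n", values_fill = 0)
  for (col in c("none", "only_DAB1", "only_DAB3", "both")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out <- dplyr::select(out, "group", "none", "only_DAB1", "only_DAB3",
                       "both")
  out$n <- out$none + out$only_DAB1 + out$only_DAB3 + out$both
  out
}

#' Per-group allele carrier frequencies
#'
#' Frequency of each allele as the fraction of carriers among expressing
#' individuals of the group (the denominator can be switched to the whole
#' group).
#'
#' @param genotypes Tidy genotype tibble.
#' @param denominator `"expressing"` (default) or `"all"`.
#' @return Tibble: `group`, `allele`, `carriers`, `frequency`.
#' @export
allele_frequencies <- function(genotypes,
                               denominator = c("expressing", "all")) {
  denominator <- match.arg(denominator)
  g <- .geno_check(genotypes)
  denom <- dplyr::summarise(
    dplyr::group_by(g, .data$group),
    n_all = dplyr::n_distinct(.data$individual),
    n_expr = dplyr::n_distinct(.data$individual[!is.na(.data$allele)]),
    .groups = "drop")
  car <- dplyr::summarise(
    dplyr::group_by(g[!is.na(g$allele), ], .data$group, .data$allele),
    carriers = dplyr::n_distinct(.data$individual), .groups = "drop")
  car <- dplyr::left_join(car, denom, by = "group")
  car$frequency <- car$carriers /
    (if (denominator == "expressing") car$n_expr else car$n_all)
  dplyr::select(car, "group", "allele", "carriers", "frequency")
}

# tie-corrected Dunn post-hoc z statistics
.dunn_pairs <- function(x, g, p_adjust = "bonferroni") {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  cmb <- utils::combn(levels(g), 2)
  res <- apply(cmb, 2, function(p) {
    z <- (mr[[p[1]]] - mr[[p[2]]]) /
      sqrt(s2 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  tibble::tibble(group1 = cmb[1, ], group2 = cmb[2, ],
                 z = res["z", ],
                 p_value = stats::p.adjust(res["p", ], method = p_adjust))
}

#' Kruskal-Wallis comparison of per-individual allele counts
#'
#' Tie-corrected Kruskal-Wallis H test across host groups, followed by
#' Dunn's pairwise z comparisons with family-wise adjustment.
#'
#' @param genotypes Tidy genotype tibble.
#' @param lineage Optional lineage restriction (`"DAB1"` or `"DAB3"`).
#'   Individuals expressing no allele of the lineage count 0.
#' @param p_adjust Adjustment method for the pairwise comparisons
#'   (default `"bonferroni"`, per the standard companion to the H test;
#'   `"holm"` etc. also accepted).
#' @param expressing_only If `TRUE` (default), restrict to individuals
#'   expressing at least one allele overall.
#' @return List of class `kw_report`: `omnibus` (H, df, p) and `pairwise`.
#' @export
kruskal_allele_counts <- function(genotypes, lineage = NULL,
                                  p_adjust = "bonferroni",
                                  expressing_only = TRUE) {
  g <- .geno_check(genotypes)
  if (expressing_only) {
    keep <- unique(g$individual[!is.na(g$allele)])
    g <- g[g$individual %in% keep, ]
  }
  counts <- dplyr::summarise(
    dplyr::group_by(g, .data$group, .data$individual),
    k = if (is.null(lineage)) {
      sum(!is.na(.data$allele))
    } else {
      sum(.data$lineage == lineage, na.rm = TRUE)
    },
    .groups = "drop")
  if (dplyr::n_distinct(counts$group) < 2) {
    stop("need at least two groups")
  }
  if (any(table(counts$group) == 0)) stop("a group has no observations")
  kt <- stats::kruskal.test(counts$k, factor(counts$group))
  structure(list(
    omnibus = tibble::tibble(H = unname(kt$statistic),
                             df = unname(kt$parameter),
                             p_value = kt$p.value),
    pairwise = .dunn_pairs(counts$k, counts$group, p_adjust),
    counts = counts),
    class = "kw_report")
}

#' @export
print.kw_report <- function(x, ...) {
  cat("Kruskal-Wallis H =", signif(x$omnibus$H, 4),
      " df =", x$omnibus$df, " p =", signif(x$omnibus$p_value, 3), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Expand membership-class counts into a minimal genotype table
#'
#' Reference summaries of allele sharing are often published as counts of
#' alleles per group-membership class (private to one group, shared by a
#' pair, shared by all). This helper materialises such a table as a
#' minimal tidy genotype table (one pseudo-individual per group) so the
#' partition arithmetic can be recomputed and checked with
#' [sharing_partition()].
#'
#' @param classes Tibble with columns `lineage`, `membership` (group
#'   names joined by `+`), `n`.
#' @return Tidy genotype tibble (`individual`, `group`, `allele`,
#'   `lineage`).
#' @export
sharing_classes_to_genotypes <- function(classes) {
  rows <- list()
  aid <- 0
  for (i in seq_len(nrow(classes))) {
    groups <- strsplit(classes$membership[i], "+", fixed = TRUE)[[1]]
    for (j in seq_len(classes$n[i])) {
      aid <- aid + 1
      al <- sprintf("%s_%04d", classes$lineage[i], aid)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = groups, group = groups, allele = al,
        lineage = classes$lineage[i])
    }
  }
  dplyr::bind_rows(rows)
}
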