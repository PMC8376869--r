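# Co-inertia analysis between an MHC presence/absence table and a parasite
# abundance table: correspondence analysis of the genetic matrix, row-
# weighted PCA of the parasite matrix, SVD of the weighted cross-covariance,
# RV coefficient with a Monte-Carlo permutation test.
#
# Triplets follow the duality-diagram convention: a transformed table Z,
# a diagonal column metric Q and diagonal row weights D; the eigenvalues
# are the squared singular values of D^(1/2) Z Q^(1/2).

#' Filter parasite taxa by prevalence in the parental species
#'
#' A taxon is retained iff its prevalence exceeds `threshold` in at least
#' one of the `reference_groups`.
#'
#' @param parasites Wide tibble: `individual`, `group`, metadata, then one
#'   abundance column per taxon.
#' @param taxa Character vector of taxon columns (default: all numeric
#'   columns except metadata).
#' @param reference_groups The two parental groups used for the rule.
#' @param threshold Prevalence threshold (default 0.02).
#' @return `parasites` with failing taxon columns removed; removed taxa in
#'   the `"removed"` attribute.
#' @export
filter_parasites_by_prevalence <- function(parasites, taxa = NULL,
                                           reference_groups = c("bream",
                                                                "roach"),
                                           threshold = 0.02) {
  if (is.null(taxa)) taxa <- .parasite_taxa_cols(parasites)
  keep <- vapply(taxa, function(tx) {
    any(vapply(reference_groups, function(g) {
      v <- parasites[[tx]][parasites$group == g]
      length(v) > 0 && mean(v > 0) > threshold
    }, logical(1)))
  }, logical(1))
  out <- parasites[, c(setdiff(names(parasites), taxa), taxa[keep])]
  attr(out, "removed") <- taxa[!keep]
  out
}

.parasite_taxa_cols <- function(parasites) {
  meta <- c("individual", "group", "season", "year", "maternal_line")
  setdiff(names(parasites)[vapply(parasites, is.numeric, logical(1))],
          meta)
}

#' Correspondence analysis of a presence/absence table
#'
#' Chi-square-metric decomposition of the doubly centred relative
#' frequency table. All-zero rows and columns are dropped with a report.
#'
#' @param x Numeric matrix or data frame of nonnegative values (rows =
#'   individuals).
#' @return List of class `dudi_triplet` (`type = "coa"`): transformed
#'   table `tab`, row weights `lw`, column weights `cw`, `eigenvalues`,
#'   row and column scores of the retained axes, `inertia`.
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("correspondence analysis needs nonnegative input")
  rs <- rowSums(x); cs <- colSums(x)
  dropped_rows <- rownames(x)[rs == 0]
  dropped_cols <- colnames(x)[cs == 0]
  x <- x[rs > 0, cs > 0, drop = FALSE]
  n <- sum(x)
  if (n == 0) stop("table grand total is zero")
  P <- x / n
  r <- rowSums(P); c <- colSums(P)
  Z <- P / (r %o% c) - 1
  .triplet(Z, lw = r, cw = c, type = "coa",
           dropped = list(rows = dropped_rows, cols = dropped_cols))
}

#' Row-weighted principal component analysis
#'
#' Columns are centred (and optionally scaled) with the supplied row
#' weights; the decomposition uses the same weights, as required for
#' pairing with a correspondence analysis in co-inertia.
#'
#' @param x Numeric matrix or data frame.
#' @param row_w Row weights, nonnegative, summing to 1 (default uniform).
#' @param scale Scale columns to unit weighted variance.
#' @return List of class `dudi_triplet` (`type = "pca"`).
#' @export
weighted_pca <- function(x, row_w = NULL, scale = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two columns")
  if (is.null(row_w)) row_w <- rep(1 / nrow(x), nrow(x))
  if (any(row_w < 0) || abs(sum(row_w) - 1) > 1e-8) {
    stop("row weights must be nonnegative and sum to 1")
  }
  mu <- colSums(x * row_w)
  Z <- sweep(x, 2, mu)
  if (scale) {
    sd_w <- sqrt(colSums(Z^2 * row_w))
    sd_w[sd_w == 0] <- 1
    Z <- sweep(Z, 2, sd_w, "/")
  }
  .triplet(Z, lw = row_w, cw = rep(1, ncol(Z)), type = "pca")
}

# assemble a duality-diagram triplet and its own decomposition
.triplet <- function(Z, lw, cw, type, dropped = NULL) {
  A <- sqrt(lw) * Z %*% diag(sqrt(cw), ncol(Z))
  sv <- svd(A)
  pos <- sv$d^2 > max(sv$d^2, 0) * 1e-12
  d <- sv$d[pos]
  structure(list(tab = Z, lw = lw, cw = cw, type = type,
                 eigenvalues = d^2,
                 inertia = sum(sv$d^2),
                 # principal coordinates
                 row_scores = (sv$u[, pos, drop = FALSE] / sqrt(lw)) %*%
                   diag(d, length(d)),
                 col_scores = (sv$v[, pos, drop = FALSE] / sqrt(cw)) %*%
                   diag(d, length(d)),
                 dropped = dropped),
            class = "dudi_triplet")
}

# squared Frobenius norm of the metricised cross-product of two triplets
.cross_norm2 <- function(X, Y) {
  K <- .cross_matrix(X, Y)
  sum(K^2)
}

.cross_matrix <- function(X, Y) {
  # Q_X^(1/2) X' D Y Q_Y^(1/2); row weights taken from X
  t(X$tab * X$lw) %*% Y$tab *
    (sqrt(X$cw) %o% sqrt(Y$cw))
}

# total squared co-structure of a triplet with itself: ||Q^0.5 Z' D Z Q^0.5||^2
.self_norm2 <- function(X) {
  A <- t(X$tab * X$lw) %*% X$tab * (sqrt(X$cw) %o% sqrt(X$cw))
  sum(A^2)
}

#' Co-inertia analysis of two triplets
#'
#' Decomposes the weighted cross-covariance between a correspondence
#' analysis triplet (MHC table) and a row-weighted PCA triplet (parasite
#' table) sharing the same rows and row weights.
#'
#' @param X,Y `dudi_triplet` objects from [correspondence_analysis()] and
#'   [weighted_pca()] (row weights of `X` are used and must match `Y`'s).
#' @param nf Number of axes to keep scores for.
#' @return List of class `coinertia_result`: `eigenvalues`, `percent`
#'   (percent of total co-inertia per axis), `total_coinertia`, `rv`,
#'   row scores of both tables and column loadings on the co-inertia axes.
#' @export
coinertia <- function(X, Y, nf = 2) {
  stopifnot(inherits(X, "dudi_triplet"), inherits(Y, "dudi_triplet"))
  if (nrow(X$tab) != nrow(Y$tab)) stop("row sets differ between tables")
  if (max(abs(X$lw - Y$lw)) > 1e-8) {
    stop("the two triplets must share row weights")
  }
  K <- .cross_matrix(X, Y)
  sv <- svd(K)
  ev <- sv$d^2
  keep <- ev > max(ev, 0) * 1e-12
  ev <- ev[keep]
  nf <- min(nf, length(ev))
  total <- sum(sv$d^2)
  denom <- sqrt(.self_norm2(X) * .self_norm2(Y))
  rv <- if (denom > 0) total / denom else NA_real_
  # loadings back in original column coordinates
  u <- (sv$u / sqrt(X$cw))[, seq_len(nf), drop = FALSE]
  v <- (sv$v / sqrt(Y$cw))[, seq_len(nf), drop = FALSE]
  structure(list(
    eigenvalues = ev,
    percent = 100 * ev / total,
    total_coinertia = total,
    rv = rv,
    col_loadings_x = u, col_loadings_y = v,
    row_scores_x = X$tab %*% (X$cw * u),
    row_scores_y = Y$tab %*% (Y$cw * v),
    lw = X$lw, nf = nf),
    class = "coinertia_result")
}

#' @export
print.coinertia_result <- function(x, ...) {
  cat("<coinertia_result> RV =", signif(x$rv, 4),
      " total co-inertia =", signif(x$total_coinertia, 4), "\n")
  cat("  axis percentages:",
      paste(sprintf("%.2f%%", x$percent[seq_len(min(4, length(x$percent)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' RV coefficient with Monte-Carlo permutation test
#'
#' The observed RV is the total co-inertia divided by the geometric mean
#' of the two tables' self-co-structure norms. Rows of the second table
#' are permuted `n_perm` times with the row weights held fixed to the
#' first table's rows; `p = (1 + #(RV* >= RV)) / (n_perm + 1)`.
#'
#' @param X,Y `dudi_triplet` objects with matching rows.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble of class `rv_test`: `rv`, `p_value`, `n_perm`.
#' @export
rv_test <- function(X, Y, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 1)
  sx <- .self_norm2(X); sy <- .self_norm2(Y)
  if (sx <= 0 || sy <= 0) {
    stop("RV undefined: a table has no variance under its metric")
  }
  denom <- sqrt(sx * sy)
  obs <- .cross_norm2(X, Y) / denom
  n <- nrow(Y$tab)
  perm_rv <- .with_substream(seed, "rvperm", {
    vapply(seq_len(n_perm), function(i) {
      Yp <- Y
      Yp$tab <- Y$tab[sample.int(n), , drop = FALSE]
      .cross_norm2(X, Yp) / denom
    }, numeric(1))
  })
  p <- (1 + sum(perm_rv >= obs - 1e-12)) / (n_perm + 1)
  structure(tibble::tibble(rv = obs, p_value = p, n_perm = n_perm),
            class = c("rv_test", "tbl_df", "tbl", "data.frame"),
            perm = perm_rv)
}

#' Co-inertia between MHC and parasite data
#'
#' Convenience preset mirroring the standard analysis pairings:
#' presence/absence of alleles (or supertypes) against parasite species
#' (or higher-group) abundances, with the prevalence filter and the
#' minimum-carrier restriction on MHC columns applied first.
#'
#' @param genotypes Tidy genotype tibble (individual, group, allele, ...);
#'   for supertype mode, an `allele`-to-supertype mapping is applied
#'   first via `supertypes`.
#' @param parasites Wide parasite tibble (individual, group, ..., taxa).
#' @param supertypes Optional tibble `allele`, `supertype` switching the
#'   MHC columns to supertype presence.
#' @param groups Subset of host groups to analyse (default all).
#' @param min_carriers MHC columns must be present in at least this many
#'   individuals (default 5).
#' @param prevalence_threshold Passed to
#'   [filter_parasites_by_prevalence()].
#' @param scale_parasites Use correlation-scaled PCA for the parasite
#'   table.
#' @param n_perm,seed Permutation test settings.
#' @return List of class `mhc_coinertia`: `coia` (a `coinertia_result`),
#'   `test` (an `rv_test`), the two input matrices, and bookkeeping.
#' @export
mhc_parasite_coinertia <- function(genotypes, parasites,
                                   supertypes = NULL, groups = NULL,
                                   min_carriers = 5,
                                   prevalence_threshold = 0.02,
                                   scale_parasites = FALSE,
                                   n_perm = 999, seed = 1) {
  g <- .geno_check(genotypes)
  g <- g[!is.na(g$allele), ]
  if (!is.null(supertypes)) {
    g <- dplyr::inner_join(g, supertypes, by = "allele")
    g$allele <- g$supertype
  }
  if (!is.null(groups)) {
    g <- g[g$group %in% groups, ]
    parasites <- parasites[parasites$group %in% groups, ]
  }
  taxa <- .parasite_taxa_cols(parasites)
  parasites <- filter_parasites_by_prevalence(
    parasites, taxa, threshold = prevalence_threshold)
  taxa <- .parasite_taxa_cols(parasites)

  common <- intersect(unique(g$individual), parasites$individual)
  g <- g[g$individual %in% common, ]
  pm <- parasites[match(common, parasites$individual), taxa, drop = FALSE]
  mhc <- table(factor(g$individual, levels = common), g$allele)
  mhc <- (unclass(mhc) > 0) * 1
  mhc <- mhc[, colSums(mhc) >= min_carriers, drop = FALSE]
  keep_rows <- rowSums(mhc) > 0
  mhc <- mhc[keep_rows, , drop = FALSE]
  pm <- as.matrix(pm)[keep_rows, , drop = FALSE]
  rownames(pm) <- rownames(mhc)

  ca <- correspondence_analysis(mhc)
  kept_rows <- setdiff(rownames(mhc), ca$dropped$rows)
  pm <- pm[kept_rows, , drop = FALSE]
  pca <- weighted_pca(pm, row_w = ca$lw, scale = scale_parasites)
  co <- coinertia(ca, pca)
  tst <- rv_test(ca, pca, n_perm = n_perm, seed = seed)
  structure(list(coia = co, test = tst, mhc = mhc, parasites = pm,
                 min_carriers = min_carriers),
            class = "mhc_coinertia")
}

#' @export
print.mhc_coinertia <- function(x, ...) {
  cat("<mhc_coinertia> ", nrow(x$mhc), " individuals, ",
      ncol(x$mhc), " MHC columns x ", ncol(x$parasites),
      " parasite taxa\n", sep = "")
  cat("  RV =", signif(x$test$rv, 3), " p =", signif(x$test$p_value, 4),
      " (", x$test$n_perm, "permutations )\n")
  invisible(x)
}
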