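# Functional supertype clustering of MHC alleles: physicochemical
# z-descriptors at positively selected sites, K-means with a BIC scan over
# k, DAPC membership probabilities, and a run-to-run consistency filter.

# Five-dimensional z-scale physicochemical descriptors (Sandberg-style:
# z1 hydrophilicity, z2 steric bulk, z3 polarity, z4/z5 electronic terms).
.ZSCALES <- matrix(c(
  # z1     z2     z3     z4     z5
   0.24, -2.32,  0.60, -0.14,  1.30,  # A
   0.84, -1.67,  3.71,  0.18, -2.65,  # C
   3.98,  0.93,  1.93, -2.46,  0.75,  # D
   3.11,  0.26, -0.11, -3.04, -0.25,  # E
  -4.22,  1.94,  1.06,  0.54, -0.62,  # F
   2.05, -4.06,  0.36, -0.82, -0.38,  # G
   2.47,  1.95,  0.26,  3.90,  0.09,  # H
  -3.89, -1.73, -1.71, -0.84,  0.26,  # I
   2.29,  0.89, -2.49,  1.49,  0.31,  # K
  -4.28, -1.30, -1.49, -0.72,  0.84,  # L
  -2.85, -0.22,  0.47,  1.94, -0.98,  # M
   3.05,  1.62,  1.04, -1.15,  1.61,  # N
  -1.66,  0.27,  1.84,  0.70,  2.00,  # P
   1.75,  0.50, -1.44, -1.34,  0.66,  # Q
   3.52,  2.50, -3.50,  1.99, -0.17,  # R
   2.39, -1.07,  1.15, -1.39,  0.67,  # S
   0.75, -2.18, -1.12, -1.46, -0.40,  # T
  -2.59, -2.64, -1.54, -0.85, -0.02,  # V
  -4.36,  3.94,  0.59,  3.44, -1.59,  # W
  -2.54,  2.44,  0.43,  0.04, -1.47), # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  paste0("z", 1:5)))

#' Physicochemical z-scale descriptor table
#'
#' @return Tibble with one row per amino acid and columns `aa`, `z1`-`z5`.
#' @export
zscale_descriptors <- function() {
  dplyr::bind_cols(tibble::tibble(aa = rownames(.ZSCALES)),
                   tibble::as_tibble(.ZSCALES))
}

#' Encode alleles as descriptor vectors at selected sites
#'
#' Each allele becomes the concatenation of the five z-descriptors of its
#' residue at every positively selected site; columns are standardised to
#' zero mean and unit variance by default. Alleles with a gap, stop or
#' nonstandard residue at any selected site are dropped with a warning.
#'
#' @param proteins Named character vector of aligned amino-acid sequences.
#' @param pss_positions Integer vector of selected site positions
#'   (1-based, within the protein alignment).
#' @param descriptors Descriptor matrix (rows = amino acids); defaults to
#'   the bundled z-scales.
#' @param standardize Standardise columns after encoding.
#' @return Numeric matrix alleles x (5 * number of sites); dropped alleles
#'   are recorded in the `"dropped"` attribute.
#' @export
encode_descriptors <- function(proteins, pss_positions,
                               descriptors = NULL, standardize = TRUE) {
  if (is.null(descriptors)) descriptors <- .ZSCALES
  plen <- unique(nchar(proteins))
  if (length(plen) != 1) stop("protein sequences must be aligned")
  if (any(pss_positions < 1 | pss_positions > plen)) {
    stop("selected positions outside the sequence length")
  }
  res <- do.call(rbind, strsplit(toupper(proteins), ""))
  res <- res[, pss_positions, drop = FALSE]
  ok <- apply(res, 1, function(r) all(r %in% rownames(descriptors)))
  if (any(!ok)) {
    warning(sum(!ok), " allele(s) dropped: nonstandard residue at a ",
            "selected site")
  }
  res <- res[ok, , drop = FALSE]
  nd <- ncol(descriptors)
  m <- matrix(0, nrow(res), length(pss_positions) * nd,
              dimnames = list(names(proteins)[ok],
                              paste0("p", rep(pss_positions, each = nd),
                                     "_", colnames(descriptors))))
  for (j in seq_along(pss_positions)) {
    m[, (j - 1) * nd + seq_len(nd)] <- descriptors[res[, j], , drop = FALSE]
  }
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    m <- scale(m, center = TRUE, scale = sds)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  attr(m, "dropped") <- names(proteins)[!ok]
  m
}

# deterministic K-means wrapper (seeded, multi-start)
.kmeans_seeded <- function(m, k, n_starts, seed, name) {
  .with_substream(seed, name, {
    stats::kmeans(m, centers = k, nstart = n_starts, iter.max = 100)
  })
}

#' K-means BIC scan over the number of supertypes
#'
#' Fits K-means for each k and scores it as
#' `BIC(k) = n * log(W(k) / n) + k * d * log(n)` with `W(k)` the total
#' within-cluster sum of squares. The chosen k is the smallest k whose
#' BIC decrease to k+1 falls below `elbow_frac` times the initial
#' decrease.
#'
#' @param m Descriptor matrix (rows = alleles).
#' @param k_range Candidate cluster counts.
#' @param n_starts K-means restarts per k.
#' @param seed Integer seed.
#' @param elbow_frac Elbow fraction for the change-in-BIC stopping rule.
#' @return Tibble of class `bic_scan`: `k`, `W`, `BIC`; chosen k in the
#'   `"chosen_k"` attribute.
#' @export
kmeans_bic_scan <- function(m, k_range = 1:15, n_starts = 20, seed = 1,
                            elbow_frac = 0.1) {
  n <- nrow(m); d <- ncol(m)
  k_range <- sort(unique(k_range))
  if (max(k_range) > n - 1) stop("k_range must stay below n_alleles")
  W <- vapply(k_range, function(k) {
    if (k == 1) {
      sum(scale(m, scale = FALSE)^2)
    } else {
      km <- .kmeans_seeded(m, k, n_starts, seed, paste0("bic", k))
      km$tot.withinss
    }
  }, numeric(1))
  bic <- n * log(pmax(W, 1e-12) / n) + k_range * d * log(n)
  out <- tibble::tibble(k = k_range, W = W, BIC = bic)
  dec <- -diff(bic)
  chosen <- if (length(dec) == 0 || dec[1] <= 0) {
    k_range[1]
  } else {
    idx <- which(dec < elbow_frac * dec[1])
    if (length(idx)) k_range[min(idx)] else k_range[length(k_range)]
  }
  structure(out, class = c("bic_scan", class(out)), chosen_k = chosen)
}

# regularised equal-covariance Gaussian classifier (DAPC fallback when the
# within-class scatter is singular for MASS::lda)
.ridge_lda_posterior <- function(x, labels, newx = x, ridge = 1e-6) {
  labels <- factor(labels)
  mu <- do.call(rbind, lapply(levels(labels), function(l) {
    colMeans(x[labels == l, , drop = FALSE])
  }))
  resid <- x - mu[as.integer(labels), , drop = FALSE]
  Sw <- crossprod(resid) / max(1, nrow(x) - nlevels(labels))
  Sw <- Sw + diag(ridge * max(diag(Sw), 1), ncol(x))
  Si <- solve(Sw)
  prior <- as.numeric(table(labels)) / nrow(x)
  disc <- sapply(seq_len(nlevels(labels)), function(k) {
    dl <- sweep(newx, 2, mu[k, ])
    -0.5 * rowSums((dl %*% Si) * dl) + log(prior[k])
  })
  disc <- matrix(disc, nrow = nrow(newx))
  p <- exp(disc - apply(disc, 1, max))
  p / rowSums(p)
}

#' DAPC membership probabilities
#'
#' Discriminant analysis of principal components: the descriptor matrix is
#' reduced by PCA (retaining `n_pcs` axes, default enough for 90 percent
#' of variance), then linear discriminant analysis on the provided cluster
#' labels yields per-allele posterior membership probabilities and the
#' modal supertype. A singular within-class scatter triggers a
#' ridge-regularised fallback (message emitted).
#'
#' @param m Descriptor matrix.
#' @param labels Cluster labels (e.g. from K-means at the chosen k).
#' @param n_pcs Number of principal components retained.
#' @return Tibble: `allele`, `modal` (label), `prob_modal`, plus one
#'   `p_<label>` column per cluster.
#' @export
dapc_assign <- function(m, labels, n_pcs = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two clusters")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  if (is.null(n_pcs)) {
    v <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- max(which(v >= 0.9)[1], nlevels(labels))
  }
  n_pcs <- min(n_pcs, sum(pc$sdev > 1e-10), ncol(pc$x))
  x <- pc$x[, seq_len(n_pcs), drop = FALSE]
  post <- tryCatch({
    fit <- MASS::lda(x, grouping = labels)
    stats::predict(fit, x)$posterior
  }, error = function(e) {
    message("within-class scatter singular; ridge regularisation applied")
    p <- .ridge_lda_posterior(x, labels)
    colnames(p) <- levels(labels)
    p
  })
  modal <- colnames(post)[max.col(post, ties.method = "first")]
  out <- tibble::tibble(
    allele = rownames(m) %||% as.character(seq_len(nrow(m))),
    modal = modal,
    prob_modal = post[cbind(seq_len(nrow(post)),
                            max.col(post, ties.method = "first"))])
  colnames(post) <- paste0("p_", colnames(post))
  dplyr::bind_cols(out, tibble::as_tibble(post))
}

# align labels of `km` to `ref` by greedy maximal overlap
.align_labels <- function(ref, km) {
  tab <- table(ref, km)
  map <- integer(ncol(tab))
  used_r <- used_c <- logical(nrow(tab))
  for (step in seq_len(min(nrow(tab), ncol(tab)))) {
    t2 <- tab
    t2[used_r, ] <- -1
    t2[, used_c] <- -1
    best <- arrayInd(which.max(t2), dim(t2))
    map[best[2]] <- best[1]
    used_r[best[1]] <- TRUE
    used_c[best[2]] <- TRUE
  }
  map[map == 0] <- which(!used_r)[seq_len(sum(map == 0))]
  as.integer(map[km])
}

#' Consistency filter over repeated clusterings
#'
#' Repeats K-means with distinct seeds, aligns cluster labels to the
#' reference run by maximal overlap, and scores each allele by the
#' fraction of runs assigning it its reference label. Supertype letters
#' (A, B, ...) map to reference clusters by descending size (ties broken
#' by centroid lexicographic order).
#'
#' @param m Descriptor matrix.
#' @param k Number of supertypes.
#' @param n_repeats Number of repeated runs (>= 2).
#' @param seed Integer seed.
#' @param threshold Minimum consistency to keep an allele.
#' @param n_starts K-means restarts within each run.
#' @return Tibble of class `supertype_assignment`: `allele`, `supertype`,
#'   `consistency`, `kept`.
#' @export
consistency_filter <- function(m, k, n_repeats = 20, seed = 1,
                               threshold = 0.9, n_starts = 10) {
  if (n_repeats < 2) stop("n_repeats must be at least 2")
  ref <- .kmeans_seeded(m, k, n_starts, seed, "consist_ref")
  agree <- matrix(0, nrow(m), n_repeats - 1)
  for (r in seq_len(n_repeats - 1)) {
    km <- .kmeans_seeded(m, k, n_starts, seed, paste0("consist", r))
    agree[, r] <- .align_labels(ref$cluster, km$cluster) == ref$cluster
  }
  consistency <- rowMeans(agree)
  # letters by descending cluster size; ties by centroid lexicographic order
  sizes <- as.numeric(table(factor(ref$cluster, levels = seq_len(k))))
  ord <- order(-sizes, apply(ref$centers, 1, paste, collapse = ","))
  letter <- stats::setNames(LETTERS[seq_len(k)], ord)
  out <- tibble::tibble(
    allele = rownames(m) %||% as.character(seq_len(nrow(m))),
    cluster = ref$cluster,
    supertype = unname(letter[as.character(ref$cluster)]),
    consistency = consistency,
    kept = consistency >= threshold)
  structure(out, class = c("supertype_assignment", class(out)),
            k = k, reference = ref)
}

#' Full supertyping pipeline
#'
#' Encode alleles at the selected sites, scan k by BIC, cluster at the
#' chosen k, attach DAPC membership probabilities, and filter by
#' clustering consistency.
#'
#' @param proteins Named amino-acid sequences.
#' @param pss_positions Positively selected site positions.
#' @param k Fixed number of supertypes; when `NULL` (default) the BIC
#'   scan's elbow choice is used.
#' @param k_range,n_repeats,seed,threshold,elbow_frac See the component
#'   functions.
#' @return List of class `supertype_result`: `assignment`, `bic`,
#'   `dapc`, `matrix`.
#' @export
supertype_alleles <- function(proteins, pss_positions, k = NULL,
                              k_range = 2:12, n_repeats = 20, seed = 1,
                              threshold = 0.9, elbow_frac = 0.1) {
  m <- encode_descriptors(proteins, pss_positions)
  scan <- kmeans_bic_scan(m, k_range = k_range, seed = seed,
                          elbow_frac = elbow_frac)
  if (is.null(k)) k <- attr(scan, "chosen_k")
  if (k < 2) k <- 2
  assign <- consistency_filter(m, k, n_repeats = n_repeats, seed = seed,
                               threshold = threshold)
  dapc <- dapc_assign(m, assign$cluster)
  assign$prob_modal <- dapc$prob_modal
  structure(list(assignment = assign, bic = scan, dapc = dapc,
                 matrix = m, k = k),
            class = "supertype_result")
}

#' @export
print.supertype_result <- function(x, ...) {
  cat("<supertype_result> k =", x$k, "supertypes;",
      sum(!x$assignment$kept), "of", nrow(x$assignment),
      "alleles removed by the consistency filter\n")
  invisible(x)
}
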