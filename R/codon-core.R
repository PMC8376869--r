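# Genetic-code tables and the GY94 codon substitution process.
#
# Codons are enumerated in TCAG order (first base slowest), stop codons
# removed, giving the 61 sense codons of the standard code. All rate-matrix
# work indexes into this fixed ordering.

.codon_env <- new.env(parent = emptyenv())

# 64-codon amino-acid string for TCAG ordering of the standard code
.GENETIC_CODE_TCAG <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) {
    return(.codon_env$tab)
  }
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons64 <- paste0(grid$b1, grid$b2, grid$b3)
  aa64 <- strsplit(.GENETIC_CODE_TCAG, "")[[1]]
  sense <- aa64 != "*"
  codons <- codons64[sense]
  aa <- aa64[sense]
  n <- length(codons)          # 61
  cmat <- do.call(rbind, strsplit(codons, ""))

  # enumerate single-nucleotide neighbour pairs
  purines <- c("A", "G")
  is_transition_pair <- function(x, y) {
    (x %in% purines) == (y %in% purines)
  }
  ii <- jj <- integer(0)
  ts <- syn <- logical(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diff <- which(cmat[i, ] != cmat[j, ])
      if (length(diff) == 1L) {
        ii <- c(ii, i); jj <- c(jj, j)
        ts <- c(ts, is_transition_pair(cmat[i, diff], cmat[j, diff]))
        syn <- c(syn, aa[i] == aa[j])
      }
    }
  }
  tab <- list(codons = codons, aa = aa, cmat = cmat, n = n,
              pairs = data.frame(i = ii, j = jj, transition = ts,
                                 synonymous = syn))
  .codon_env$tab <- tab
  tab
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in the package's fixed
#'   ordering (TCAG expansion with stop codons removed).
#' @export
sense_codons <- function() .codon_tables()$codons

#' Translate sense codons to amino acids
#'
#' @param codons Character vector of codons (uppercase, T alphabet).
#' @return Character vector of one-letter amino-acid codes; `NA` for codons
#'   that are not sense codons of the standard code.
#' @export
translate_codons <- function(codons) {
  tab <- .codon_tables()
  tab$aa[match(toupper(codons), tab$codons)]
}

#' GY94 codon rate matrix
#'
#' Builds the 61 x 61 generator of the Goldman-Yang codon substitution
#' process: single-nucleotide changes only, target-codon frequency `pi_j`
#' times `kappa` for transitions and times `omega` for nonsynonymous
#' changes. The matrix is reversible with respect to `codon_freqs`.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_freqs Numeric vector of 61 sense-codon equilibrium
#'   frequencies summing to 1 (order of [sense_codons()]).
#' @param scale If `TRUE` (default) the matrix is scaled so the expected
#'   substitution rate at equilibrium is 1.
#' @return 61 x 61 matrix with rows summing to zero. The attribute
#'   `"mean_rate"` carries the pre-scaling mean rate, used for mixture-wide
#'   normalisation.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs, scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0)
  tab <- .codon_tables()
  if (length(codon_freqs) != tab$n) {
    stop("codon_freqs must have length ", tab$n)
  }
  if (abs(sum(codon_freqs) - 1) > 1e-6) {
    stop("codon_freqs must sum to 1 over the sense codons")
  }
  n <- tab$n
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  p <- tab$pairs
  rate <- ifelse(p$transition, kappa, 1) * ifelse(p$synonymous, 1, omega)
  Q[cbind(p$i, p$j)] <- rate * codon_freqs[p$j]
  Q[cbind(p$j, p$i)] <- rate * codon_freqs[p$i]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(codon_freqs * diag(Q))
  if (scale && mu > 0) {
    Q <- Q / mu
  }
  attr(Q, "mean_rate") <- mu
  Q
}

# Eigen-decomposition of a reversible GY94 generator, unscaled.
# P(t) = V diag(exp(d * t)) Vinv. Returned pieces feed the C++ pruning core.
codon_eigen <- function(kappa, omega, codon_freqs) {
  Q <- codon_rate_matrix(kappa, omega, codon_freqs, scale = FALSE)
  mu <- attr(Q, "mean_rate")
  sp <- sqrt(codon_freqs)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2                     # symmetric up to rounding
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors / sp, Vinv = t(e$vectors) * rep(sp, each = length(sp)),
       d = e$values, mean_rate = mu)
}

# Transition probability matrix from an eigensystem
codon_prob_matrix <- function(es, t) {
  P <- es$V %*% (exp(es$d * t) * es$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Codon equilibrium frequencies from an alignment
#'
#' @param aln A [codon_alignment] object.
#' @param mode One of `"F3x4"` (position-specific nucleotide frequencies),
#'   `"F1x4"` (overall nucleotide frequencies), `"Fequal"` (1/61), or
#'   `"empirical"` (observed codon proportions, with a small floor so no
#'   sense codon has probability zero).
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(aln,
                              mode = c("F3x4", "F1x4", "Fequal", "empirical")) {
  mode <- match.arg(mode)
  tab <- .codon_tables()
  if (mode == "Fequal") {
    return(rep(1 / tab$n, tab$n))
  }
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- as.vector(aln$codons)
  idx <- idx[!is.na(idx)]
  if (mode == "empirical") {
    cnt <- tabulate(idx, nbins = tab$n) + 0.5
    return(cnt / sum(cnt))
  }
  cm <- tab$cmat[idx, , drop = FALSE]
  bases <- c("T", "C", "A", "G")
  if (mode == "F1x4") {
    f <- table(factor(as.vector(cm), levels = bases))
    f <- (as.numeric(f) + 0.5) / (sum(f) + 2)
    fr <- f[match(tab$cmat[, 1], bases)] *
      f[match(tab$cmat[, 2], bases)] *
      f[match(tab$cmat[, 3], bases)]
  } else { # F3x4
    fpos <- lapply(1:3, function(k) {
      f <- table(factor(cm[, k], levels = bases))
      (as.numeric(f) + 0.5) / (sum(f) + 2)
    })
    fr <- fpos[[1]][match(tab$cmat[, 1], bases)] *
      fpos[[2]][match(tab$cmat[, 2], bases)] *
      fpos[[3]][match(tab$cmat[, 3], bases)]
  }
  fr / sum(fr)
}
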