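# Codon alignment container and tree helpers.

#' Build a codon alignment from aligned nucleotide sequences
#'
#' Checks the reading frame and rejects sequences with internal stop codons,
#' reporting the offending codon index. Sequences are uppercased and U is
#' normalised to T before translation.
#'
#' @param seqs Named character vector of aligned, equal-length nucleotide
#'   sequences.
#' @param frame Reading-frame offset (0, 1 or 2 bases skipped at the start).
#' @return An object of class `codon_alignment`: list with `codons` (integer
#'   matrix taxa x sites indexing [sense_codons()], `NA` for ambiguous
#'   codons), `taxa`, and `n_codons`.
#' @export
translate_and_check <- function(seqs, frame = 0) {
  stopifnot(frame %in% 0:2)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  seqs <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be aligned to equal length")
  }
  L <- unique(lens) - frame
  if (L %% 3 != 0) {
    stop("sequence length after frame offset (", L,
         ") is not divisible by 3")
  }
  n_codons <- L %/% 3
  tab <- .codon_tables()
  stops <- c("TAA", "TAG", "TGA")
  mat <- matrix(NA_integer_, length(seqs), n_codons,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cds <- substring(seqs[i], frame + 3 * (seq_len(n_codons) - 1) + 1,
                     frame + 3 * seq_len(n_codons))
    hit <- which(cds %in% stops)
    if (length(hit)) {
      stop("sequence '", names(seqs)[i], "' contains a stop codon at codon ",
           hit[1])
    }
    mat[i, ] <- match(cds, tab$codons)   # non-ACGT codons become NA
  }
  structure(list(codons = mat, taxa = names(seqs), n_codons = n_codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", x$n_codons,
      " codons\n", sep = "")
  invisible(x)
}

# codon alignment -> ape DNAbin (for distance computation)
.aln_to_dnabin <- function(aln) {
  tab <- .codon_tables()
  chr <- apply(aln$codons, 1, function(row) {
    cds <- ifelse(is.na(row), "NNN", tab$codons[row])
    strsplit(paste(cds, collapse = ""), "")[[1]]
  })
  ape::as.DNAbin(t(chr))
}

#' Neighbour-joining tree from a codon alignment
#'
#' Builds an unrooted NJ tree from Jukes-Cantor nucleotide distances.
#' Identical sequences yield zero-length branches (a warning is issued);
#' negative NJ branch lengths are clamped to zero.
#'
#' @param aln A [codon_alignment].
#' @param model Distance model passed to [ape::dist.dna()].
#' @return An [ape::phylo] tree.
#' @export
build_nj_tree <- function(aln, model = "JC69") {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 3) stop("need at least 3 taxa")
  d <- ape::dist.dna(.aln_to_dnabin(aln), model = model,
                     pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.75) * 1.5
  if (any(d == 0)) {
    warning("identical sequences present; zero-length branches allowed")
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# integer tip matrix ordered as tree tips, plus site-pattern compression
.aln_patterns <- function(aln, tree) {
  miss <- setdiff(tree$tip.label, aln$taxa)
  if (length(miss)) {
    stop("tree taxa absent from alignment: ", paste(miss, collapse = ", "))
  }
  m <- aln$codons[tree$tip.label, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(tips = m[, u, drop = FALSE] - 1L,     # 0-based, NA -> -1 below
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       map = idx)
}

.tips_int <- function(tips) {
  tips[is.na(tips)] <- -1L
  storage.mode(tips) <- "integer"
  tips
}
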