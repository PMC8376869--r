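# Sequence-level simulation: random trees and codon alignments evolved
# under a site-class mixture of GY94 processes.

#' Simulate a random binary tree
#'
#' Random topology with exponential branch lengths, used as plumbing for
#' the codon-model machinery. Deterministic for a fixed seed.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Integer seed.
#' @param mean_branch Mean branch length (expected substitutions per
#'   codon site).
#' @return An [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = 1, mean_branch = 0.1) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  .with_substream(seed, "tree", {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) stats::rexp(n, 1 / mean_branch))
    tr$tip.label <- paste0("t", seq_len(n_taxa))
    tr
  })
}

#' Evolve a codon alignment under a site-class mixture
#'
#' Sites are assigned to omega classes by the class proportions; each site
#' then evolves along the tree under the GY94 process of its class, with
#' branch lengths interpreted as expected substitutions per codon site
#' under the proportion-weighted mixture (the same normalisation the
#' fitting machinery uses).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param site_classes Data frame with columns `prop` and `omega`;
#'   proportions must sum to 1.
#' @param kappa Transition/transversion ratio.
#' @param codon_freqs Equilibrium frequencies over the 61 sense codons
#'   (default uniform).
#' @param n_codons Number of codon sites (0 gives an empty alignment).
#' @param seed Integer seed.
#' @return List with `aln` (a [codon_alignment]) and `site_class` (integer
#'   vector of true class per site).
#' @export
evolve_codon_alignment <- function(tree, site_classes, kappa = 2,
                                   codon_freqs = NULL, n_codons = 100,
                                   seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  props <- site_classes$prop
  omegas <- site_classes$omega
  if (abs(sum(props) - 1) > 1e-9) stop("class proportions must sum to 1")
  tab <- .codon_tables()
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / tab$n, tab$n)
  if (length(codon_freqs) != tab$n) {
    stop("codon_freqs must cover exactly the 61 sense codons")
  }
  tree <- stats::reorder(ape::unroot(tree), "postorder")
  n_tip <- length(tree$tip.label)
  if (n_codons == 0) {
    aln <- structure(list(codons = matrix(integer(0), n_tip, 0,
                                          dimnames = list(tree$tip.label,
                                                          NULL)),
                          taxa = tree$tip.label, n_codons = 0L),
                     class = "codon_alignment")
    return(list(aln = aln, site_class = integer(0)))
  }

  .with_substream(seed, "evolve", {
    cls <- sample.int(length(props), n_codons, replace = TRUE, prob = props)
    esl <- lapply(omegas, function(w) codon_eigen(kappa, w, codon_freqs))
    mu <- sum(props * vapply(esl, `[[`, numeric(1), "mean_rate"))
    root <- n_tip + 1
    n_node <- max(tree$edge)
    states <- matrix(NA_integer_, n_node, n_codons)
    states[root, ] <- sample.int(tab$n, n_codons, replace = TRUE,
                                 prob = codon_freqs)
    # preorder = reverse postorder edge traversal
    for (e in rev(seq_len(nrow(tree$edge)))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_eff <- tree$edge.length[e] / mu
      for (k in unique(cls)) {
        P <- codon_prob_matrix(esl[[k]], t_eff)
        sites <- which(cls == k)
        from <- states[parent, sites]
        states[child, sites] <- vapply(from, function(f) {
          sample.int(tab$n, 1, prob = P[f, ])
        }, integer(1))
      }
    }
    mat <- states[seq_len(n_tip), , drop = FALSE]
    rownames(mat) <- tree$tip.label
    aln <- structure(list(codons = mat, taxa = tree$tip.label,
                          n_codons = as.integer(n_codons)),
                     class = "codon_alignment")
    list(aln = aln, site_class = cls)
  })
}

#' Nucleotide sequences from a codon alignment
#'
#' @param aln A [codon_alignment].
#' @return Named character vector of nucleotide sequences.
#' @export
alignment_sequences <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- .codon_tables()
  out <- apply(aln$codons, 1, function(row) {
    paste(ifelse(is.na(row), "NNN", tab$codons[row]), collapse = "")
  })
  stats::setNames(as.character(out), aln$taxa)
}
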