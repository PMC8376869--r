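# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-site posterior mean omega with PSS markers
#'
#' The classic site-scan display: posterior mean omega per codon under the
#' fitted site model, with sites above the 95 and 99 percent posterior
#' levels highlighted.
#'
#' @param object A `beb_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot beb_result
#' @export
autoplot.beb_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$level <- dplyr::case_when(df$pss99 ~ "PSS 99%",
                               df$pss95 ~ "PSS 95%",
                               TRUE ~ "not selected")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$mean_omega)) +
    ggplot2::geom_col(fill = "grey55", width = 0.8) +
    ggplot2::geom_point(data = df[df$level != "not selected", ],
                        ggplot2::aes(shape = .data$level), size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_shape_manual(values = c("PSS 95%" = 0,
                                           "PSS 99%" = 15)) +
    ggplot2::labs(x = "codon site", y = "posterior mean ω",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a BIC scan over cluster counts
#'
#' @param object A `bic_scan`.
#' @param ... Unused.
#' @return A ggplot with the chosen k marked.
#' @method autoplot bic_scan
#' @export
autoplot.bic_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$BIC)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"),
                        linetype = 2) +
    ggplot2::labs(x = "number of supertypes (k)", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Co-inertia variable map
#'
#' Column loadings of both tables on the first two co-inertia axes; MHC
#' columns and parasite taxa in one display, the standard reading being
#' that variables pointing in the same direction from the origin covary
#' positively.
#'
#' @param object A `coinertia_result`.
#' @param x_names,y_names Optional variable names for the two tables.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coinertia_result
#' @export
autoplot.coinertia_result <- function(object, x_names = NULL,
                                      y_names = NULL, ...) {
  nf <- min(2, object$nf)
  if (nf < 2) stop("need at least two co-inertia axes to map")
  dx <- tibble::tibble(axis1 = object$col_loadings_x[, 1],
                       axis2 = object$col_loadings_x[, 2],
                       name = x_names %||%
                         paste0("mhc", seq_len(nrow(object$col_loadings_x))),
                       table = "MHC")
  dy <- tibble::tibble(axis1 = object$col_loadings_y[, 1],
                       axis2 = object$col_loadings_y[, 2],
                       name = y_names %||%
                         paste0("taxon",
                                seq_len(nrow(object$col_loadings_y))),
                       table = "parasites")
  df <- dplyr::bind_rows(dx, dy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   colour = .data$table)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0), alpha = 0.4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), size = 3) +
    ggplot2::labs(x = sprintf("F1 (%.1f%%)", object$percent[1]),
                  y = sprintf("F2 (%.1f%%)", object$percent[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the most common allele frequencies per group
#'
#' @param frequencies Output of [allele_frequencies()].
#' @param top_n Number of most frequent alleles (over all groups) shown.
#' @return A ggplot.
#' @export
plot_allele_frequencies <- function(frequencies, top_n = 8) {
  top <- dplyr::slice_max(
    dplyr::summarise(dplyr::group_by(frequencies, .data$allele),
                     f = max(.data$frequency), .groups = "drop"),
    order_by = .data$f, n = top_n)
  df <- frequencies[frequencies$allele %in% top$allele, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$allele, y = .data$frequency,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "carrier frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
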