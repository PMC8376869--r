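# broom-style tidiers for the fitted-object classes.

#' @describeIn fit_site_model Tidy the class mixture of a codon fit (one
#'   row per omega class).
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @method tidy codon_fit
#' @export
tidy.codon_fit <- function(x, ...) {
  tibble::tibble(model = x$model, class = seq_along(x$props),
                 proportion = x$props, omega = x$omegas)
}

#' @describeIn fit_site_model One-row model summary (lnL, parameter count,
#'   kappa, convergence).
#' @method glance codon_fit
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$lnL, np = x$np,
                 kappa = x$kappa, tree_scale = x$tree_scale,
                 p_beta = x$p_beta %||% NA_real_,
                 q_beta = x$q_beta %||% NA_real_,
                 omega_s = x$omega_s %||% NA_real_,
                 converged = x$converged)
}

#' @describeIn coinertia Per-axis eigenvalues and percentages.
#' @param x A `coinertia_result`.
#' @param ... Unused.
#' @method tidy coinertia_result
#' @export
tidy.coinertia_result <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues, percent = x$percent)
}

#' @describeIn coinertia One-row summary (RV, total co-inertia, leading
#'   axis percentages).
#' @method glance coinertia_result
#' @export
glance.coinertia_result <- function(x, ...) {
  tibble::tibble(rv = x$rv, total_coinertia = x$total_coinertia,
                 percent_axis1 = x$percent[1],
                 percent_axis2 = if (length(x$percent) > 1) {
                   x$percent[2]
                 } else {
                   NA_real_
                 })
}

#' @describeIn fit_parasite_glm Coefficient table of a parasite GLM.
#' @param x A `parasite_fit`.
#' @param ... Unused.
#' @method tidy parasite_fit
#' @export
tidy.parasite_fit <- function(x, ...) {
  s <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
  if (is.null(s) || x$separation) {
    return(tibble::tibble(term = names(x$coefficients),
                          estimate = unname(x$coefficients),
                          std_error = NA_real_, p_value = NA_real_))
  }
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], p_value = s[, 4])
}

#' @describeIn fit_parasite_glm One-row fit summary.
#' @method glance parasite_fit
#' @export
glance.parasite_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$logLik, k = x$k, n = x$n,
                 aicc = x$aicc, theta = x$theta %||% NA_real_,
                 separation = x$separation)
}

#' @describeIn kruskal_allele_counts Omnibus H-test row.
#' @param x A `kw_report`.
#' @param ... Unused.
#' @method glance kw_report
#' @export
glance.kw_report <- function(x, ...) x$omnibus

#' @describeIn kruskal_allele_counts Pairwise Dunn comparisons.
#' @method tidy kw_report
#' @export
tidy.kw_report <- function(x, ...) x$pairwise
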