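# GLM screens of parasite load: Poisson for richness, negative binomial
# for abundance, Bernoulli for prevalence, with AICc backward stepwise
# selection. Year enters as a fixed factor; the negative-binomial family
# stands in for observation-level overdispersion.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, with `k` counting all
#' estimated parameters (including the NB dispersion).
#'
#' @param fit A fitted model (`glm`, `negbin`) or a `logLik` value.
#' @param k,n Parameter and observation counts (taken from `fit` when
#'   omitted).
#' @return Numeric AICc (infinite when `n <= k + 1`).
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (is.numeric(fit)) {
    ll <- fit
  } else {
    ll <- as.numeric(stats::logLik(fit))
    if (is.null(k)) k <- attr(stats::logLik(fit), "df")
    if (is.null(n)) n <- stats::nobs(fit)
  }
  if (n <= k + 1) return(Inf)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Choose between abundance and prevalence modelling
#'
#' Low-prevalence taxa are modelled as presence/absence to avoid
#' zero-inflated abundance fits.
#'
#' @param prevalence Proportion of infected hosts, in `[0, 1]`.
#' @param threshold Prevalence cutoff (default 0.30).
#' @param strict Use strict `<` instead of the default `<=`.
#' @return `"prevalence"` or `"abundance"`.
#' @export
choose_response_form <- function(prevalence, threshold = 0.3,
                                 strict = FALSE) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  low <- if (strict) prevalence < threshold else prevalence <= threshold
  if (low) "prevalence" else "abundance"
}

#' Eligible allele/supertype predictors for a group
#'
#' A presence predictor is retained iff it occurs in more than
#' `min_carriers` individuals of the analysed group.
#'
#' @param genotypes Tidy genotype tibble (or allele/supertype long table
#'   with columns `individual`, `group`, `allele`).
#' @param group Host group to subset to.
#' @param min_carriers Carrier threshold; retention requires strictly
#'   more carriers than this (default 7).
#' @return Character vector of eligible predictor names.
#' @export
eligible_predictors <- function(genotypes, group, min_carriers = 7) {
  g <- .geno_check(genotypes)
  g <- g[g$group == group & !is.na(g$allele), ]
  tab <- dplyr::summarise(
    dplyr::group_by(g, .data$allele),
    carriers = dplyr::n_distinct(.data$individual), .groups = "drop")
  sort(tab$allele[tab$carriers > min_carriers])
}

# ridge-penalised logistic fit used when ML separation is detected
.penalized_logistic <- function(X, y, lambda = 1e-2, maxit = 100) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  list(coefficients = drop(beta),
       logLik = sum(stats::dbinom(y, 1, stats::plogis(drop(X %*% beta)),
                                  log = TRUE)))
}

#' Fit one parasite GLM
#'
#' @param data Model frame containing the response and predictors.
#' @param formula Model formula.
#' @param family `"poisson"` (richness), `"nbinom"` (abundance; ML
#'   dispersion via [MASS::glm.nb()]), or `"bernoulli"` (prevalence).
#' @return Object of class `parasite_fit`: the underlying fit, `family`,
#'   `logLik`, `k`, `n`, `aicc`, `separation` flag (Bernoulli fits with
#'   divergent coefficients are refit with a ridge penalty for
#'   reporting).
#' @export
fit_parasite_glm <- function(data, formula,
                             family = c("poisson", "nbinom",
                                        "bernoulli")) {
  family <- match.arg(family)
  fit <- switch(family,
    poisson = stats::glm(formula, data = data, family = stats::poisson()),
    nbinom = suppressWarnings(MASS::glm.nb(formula, data = data)),
    bernoulli = suppressWarnings(
      stats::glm(formula, data = data, family = stats::binomial())))
  separation <- FALSE
  coefs <- stats::coef(fit)
  if (family == "bernoulli" &&
      (any(abs(coefs[-1]) > 15, na.rm = TRUE) || !fit$converged)) {
    separation <- TRUE
    X <- stats::model.matrix(formula, data)
    y <- stats::model.response(stats::model.frame(formula, data))
    pf <- .penalized_logistic(X, as.numeric(y))
    coefs <- stats::setNames(pf$coefficients, colnames(X))
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  structure(list(fit = fit, family = family, formula = formula,
                 coefficients = coefs, logLik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n), separation = separation,
                 theta = if (family == "nbinom") fit$theta else NULL),
            class = "parasite_fit")
}

#' @export
print.parasite_fit <- function(x, ...) {
  cat("<parasite_fit> ", x$family, "  AICc = ", round(x$aicc, 2),
      if (x$separation) "  [separation: ridge-penalised coefficients]",
      "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

# terms removable without violating marginality (not part of a higher-
# order interaction)
.removable_terms <- function(formula) {
  tt <- stats::terms(formula)
  labs <- attr(tt, "term.labels")
  fac <- attr(tt, "factors")
  ord <- attr(tt, "order")
  vapply(seq_along(labs), function(i) {
    if (ord[i] == max(ord)) return(TRUE)
    vars <- rownames(fac)[fac[, i] > 0]
    !any(vapply(seq_along(labs), function(j) {
      j != i && ord[j] > ord[i] &&
        all(vars %in% rownames(fac)[fac[, j] > 0])
    }, logical(1)))
  }, logical(1)) -> ok
  labs[ok]
}

#' Backward stepwise selection on AICc
#'
#' At each step every removable term (interactions before their main
#' effects) is dropped in turn; the candidate with the lowest AICc is
#' accepted when its AICc is lower than, or within `delta` of, the
#' current model's (the simpler model is preferred on near-ties). A
#' supplementary likelihood-ratio p value is recorded for every accepted
#' removal. Candidate ties within 1e-9 AICc are broken by the larger LRT
#' p, then lexicographically.
#'
#' @param data Model frame.
#' @param formula Full-model formula.
#' @param family Passed to [fit_parasite_glm()].
#' @param delta AICc equivalence margin (default 2).
#' @return List of class `stepwise_result`: `final` (a `parasite_fit`),
#'   `formula`, `trace` (tibble of accepted removals), and
#'   `retained_terms`.
#' @export
backward_stepwise <- function(data, formula,
                              family = c("poisson", "nbinom",
                                         "bernoulli"),
                              delta = 2) {
  family <- match.arg(family)
  current <- fit_parasite_glm(data, formula, family)
  trace <- list()
  repeat {
    labs <- .removable_terms(current$formula)
    if (!length(labs)) break
    cand <- lapply(labs, function(tm) {
      f2 <- stats::update(current$formula,
                          stats::as.formula(paste("~ . -", tm)))
      fit2 <- try(fit_parasite_glm(data, f2, family), silent = TRUE)
      if (inherits(fit2, "try-error")) return(NULL)
      lr <- max(0, 2 * (current$logLik - fit2$logLik))
      df <- max(1, current$k - fit2$k)
      list(term = tm, fit = fit2, aicc = fit2$aicc,
           p = stats::pchisq(lr, df, lower.tail = FALSE))
    })
    cand <- cand[!vapply(cand, is.null, logical(1))]
    if (!length(cand)) break
    av <- vapply(cand, `[[`, numeric(1), "aicc")
    pv <- vapply(cand, `[[`, numeric(1), "p")
    tmv <- vapply(cand, `[[`, character(1), "term")
    best <- order(av, -pv, tmv)[1]
    if (av[best] >= current$aicc + delta) break
    trace[[length(trace) + 1]] <- tibble::tibble(
      removed = tmv[best], aicc_before = current$aicc,
      aicc_after = av[best], lrt_p = pv[best])
    current <- cand[[best]]$fit
  }
  structure(list(final = current, formula = current$formula,
                 trace = dplyr::bind_rows(trace),
                 retained_terms = attr(stats::terms(current$formula),
                                       "term.labels")),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result> final: ",
      deparse(x$formula), "  AICc = ", round(x$final$aicc, 2), "\n",
      sep = "")
  invisible(x)
}

# assemble the modelling frame: responses + predictors per individual
.series_frame <- function(parasites, genotypes, supertypes = NULL) {
  taxa <- .parasite_taxa_cols(parasites)
  df <- parasites
  df$season <- factor(df$season)
  df$group <- factor(df$group)
  df$year <- factor(df$year)
  g <- genotypes[!is.na(genotypes$allele), ]
  if (!is.null(supertypes)) {
    g <- dplyr::inner_join(g, supertypes, by = "allele")
    g$allele <- g$supertype
  }
  counts <- dplyr::summarise(
    dplyr::group_by(g, .data$individual),
    DAB_t = dplyr::n_distinct(.data$allele),
    DAB1_t = dplyr::n_distinct(.data$allele[.data$lineage == "DAB1"]),
    DAB3_t = dplyr::n_distinct(.data$allele[.data$lineage == "DAB3"]),
    .groups = "drop")
  df <- dplyr::left_join(df, counts, by = "individual")
  for (col in c("DAB_t", "DAB1_t", "DAB3_t")) {
    df[[col]][is.na(df[[col]])] <- 0
  }
  list(frame = df, taxa = taxa, alleles_long = g)
}

.sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Run a parasite-association model series
#'
#' Builds and selects one model per response, mirroring the standard
#' screen layouts: `"counts"` tests season + fish group + allele counts
#' (`DAB_t`, or `DAB1_t`/`DAB3_t`) with count-by-group interactions on
#' the pooled data; `"alleles-by-group"` and `"supertypes-by-group"` test
#' season plus each eligible presence predictor within one host group.
#' Responses are total richness and per-taxon abundance or prevalence
#' (the form chosen by the 30 percent prevalence rule). Families:
#' Poisson (richness), negative binomial (abundance), Bernoulli
#' (prevalence).
#'
#' @param parasites Wide parasite tibble.
#' @param genotypes Tidy genotype tibble.
#' @param series One of `"counts"`, `"alleles-by-group"`,
#'   `"supertypes-by-group"`.
#' @param group Host group for the by-group series.
#' @param supertypes Optional `allele`,`supertype` mapping (required for
#'   the supertype series).
#' @param count_predictors `"total"` (DAB_t) or `"by_lineage"`
#'   (DAB1_t + DAB3_t) for the counts series.
#' @param season_subset Optional season restriction (e.g. `"spring"`).
#' @param min_carriers Carrier threshold for presence predictors.
#' @param prevalence_threshold,strict_prevalence Response-form rule.
#' @param responses Optional subset of response names.
#' @return Tibble of class `model_series`: one row per retained term per
#'   response (`response`, `form`, `family`, `term`, `estimate`, `sign`,
#'   `lrt_p`, `aicc`), with per-response fits in the `"fits"` attribute.
#'   A Benjamini-Hochberg adjusted p column (`lrt_p_bh`) is appended as a
#'   supplementary, clearly non-primary multiple-testing aid.
#' @export
run_model_series <- function(parasites, genotypes,
                             series = c("counts", "alleles-by-group",
                                        "supertypes-by-group"),
                             group = NULL, supertypes = NULL,
                             count_predictors = c("total", "by_lineage"),
                             season_subset = NULL, min_carriers = 7,
                             prevalence_threshold = 0.3,
                             strict_prevalence = FALSE,
                             responses = NULL) {
  series <- match.arg(series)
  count_predictors <- match.arg(count_predictors)
  if (series == "supertypes-by-group" && is.null(supertypes)) {
    stop("the supertype series needs an allele-supertype mapping")
  }
  sf <- .series_frame(parasites, genotypes,
                      if (series == "supertypes-by-group") supertypes)
  df <- sf$frame
  if (series != "counts") {
    if (is.null(group)) stop("by-group series need `group`")
    df <- df[df$group == group, ]
  }
  if (!is.null(season_subset)) df <- df[df$season %in% season_subset, ]

  # response set: total richness + each taxon
  df$richness <- rowSums(df[, sf$taxa, drop = FALSE] > 0)
  resp_specs <- list(list(name = "richness", col = "richness",
                          form = "richness", family = "poisson"))
  for (tx in sf$taxa) {
    prev <- mean(df[[tx]] > 0)
    if (prev == 0 || all(df[[tx]] == df[[tx]][1])) next
    form <- choose_response_form(prev, prevalence_threshold,
                                 strict_prevalence)
    if (form == "prevalence") {
      df[[paste0(tx, "_prev")]] <- as.integer(df[[tx]] > 0)
      resp_specs[[length(resp_specs) + 1]] <-
        list(name = tx, col = paste0(tx, "_prev"), form = "prevalence",
             family = "bernoulli")
    } else {
      resp_specs[[length(resp_specs) + 1]] <-
        list(name = tx, col = tx, form = "abundance", family = "nbinom")
    }
  }
  if (!is.null(responses)) {
    resp_specs <- Filter(function(s) s$name %in% responses, resp_specs)
  }

  # predictor block
  drop_const <- function(v) length(unique(df[[v]])) > 1
  if (series == "counts") {
    base <- Filter(drop_const, c("season", "group", "year"))
    preds <- if (count_predictors == "total") {
      c(base, "DAB_t",
        if ("group" %in% base) "DAB_t:group")
    } else {
      c(base, "DAB1_t", "DAB3_t",
        if ("group" %in% base) c("DAB1_t:group", "DAB3_t:group"))
    }
  } else {
    elig <- eligible_predictors(sf$alleles_long, group, min_carriers)
    carriers <- lapply(elig, function(a) {
      unique(sf$alleles_long$individual[sf$alleles_long$allele == a])
    })
    pres_cols <- character(0)
    for (i in seq_along(elig)) {
      cn <- paste0("has_", .sanitize(elig[i]))
      df[[cn]] <- as.integer(df$individual %in% carriers[[i]])
      if (length(unique(df[[cn]])) > 1) pres_cols <- c(pres_cols, cn)
    }
    preds <- c(Filter(drop_const, c("season", "year")), pres_cols)
  }
  if (!length(preds)) preds <- "1"

  rows <- list(); fits <- list()
  for (spec in resp_specs) {
    f <- stats::as.formula(paste(spec$col, "~",
                                 paste(preds, collapse = " + ")))
    st <- try(backward_stepwise(df, f, spec$family), silent = TRUE)
    if (inherits(st, "try-error")) next
    fits[[spec$name]] <- st
    terms_kept <- st$retained_terms
    if (!length(terms_kept)) {
      rows[[spec$name]] <- tibble::tibble(
        response = spec$name, form = spec$form, family = spec$family,
        term = "(none)", estimate = NA_real_, sign = NA_character_,
        lrt_p = NA_real_, aicc = st$final$aicc)
      next
    }
    co <- st$final$coefficients
    rws <- lapply(terms_kept, function(tm) {
      hit <- grep(paste0("^", gsub(":", ".*:", .sanitize(tm))),
                  .sanitize(names(co)))
      est <- if (length(hit)) unname(co[hit[length(hit)]]) else NA_real_
      # LRT p for removing the term from the final model
      f2 <- stats::update(st$final$formula,
                          stats::as.formula(paste("~ . -", tm)))
      p <- tryCatch({
        fit2 <- fit_parasite_glm(df, f2, spec$family)
        lr <- max(0, 2 * (st$final$logLik - fit2$logLik))
        stats::pchisq(lr, max(1, st$final$k - fit2$k),
                      lower.tail = FALSE)
      }, error = function(e) NA_real_)
      tibble::tibble(response = spec$name, form = spec$form,
                     family = spec$family, term = tm,
                     estimate = unname(est),
                     sign = ifelse(is.na(est), NA_character_,
                                   ifelse(est >= 0, "+", "-")),
                     lrt_p = p, aicc = st$final$aicc)
    })
    rows[[spec$name]] <- dplyr::bind_rows(rws)
  }
  out <- dplyr::bind_rows(rows)
  out$lrt_p_bh <- stats::p.adjust(out$lrt_p, method = "BH")
  structure(out, class = c("model_series", class(out)), fits = fits,
            series = series, group = group)
}
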