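# Random-site codon models: M0, M1a, M2a, M3, M7, M8.
#
# Likelihood engine: GY94 rate matrices per omega class, shared branch
# lengths up to one free tree-scale parameter, PAML-style normalisation (a
# single scale factor equal to the class-proportion-weighted mean rate, so
# relative rates between classes are preserved). Inner pruning loop is
# compiled (src/pruning.cpp).

# ---- beta discretisation (M7/M8) ------------------------------------------

# Means of K equal-probability categories of Beta(p, q)
beta_category_means <- function(p, q, K = 10) {
  p <- min(max(p, 1e-3), 999)
  q <- min(max(q, 1e-3), 999)
  b <- stats::qbeta((0:K) / K, p, q)
  # E[X; bin] via the partial expectation I_x(p+1, q) * p/(p+q)
  pe <- stats::pbeta(b, p + 1, q) * p / (p + q)
  mk <- (pe[-1] - pe[-(K + 1)]) * K
  pmin(pmax(mk, 1e-8), 1 - 1e-8)
}

# ---- parameter transforms --------------------------------------------------

.stick_to_props <- function(x) {
  # K-1 unconstrained values -> K proportions
  v <- stats::plogis(x)
  K <- length(x) + 1
  p <- numeric(K)
  rem <- 1
  for (i in seq_along(x)) {
    p[i] <- rem * v[i]
    rem <- rem - p[i]
  }
  p[K] <- rem
  p
}

.props_to_stick <- function(p) {
  K <- length(p)
  x <- numeric(K - 1)
  rem <- 1
  for (i in seq_len(K - 1)) {
    x[i] <- stats::qlogis(min(max(p[i] / rem, 1e-8), 1 - 1e-8))
    rem <- rem - p[i]
  }
  x
}

.SITE_MODELS <- c("M0", "M1a", "M2a", "M3", "M7", "M8")

# number of free parameters (kappa + tree scale + model parameters)
.model_np <- function(model, k_classes = 3) {
  switch(model,
    M0 = 3, M1a = 4, M2a = 6, M3 = 2 + (2 * k_classes - 1), M7 = 4, M8 = 6)
}

# transformed parameter vector -> named model parameters
.unpack_params <- function(model, par, k_classes = 3, n_beta = 10) {
  kappa <- exp(par[1])
  scale <- exp(par[2])
  rest <- par[-(1:2)]
  out <- list(kappa = kappa, scale = scale)
  if (model == "M0") {
    out$props <- 1
    out$omegas <- exp(rest[1])
  } else if (model == "M1a") {
    p0 <- stats::plogis(rest[1])
    out$props <- c(p0, 1 - p0)
    out$omegas <- c(stats::plogis(rest[2]), 1)
  } else if (model == "M2a") {
    out$props <- .stick_to_props(rest[1:2])
    out$omegas <- c(stats::plogis(rest[3]), 1, 1 + exp(rest[4]))
  } else if (model == "M3") {
    K <- k_classes
    out$props <- .stick_to_props(rest[seq_len(K - 1)])
    out$omegas <- exp(rest[K:(2 * K - 1)])
  } else if (model == "M7") {
    out$p_beta <- exp(rest[1]); out$q_beta <- exp(rest[2])
    out$props <- rep(1 / n_beta, n_beta)
    out$omegas <- beta_category_means(out$p_beta, out$q_beta, n_beta)
  } else if (model == "M8") {
    p0 <- stats::plogis(rest[1])
    out$p_beta <- exp(rest[2]); out$q_beta <- exp(rest[3])
    out$omega_s <- 1 + exp(rest[4])
    out$props <- c(rep(p0 / n_beta, n_beta), 1 - p0)
    out$omegas <- c(beta_category_means(out$p_beta, out$q_beta, n_beta),
                    out$omega_s)
    out$p0 <- p0
  }
  out
}

.default_start <- function(model, k_classes = 3) {
  lk <- log(2); ls <- 0
  switch(model,
    M0 = c(lk, ls, log(0.4)),
    M1a = c(lk, ls, stats::qlogis(0.7), stats::qlogis(0.2)),
    M2a = c(lk, ls, .props_to_stick(c(0.6, 0.3, 0.1)),
            stats::qlogis(0.2), log(1)),
    M3 = c(lk, ls, .props_to_stick(rep(1 / k_classes, k_classes)),
           log(c(0.1, 0.5, 1.5))[seq_len(k_classes)]),
    M7 = c(lk, ls, log(0.5), log(1.5)),
    M8 = c(lk, ls, stats::qlogis(0.9), log(0.5), log(1.5), log(1)))
}

# ---- likelihood ------------------------------------------------------------

# per-pattern class log-likelihood matrix under a class mixture
.class_loglik <- function(pat, tree, kappa, omegas, freqs, edge_scale,
                          esl = NULL) {
  if (is.null(esl)) {
    esl <- lapply(omegas, function(w) codon_eigen(kappa, w, freqs))
  }
  prune_site_loglik(
    .tips_int(pat$tips),
    lapply(esl, `[[`, "V"), lapply(esl, `[[`, "Vinv"),
    lapply(esl, `[[`, "d"),
    tree$edge, tree$edge.length * edge_scale, freqs,
    length(tree$tip.label))
}

# mixture log-likelihood; returns total and per-pattern pieces
.mix_loglik <- function(pat, tree, kappa, scale, props, omegas, freqs) {
  keep <- props > 1e-12
  esl <- lapply(omegas, function(w) codon_eigen(kappa, w, freqs))
  mus <- vapply(esl, `[[`, numeric(1), "mean_rate")
  mu <- sum(props * mus)
  M <- .class_loglik(pat, tree, kappa, omegas[keep], freqs,
                     edge_scale = scale / mu, esl = esl[keep])
  lw <- matrix(log(props[keep]), nrow(M), ncol(M), byrow = TRUE)
  A <- M + lw
  mx <- apply(A, 1, max)
  site_ll <- mx + log(rowSums(exp(A - mx)))
  list(total = sum(pat$weights * site_ll), site = site_ll,
       class_ll = M, mu = mu, keep = keep)
}

#' Fit a random-site codon model
#'
#' Maximum-likelihood fit of one of the standard random-site models on a
#' fixed tree topology. Relative branch lengths are taken from the tree and
#' a single tree-scale factor is estimated jointly with the model
#' parameters. Optimisation is bounded quasi-Newton on transformed
#' parameters (log for kappa/omega/scale, stick-breaking logistic for class
#' proportions) with random multi-start.
#'
#' @param aln A [codon_alignment].
#' @param tree An [ape::phylo] tree whose tips match the alignment taxa.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M7"`, `"M8"`.
#' @param freq_mode Codon-frequency model passed to [codon_frequencies()].
#' @param k_classes Number of discrete classes for M3.
#' @param n_beta_cats Number of equal-probability beta categories for M7/M8
#'   (M8 adds one positive-selection class, 11 classes total at the
#'   default).
#' @param n_starts Number of optimiser starts (first from fixed defaults,
#'   the rest jittered).
#' @param seed Integer seed controlling the jittered restarts.
#' @param init Optional transformed-parameter start vector overriding the
#'   default first start (see [m2a_init_from_m1a()]).
#' @param control Optimiser control overrides passed to [stats::nlminb()].
#' @return A `codon_fit` object: maximum-likelihood estimates, `lnL`,
#'   per-site naive-empirical-Bayes class posteriors, convergence
#'   diagnostics.
#' @export
fit_site_model <- function(aln, tree,
                           model = c("M0", "M1a", "M2a", "M3", "M7", "M8"),
                           freq_mode = "F3x4", k_classes = 3,
                           n_beta_cats = 10, n_starts = 5, seed = 1,
                           init = NULL, control = list()) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  tree <- stats::reorder(ape::unroot(tree), "postorder")
  tree$edge.length[tree$edge.length < 1e-9] <- 1e-9
  pat <- .aln_patterns(aln, tree)
  freqs <- codon_frequencies(aln, freq_mode)

  negll <- function(par) {
    pp <- .unpack_params(model, par, k_classes, n_beta_cats)
    val <- try(.mix_loglik(pat, tree, pp$kappa, pp$scale, pp$props,
                           pp$omegas, freqs)$total, silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) {
      return(1e10)
    }
    -val
  }

  start0 <- if (is.null(init)) .default_start(model, k_classes) else init
  # initial tree scale: keep input branch lengths as-is
  best <- NULL
  starts_log <- list()
  for (s in seq_len(max(1, n_starts))) {
    par0 <- if (s == 1) {
      start0
    } else {
      withr::with_seed(substream_seed(seed, paste0("fit", model, s)),
                       start0 + stats::rnorm(length(start0), 0, 0.7))
    }
    ctrl <- utils::modifyList(list(rel.tol = 1e-9, eval.max = 2000,
                                   iter.max = 1000), control)
    opt <- try(stats::nlminb(par0, negll, lower = -15, upper = 15,
                             control = ctrl),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    starts_log[[length(starts_log) + 1]] <-
      tibble::tibble(start = s, lnL = -opt$objective,
                     convergence = opt$convergence)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("all optimiser starts failed for ", model)

  pp <- .unpack_params(model, best$par, k_classes, n_beta_cats)
  ml <- .mix_loglik(pat, tree, pp$kappa, pp$scale, pp$props, pp$omegas,
                    freqs)
  # naive empirical-Bayes class posteriors per alignment site
  A <- ml$class_ll + matrix(log(pp$props[ml$keep]), nrow(ml$class_ll),
                            ncol(ml$class_ll), byrow = TRUE)
  post <- exp(A - ml$site)
  post_full <- matrix(0, nrow(post), length(pp$props))
  post_full[, ml$keep] <- post
  structure(list(
    model = model, lnL = ml$total,
    kappa = pp$kappa, tree_scale = pp$scale,
    props = pp$props, omegas = pp$omegas,
    p_beta = pp$p_beta, q_beta = pp$q_beta, omega_s = pp$omega_s,
    p0 = pp$p0,
    np = .model_np(model, k_classes),
    n_beta_cats = n_beta_cats, k_classes = k_classes,
    freq_mode = freq_mode, freqs = freqs,
    site_class_post = post_full[pat$map, , drop = FALSE],
    mu = ml$mu, converged = best$convergence == 0,
    starts = dplyr::bind_rows(starts_log),
    tree = tree, aln = aln, par = best$par),
    class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit> ", x$model, "  lnL = ", format(x$lnL, digits = 8),
      "  kappa = ", signif(x$kappa, 3), "\n", sep = "")
  cat("  classes: ",
      paste(sprintf("p=%.3f w=%.3f", x$props, x$omegas), collapse = "; "),
      "\n", sep = "")
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

# ---- LRT -------------------------------------------------------------------

.NESTED_PAIRS <- list(c("M0", "M3"), c("M1a", "M2a"), c("M7", "M8"))

#' Likelihood-ratio test between nested site models
#'
#' Supported pairs: M0 vs M3, M1a vs M2a, M7 vs M8. The statistic is
#' clamped at zero when the alternative's optimum fell marginally below the
#' null's.
#'
#' @param null,alt `codon_fit` objects.
#' @return One-row tibble with `statistic` (2 delta lnL), `df`, `p_value`.
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "codon_fit"), inherits(alt, "codon_fit"))
  ok <- any(vapply(.NESTED_PAIRS, function(p) {
    identical(p, c(null$model, alt$model))
  }, logical(1)))
  if (!ok) {
    stop("models ", null$model, " and ", alt$model,
         " are not a supported nested pair")
  }
  df <- alt$np - null$np
  stat <- max(0, 2 * (alt$lnL - null$lnL))
  tibble::tibble(null = null$model, alt = alt$model, statistic = stat,
                 df = df, p_value = stats::pchisq(stat, df,
                                                  lower.tail = FALSE))
}

# ---- Bayes empirical Bayes -------------------------------------------------

# per-pattern log-likelihood columns for arbitrary omega values, with the
# effective branch lengths frozen at the fit's MLE
.loglik_by_omega <- function(fit, omegas) {
  pat <- .aln_patterns(fit$aln, fit$tree)
  .class_loglik(pat, fit$tree, fit$kappa, omegas, fit$freqs,
                edge_scale = fit$tree_scale / fit$mu)
}

#' Bayes empirical Bayes site posteriors
#'
#' Computes per-site posterior probabilities of the positive-selection
#' class and posterior mean omega under M2a or M8, integrating over a
#' uniform grid prior on the model's mixture parameters (Yang-Wong-Nielsen
#' scheme; kappa and branch lengths fixed at their MLEs). Grids use
#' `grid_points` midpoints per free dimension: class proportions on the
#' simplex, omega0 on (0,1), the positive-class omega on (1,11), and for M8
#' the beta shapes on (0,2].
#'
#' @param fit A converged `codon_fit` under M2a or M8.
#' @param grid_points Grid density per prior dimension.
#' @param levels Posterior-probability cutoffs for the PSS lists.
#' @return A `beb_result`: tibble with `site`, `p_positive`, `mean_omega`,
#'   `pss95`, `pss99`, plus `pss` lists in attributes.
#' @export
beb_site_posteriors <- function(fit, grid_points = 10,
                                levels = c(0.95, 0.99)) {
  stopifnot(inherits(fit, "codon_fit"))
  if (!fit$model %in% c("M2a", "M8")) {
    stop("BEB is available for M2a and M8 fits only")
  }
  d <- grid_points
  mid <- (2 * seq_len(d) - 1) / (2 * d)
  pat <- .aln_patterns(fit$aln, fit$tree)
  w <- pat$weights

  if (fit$model == "M2a") {
    w0_grid <- mid
    w2_grid <- 1 + 10 * mid
    Lg <- .loglik_by_omega(fit, c(w0_grid, 1, w2_grid))
    cmax <- apply(Lg, 1, max)
    FS <- exp(Lg - cmax)                 # patterns x (d + 1 + d), scaled
    pp <- expand.grid(p0 = mid, p1 = mid)
    pp <- pp[pp$p0 + pp$p1 <= 1, ]
    theta <- expand.grid(ip = seq_len(nrow(pp)), i0 = seq_len(d),
                         i2 = seq_len(d))
    S <- nrow(FS)
    logf <- numeric(nrow(theta))
    mixes <- matrix(0, S, nrow(theta))
    for (t in seq_len(nrow(theta))) {
      p0 <- pp$p0[theta$ip[t]]; p1 <- pp$p1[theta$ip[t]]
      p2 <- 1 - p0 - p1
      mix <- p0 * FS[, theta$i0[t]] + p1 * FS[, d + 1] +
        p2 * FS[, d + 1 + theta$i2[t]]
      mixes[, t] <- mix
      logf[t] <- sum(w * log(mix))
    }
    post <- exp(logf - max(logf)); post <- post / sum(post)
    p_pos <- mean_w <- numeric(S)
    for (t in seq_len(nrow(theta))) {
      if (post[t] < 1e-14) next
      p0 <- pp$p0[theta$ip[t]]; p1 <- pp$p1[theta$ip[t]]
      p2 <- 1 - p0 - p1
      f0 <- FS[, theta$i0[t]]; f1 <- FS[, d + 1]
      f2 <- FS[, d + 1 + theta$i2[t]]
      mix <- mixes[, t]
      p_pos <- p_pos + post[t] * p2 * f2 / mix
      mean_w <- mean_w + post[t] *
        (p0 * w0_grid[theta$i0[t]] * f0 + p1 * f1 +
           p2 * w2_grid[theta$i2[t]] * f2) / mix
    }
  } else { # M8
    p_grid <- 2 * mid
    q_grid <- 2 * mid
    ws_grid <- 1 + 10 * mid
    K <- fit$n_beta_cats
    pq <- expand.grid(ip = seq_len(d), iq = seq_len(d))
    # per (p, q): log-likelihood columns for the K category means
    SB <- WB <- matrix(0, length(w), nrow(pq))
    all_logs <- vector("list", nrow(pq))
    cat_means <- vector("list", nrow(pq))
    for (g in seq_len(nrow(pq))) {
      mk <- beta_category_means(p_grid[pq$ip[g]], q_grid[pq$iq[g]], K)
      cat_means[[g]] <- mk
      all_logs[[g]] <- .loglik_by_omega(fit, mk)
    }
    Lpos <- .loglik_by_omega(fit, ws_grid)
    cmax <- pmax(apply(Lpos, 1, max),
                 do.call(pmax, lapply(all_logs, function(m) {
                   apply(m, 1, max)
                 })))
    FPos <- exp(Lpos - cmax)
    for (g in seq_len(nrow(pq))) {
      Fb <- exp(all_logs[[g]] - cmax)
      SB[, g] <- rowSums(Fb) / K
      WB[, g] <- as.vector(Fb %*% cat_means[[g]]) / K
    }
    theta <- expand.grid(i0 = seq_len(d), g = seq_len(nrow(pq)),
                         iw = seq_len(d))
    S <- length(w)
    logf <- numeric(nrow(theta))
    for (t in seq_len(nrow(theta))) {
      p0 <- mid[theta$i0[t]]
      mix <- p0 * SB[, theta$g[t]] + (1 - p0) * FPos[, theta$iw[t]]
      logf[t] <- sum(w * log(mix))
    }
    post <- exp(logf - max(logf)); post <- post / sum(post)
    p_pos <- mean_w <- numeric(S)
    for (t in seq_len(nrow(theta))) {
      if (post[t] < 1e-14) next
      p0 <- mid[theta$i0[t]]
      fpos <- FPos[, theta$iw[t]]
      mix <- p0 * SB[, theta$g[t]] + (1 - p0) * fpos
      p_pos <- p_pos + post[t] * (1 - p0) * fpos / mix
      mean_w <- mean_w + post[t] *
        (p0 * WB[, theta$g[t]] +
           (1 - p0) * ws_grid[theta$iw[t]] * fpos) / mix
    }
  }

  map <- pat$map
  res <- tibble::tibble(
    site = seq_along(map),
    p_positive = pmin(pmax(p_pos[map], 0), 1),
    mean_omega = mean_w[map])
  res$pss95 <- res$p_positive >= levels[1]
  res$pss99 <- res$p_positive >= levels[2]
  structure(res, class = c("beb_result", class(res)),
            model = fit$model, grid_points = d,
            pss = lapply(levels, function(l) which(res$p_positive >= l)))
}

#' Shared and group-specific positively selected sites
#'
#' @param pss_sets Named list of integer site vectors (one per host group),
#'   indexed on a common alignment coordinate system.
#' @param n_sites Optional total number of sites (for validation only).
#' @return Tibble with one row per membership class (e.g. sites shared by
#'   all groups, sites exclusive to one group or pair): `groups`, `n`,
#'   `sites` (list-column).
#' @export
compare_pss_sets <- function(pss_sets, n_sites = NULL) {
  stopifnot(is.list(pss_sets), !is.null(names(pss_sets)))
  all_sites <- sort(unique(unlist(pss_sets)))
  if (!is.null(n_sites) && length(all_sites) && max(all_sites) > n_sites) {
    stop("PSS index exceeds alignment length; coordinate systems differ")
  }
  member <- vapply(all_sites, function(s) {
    paste(sort(names(pss_sets)[vapply(pss_sets, function(v) s %in% v,
                                      logical(1))]), collapse = "+")
  }, character(1))
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(site = all_sites, groups = member),
                      .data$groups),
      n = dplyr::n(), sites = list(.data$site), .groups = "drop"),
    dplyr::desc(.data$n))
}

#' Seed an M2a start from an M1a fit
#'
#' Builds a transformed-parameter start vector for M2a at the M1a optimum
#' plus a small positive-selection class, which typically cuts the M2a
#' optimisation cost in half (useful in simulation calibrations).
#'
#' @param m1a_fit A `codon_fit` under M1a.
#' @param p2 Initial positive-class proportion.
#' @param omega2 Initial positive-class omega.
#' @return Numeric start vector for `fit_site_model(..., model = "M2a",
#'   init = )`.
#' @export
m2a_init_from_m1a <- function(m1a_fit, p2 = 0.02, omega2 = 2) {
  stopifnot(inherits(m1a_fit, "codon_fit"), m1a_fit$model == "M1a")
  p0 <- m1a_fit$props[1] * (1 - p2)
  p1 <- m1a_fit$props[2] * (1 - p2)
  c(log(m1a_fit$kappa), log(m1a_fit$tree_scale),
    .props_to_stick(c(p0, p1, p2)),
    stats::qlogis(min(max(m1a_fit$omegas[1], 1e-6), 1 - 1e-6)),
    log(omega2 - 1))
}
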