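#' Bayesian model averaging over covariate subsets
#'
#' Averages the Gaussian linear model over all subsets of the selectable
#' covariates (always-included intercepts and cohort dummies are in every
#' model), weighting each model by its posterior probability under the
#' g-prior marginal likelihood and the model-space prior. Exact
#' enumeration visits all `2^k` subsets; the MC3 sampler walks model space
#' with single-covariate add/drop Metropolis proposals and reports
#' posterior weights renormalised over the set of visited models (each
#' visited model's evidence is exact), with raw visit frequencies kept in
#' the diagnostics.
#'
#' For each covariate the posterior inclusion probability (PIP) is the
#' total posterior probability of models containing it; conditional
#' coefficient moments are the model-probability-weighted mixture over the
#' models that include the covariate, with the conditional variance
#' obtained by the law of total variance across the model mixture.
#'
#' @param design a [bma_design] from [build_levels_design()],
#'   [build_difference_design()] or [bma_design()].
#' @param method `"enumerate"` (exact, requires `k <= enumeration_cap`) or
#'   `"mc3"`.
#' @param g g-prior scale; default `max(n, K^2)` (see
#'   [log_marginal_likelihood()]).
#' @param model_prior `"uniform"` over the `2^k` subsets (default) or
#'   `"binomial"` with per-covariate inclusion probability
#'   `prior_inclusion`.
#' @param prior_inclusion binomial prior inclusion probability in (0, 1).
#' @param enumeration_cap largest `k` enumerated exactly (default 20).
#' @param n_draws MC3 chain length (at least 1000; default 50000).
#' @param burnin MC3 iterations discarded from the visit-frequency
#'   diagnostics (renormalised weights use every visited model).
#' @param seed optional seed for the MC3 chain; a fixed seed reproduces
#'   the chain exactly.
#' @return An object of class `"bma"`: `pip` (named vector, one entry per
#'   covariate), `cond` (data frame of covariate x group conditional
#'   moments), `sigma2` (posterior summary of the error variance),
#'   `models` (per-model table), `diagnostics`, plus the design and prior
#'   settings. Supports `print()`, `summary()`, [coef()], [predict()],
#'   [fitted()], [residuals()] and `plot()`.
#' @export
bma_fit <- function(design, method = c("enumerate", "mc3"), g = NULL,
                    model_prior = c("uniform", "binomial"), prior_inclusion = 0.5,
                    enumeration_cap = 20, n_draws = 50000, burnin = 1000,
                    seed = NULL) {
  method <- match.arg(method)
  model_prior <- match.arg(model_prior)
  if (!inherits(design, "bma_design"))
    np_error("design must be a bma_design", "validation_error")
  if (model_prior == "binomial" &&
      (prior_inclusion <= 0 || prior_inclusion >= 1))
    np_error("prior_inclusion must lie strictly in (0, 1)", "configuration_error")
  k <- length(design$covariates)
  eng <- .evidence_engine(design, g)
  K <- eng$K
  pW <- eng$pW
  lprior <- function(m) {
    if (model_prior == "uniform") 0
    else m * log(prior_inclusion) + (k - m) * log1p(-prior_inclusion)
  }
  cols_of <- function(bits) unlist(design$cov_cols[bits], use.names = FALSE)

  # weighted-moment accumulators over models
  acc <- new.env(parent = emptyenv())
  acc$pip <- numeric(k)            # per covariate
  acc$wm <- numeric(K)             # sum p * E[gamma | M] per column
  acc$wm2 <- numeric(K)            # sum p * (Var + E^2)   per column
  acc$alpha <- numeric(pW)
  acc$sig <- 0
  add_model <- function(bits, p, st) {
    if (p <= 0) return(invisible())
    acc$pip[bits] <- acc$pip[bits] + p
    if (st$k) {
      cols <- st$cols
      acc$wm[cols] <- acc$wm[cols] + p * st$gamma_bar
      acc$wm2[cols] <- acc$wm2[cols] + p * (st$var_diag + st$gamma_bar^2)
      acc$alpha <- acc$alpha + p *
        (eng$alpha_null - drop(eng$AZ[, cols, drop = FALSE] %*% st$gamma_bar))
    } else {
      acc$alpha <- acc$alpha + p * eng$alpha_null
    }
    acc$sig <- acc$sig + p * st$S / (eng$nu - 2)
    invisible()
  }

  if (method == "enumerate") {
    if (k > enumeration_cap)
      np_error(sprintf("%d selectable covariates exceed the enumeration cap (%d); use method = \"mc3\"",
                       k, enumeration_cap), "domain_error")
    nm <- 2^k
    pow <- 2^(seq_len(k) - 1)
    logev <- numeric(nm)
    kM <- integer(nm)
    for (m in seq_len(nm)) {
      bits <- bitwAnd(m - 1, pow) > 0
      st <- eng$stats_for(cols_of(bits))
      logev[m] <- eng$logev_from(st)
      kM[m] <- st$k  # selectable columns; covariate count is sum(bits)
    }
    nbits <- vapply(seq_len(nm), function(m) sum(bitwAnd(m - 1, pow) > 0), 0L)
    lp <- logev + vapply(nbits, lprior, 0)
    post <- exp(lp - max(lp))
    post <- post / sum(post)
    for (m in seq_len(nm)) {
      if (post[m] < 1e-15) next
      bits <- bitwAnd(m - 1, pow) > 0
      add_model(bits, post[m], eng$stats_for(cols_of(bits)))
    }
    models <- data.frame(mask = seq_len(nm) - 1, n_covariates = nbits,
                         log_evidence = logev, post_prob = post)
    diagnostics <- list(method = "enumerate", n_models = nm)
  } else {
    if (!is.numeric(n_draws) || n_draws < 1000)
      np_error("MC3 needs n_draws >= 1000", "configuration_error")
    if (!is.null(seed)) set.seed(seed)
    burnin <- min(burnin, n_draws %/% 10)
    cache <- new.env(hash = TRUE, parent = emptyenv())
    get_model <- function(bits) {
      key <- paste0("m", paste(which(bits), collapse = ","))
      mo <- cache[[key]]
      if (is.null(mo)) {
        st <- eng$stats_for(cols_of(bits))
        mo <- list(bits = bits, st = st, logev = eng$logev_from(st))
        mo$lp <- mo$logev + lprior(sum(bits))
        cache[[key]] <- mo
      }
      mo
    }
    cur <- get_model(rep(FALSE, k))
    freq <- numeric(k)
    n_kept <- 0L
    n_acc <- 0L
    for (i in seq_len(n_draws)) {
      j <- sample.int(k, 1)
      bits <- cur$bits
      bits[j] <- !bits[j]
      prop <- tryCatch(get_model(bits), npheight_collinearity_error = function(e) NULL)
      if (!is.null(prop) && log(runif(1)) < prop$lp - cur$lp) {
        cur <- prop
        n_acc <- n_acc + 1L
      }
      if (i > burnin) {
        freq <- freq + cur$bits
        n_kept <- n_kept + 1L
      }
    }
    keys <- ls(cache)
    lps <- unname(vapply(keys, function(kk) cache[[kk]]$lp, 0))
    w <- exp(lps - max(lps))
    w <- w / sum(w)
    logev <- unname(vapply(keys, function(kk) cache[[kk]]$logev, 0))
    nbits <- unname(vapply(keys, function(kk) sum(cache[[kk]]$bits), 0L))
    for (ii in seq_along(keys)) {
      mo <- cache[[keys[ii]]]
      add_model(mo$bits, w[ii], mo$st)
    }
    models <- data.frame(model = keys, n_covariates = nbits,
                         log_evidence = logev, post_prob = w)
    models <- models[order(-models$post_prob), ]
    rownames(models) <- NULL
    diagnostics <- list(method = "mc3", n_draws = n_draws, burnin = burnin,
                        acceptance_rate = n_acc / n_draws,
                        n_visited = length(keys),
                        pip_freq = setNames(freq / n_kept, design$covariates))
  }

  pip <- setNames(acc$pip, design$covariates)
  # per-column mixture moments conditional on inclusion
  col_cov <- rep(design$covariates, vapply(design$cov_cols, length, 0L))[
    order(unlist(design$cov_cols, use.names = FALSE))]
  pip_col <- pip[col_cov]
  cond_mean <- ifelse(pip_col > 0, acc$wm / pip_col, NA_real_)
  cond_var <- ifelse(pip_col > 0, pmax(0, acc$wm2 / pip_col - cond_mean^2), NA_real_)
  zn <- colnames(design$Z) %||% paste0("z", seq_len(K))
  grp <- if (is.null(design$groups)) rep(NA_character_, K) else sub("^[^|]*\\|", "", zn)
  cond <- data.frame(covariate = col_cov, group = grp,
                     pip = unname(pip_col),
                     cond_mean = unname(cond_mean),
                     cond_sd = sqrt(unname(cond_var)),
                     row.names = NULL)

  structure(list(pip = pip, cond = cond,
                 alpha_mean = setNames(acc$alpha, colnames(design$W)),
                 uncond_mean = setNames(acc$wm, zn),
                 sigma2 = list(mean = acc$sig, df = eng$nu),
                 models = models, diagnostics = diagnostics,
                 g = eng$g, model_prior = model_prior,
                 prior_inclusion = if (model_prior == "uniform") 0.5 else prior_inclusion,
                 design = design, call = match.call()),
            class = "bma")
}

#' @export
print.bma <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Bayesian model averaging (Zellner g-prior, g = %.6g, %s model prior)\n",
              x$g, x$model_prior))
  if (d$method == "enumerate") {
    cat(sprintf("  exact enumeration of %d models; n = %d rows, %d covariates\n",
                d$n_models, x$design$n, length(x$pip)))
  } else {
    cat(sprintf("  MC3: %d draws, acceptance %.2f, %d models visited; n = %d rows, %d covariates\n",
                d$n_draws, d$acceptance_rate, d$n_visited, x$design$n))
  }
  cat("Posterior inclusion probabilities:\n")
  print(round(sort(x$pip, decreasing = TRUE), 3))
  invisible(x)
}

#' @export
summary.bma <- function(object, ...) {
  cond <- object$cond
  cond$lo2sd <- cond$cond_mean - 2 * cond$cond_sd
  cond$hi2sd <- cond$cond_mean + 2 * cond$cond_sd
  out <- list(cond = cond[order(-cond$pip), ],
              sigma2 = object$sigma2,
              g = object$g, diagnostics = object$diagnostics)
  class(out) <- "summary.bma"
  out
}

#' @export
print.summary.bma <- function(x, ...) {
  cat("Covariate x group posterior summary (conditional on inclusion):\n")
  tab <- x$cond
  tab[-(1:2)] <- lapply(tab[-(1:2)], function(z) round(z, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("\nPosterior mean error variance: %.4f (df %d), g = %.6g\n",
              x$sigma2$mean, x$sigma2$df, x$g))
  invisible(x)
}

#' @export
coef.bma <- function(object, ...) {
  c(object$alpha_mean, object$uncond_mean)
}

#' @export
predict.bma <- function(object, newdata = NULL, ...) {
  design <- newdata %||% object$design
  if (!inherits(design, "bma_design"))
    np_error("newdata must be a bma_design built with the same columns", "validation_error")
  drop(design$W %*% object$alpha_mean + design$Z %*% object$uncond_mean)
}

#' @export
fitted.bma <- function(object, ...) predict(object)

#' @export
residuals.bma <- function(object, ...) object$design$y - fitted(object)

#' Mixture posterior density of one coefficient
#'
#' The full posterior of a selectable coefficient is a two-part mixture: a
#' point mass `1 - PIP` at zero (the covariate excluded) plus a continuous
#' component conditional on inclusion. The continuous component is
#' summarised by its mixture moments across models and exported on a grid
#' as a moment-matched scaled-t density (df = residual degrees of
#' freedom); a tall spike at zero signals a high probability that the
#' covariate is excluded from the model.
#'
#' @param object a fitted [bma_fit()] object.
#' @param covariate covariate name.
#' @param group group label for grouped designs (ignored otherwise).
#' @param n number of grid points.
#' @return List with `pip`, `point_mass` (`1 - pip`), `cond_mean`,
#'   `cond_sd`, `median_impact` (median of the symmetric conditional
#'   component), and `grid`, a data frame of `(value, density)` pairs for
#'   the continuous part scaled by `pip`. The mixture mean is
#'   `pip * cond_mean`.
#' @export
coefficient_density <- function(object, covariate, group = NULL, n = 257) {
  if (!inherits(object, "bma")) np_error("object must be a bma fit", "validation_error")
  cond <- object$cond
  sel <- cond$covariate == covariate
  if (!any(sel))
    np_error(sprintf("unknown covariate '%s'", covariate), "domain_error")
  if (!is.null(object$design$groups)) {
    if (is.null(group)) {
      group <- object$design$groups[1]
    } else if (!group %in% object$design$groups) {
      np_error(sprintf("unknown group '%s'", group), "domain_error")
    }
    sel <- sel & cond$group == group
  }
  row <- cond[sel, ][1, ]
  pip <- row$pip
  m <- row$cond_mean
  s <- row$cond_sd
  df <- object$sigma2$df
  if (!is.finite(pip) || pip <= 0 || !is.finite(m)) {
    grid <- data.frame(value = 0, density = 0)
    return(list(covariate = covariate, group = group, pip = max(pip, 0),
                point_mass = 1 - max(pip, 0), cond_mean = NA_real_,
                cond_sd = NA_real_, median_impact = NA_real_, grid = grid))
  }
  if (!is.finite(s) || s == 0) {
    grid <- data.frame(value = m, density = Inf)
  } else {
    scale <- s * sqrt((df - 2) / df)
    v <- seq(m - 4 * s, m + 4 * s, length.out = n)
    grid <- data.frame(value = v, density = pip * dt((v - m) / scale, df) / scale)
  }
  list(covariate = covariate, group = group, pip = pip, point_mass = 1 - pip,
       cond_mean = m, cond_sd = s, median_impact = m, grid = grid)
}

#' @param x a fitted `bma` object.
#' @param covariates covariates to draw, default the six with highest PIP.
#' @param ... passed to [plot()].
#' @rdname bma_fit
#' @export
plot.bma <- function(x, covariates = NULL, ...) {
  covariates <- covariates %||%
    names(sort(x$pip, decreasing = TRUE))[seq_len(min(6, length(x$pip)))]
  groups <- x$design$groups %||% NA
  panels <- expand.grid(covariate = covariates, group = groups,
                        stringsAsFactors = FALSE)
  old <- par(mfrow = c(length(covariates), length(groups)),
             mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.4, 0.4, 0))
  on.exit(par(old))
  for (i in seq_len(nrow(panels))) {
    cv <- panels$covariate[i]
    gr <- if (is.na(panels$group[i])) NULL else panels$group[i]
    den <- coefficient_density(x, cv, gr)
    ttl <- if (is.null(gr)) cv else paste0(cv, " | ", gr)
    if (all(!is.finite(den$grid$density)) || den$pip <= 0) {
      plot(0, 0, type = "n", xlim = c(-1, 1), ylim = c(0, 1),
           xlab = "coefficient", ylab = "density", main = ttl, ...)
    } else {
      plot(den$grid$value, den$grid$density, type = "l",
           xlab = "coefficient", ylab = "density", main = ttl, ...)
    }
    abline(v = 0, lty = 2)
    ymax <- if (any(is.finite(den$grid$density))) max(den$grid$density[is.finite(den$grid$density)]) else 1
    segments(0, 0, 0, den$point_mass * max(ymax, 1e-12), lwd = 3, col = "grey40")
  }
  invisible(x)
}
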