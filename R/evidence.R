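# Zellner g-prior evidence machinery.
#
# Model: y = W a + Z_M g_M + e,  e ~ N(0, s2 I), shared across groups.
# Priors: p(a) proportional to 1, p(s2) proportional to 1/s2, and
#   g_M | s2 ~ N(0, g * s2 * (Z*' Z*)^-1) with Z* = (I - P_W) Z_M, i.e. a
#   Zellner g-prior on the selectable block after projecting out the
#   always-included block. Integrating a, g_M and s2 gives the closed-form
#   log marginal likelihood
#     -(nu/2) log(2 pi) - (1/2) log|W'W| + lgamma(nu/2)
#       - (k/2) log(1 + g) - (nu/2) log(S_M / 2)
# with nu = n - ncol(W), k = ncol(Z_M) and
#     S_M = RSS_W - g/(1+g) * (RSS_W - RSS_{W+Z_M}).

.evidence_engine <- function(design, g = NULL) {
  W <- design$W
  y <- design$y
  n <- design$n
  qrW <- qr(W)
  if (qrW$rank < ncol(W))
    np_error("always-included block is rank deficient", "collinearity_error")
  pW <- ncol(W)
  nu <- n - pW
  if (nu <= 2)
    np_error("too few rows relative to the always-included block", "insufficient_data_error")
  ytil <- qr.resid(qrW, y)
  Ztil <- qr.resid(qrW, design$Z)
  C <- crossprod(Ztil)
  b <- drop(crossprod(Ztil, ytil))
  yy <- sum(ytil^2)
  K <- ncol(design$Z)
  if (is.null(g)) g <- max(n, K^2)   # benchmark (BRIC) default
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g <= 0)
    np_error("g must be a single positive number", "configuration_error")
  delta <- g / (1 + g)
  logdetWW <- 2 * sum(log(abs(diag(qr.R(qrW))[seq_len(pW)])))
  const <- -nu / 2 * log(2 * pi) - 0.5 * logdetWW + lgamma(nu / 2)
  alpha_null <- drop(qr.coef(qrW, y))
  AZ <- qr.coef(qrW, design$Z)  # pW x K, maps gamma-bar to alpha adjustment

  stats_for <- function(cols) {
    k <- length(cols)
    if (!k)
      return(list(k = 0L, S = yy, gamma_bar = numeric(0),
                  var_diag = numeric(0), cols = integer(0)))
    Cs <- C[cols, cols, drop = FALSE]
    R <- tryCatch(chol(Cs), error = function(e) NULL)
    tol <- sqrt(.Machine$double.eps) * sqrt(max(diag(Cs)))
    if (is.null(R) || any(diag(R) < tol))
      np_error(sprintf("collinear covariate columns given the always-included block: %s",
                       paste(colnames(design$Z)[cols], collapse = ", ")),
               "collinearity_error")
    u <- backsolve(R, b[cols], transpose = TRUE)
    fitSS <- sum(u^2)
    gamma_hat <- backsolve(R, u)
    S <- yy - delta * fitSS
    gamma_bar <- delta * gamma_hat
    var_diag <- delta * S / (nu - 2) * diag(chol2inv(R))
    list(k = k, S = S, gamma_bar = gamma_bar, var_diag = var_diag, cols = cols)
  }

  logev_from <- function(st) const - st$k / 2 * log1p(g) - nu / 2 * log(st$S / 2)

  list(g = g, nu = nu, pW = pW, K = K, delta = delta, const = const,
       alpha_null = alpha_null, AZ = AZ,
       stats_for = stats_for, logev_from = logev_from)
}

#' Log marginal likelihood of one covariate subset under the g-prior
#'
#' Closed-form integrated likelihood of the Gaussian linear model for a
#' given subset of selectable covariates, under Zellner's g-prior on the
#' selectable coefficients (after projecting out the always-included
#' block) and diffuse priors on the always-included coefficients and the
#' error variance. Deterministic; in a grouped design a covariate brings
#' both of its group-specific columns into the model.
#'
#' @param design a [bma_design], e.g. from [build_levels_design()].
#' @param include covariates in the model: a character subset of
#'   `design$covariates` or a logical vector along them. The empty subset
#'   gives the null model, whose evidence depends on the data only through
#'   the residual sum of squares around the always-included fit.
#' @param g prior scale; default `max(n, K^2)` where `K` is the number of
#'   selectable columns (the benchmark "BRIC" rule).
#' @return The log marginal likelihood (a single number, including all
#'   constants).
#' @export
log_marginal_likelihood <- function(design, include = design$covariates, g = NULL) {
  if (!inherits(design, "bma_design"))
    np_error("design must be a bma_design", "validation_error")
  if (is.logical(include)) {
    if (length(include) != length(design$covariates))
      np_error("logical include must match the number of covariates", "domain_error")
    include <- design$covariates[include]
  }
  unknown <- setdiff(include, design$covariates)
  if (length(unknown))
    np_error(sprintf("unknown covariate(s): %s", paste(unknown, collapse = ", ")),
             "domain_error")
  eng <- .evidence_engine(design, g)
  cols <- unlist(design$cov_cols[include], use.names = FALSE)
  eng$logev_from(eng$stats_for(cols))
}
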