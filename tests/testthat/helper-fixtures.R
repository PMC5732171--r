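# Shared fixture builders. Everything is generated in code; no data files.

# A tiny deterministic analysis panel with explicit values.
toy_panel <- function() {
  expand_base <- expand.grid(country = c("AAA", "BBB", "CCC", "DDD"),
                             cohort = c("1960s", "1970s", "1980s"),
                             stringsAsFactors = FALSE)
  out <- expand_base[order(expand_base$country, expand_base$cohort), ]
  out$height <- c(170, 171, 172, 175, 176, 177, 160, 160, 161, 164, 165, 165)
  out$N <- c(10, 11, 12, 18, 19, 20, 5, 5.5, 6, 7, 7.5, 8)
  out$P <- c(1.2, 1.25, 1.3, 2.0, 2.1, 2.2, 0.7, 0.72, 0.75, 0.9, 0.95, 1.0)
  out$NP <- out$N / out$P
  out$GDP <- c(5000, 6000, 7000, 30000, 35000, 40000, 1000, 1100, 1300,
               2000, 2300, 2500)
  out$Cal <- c(2500, 2550, 2600, 3300, 3350, 3400, 2000, 2050, 2100,
               2200, 2250, 2300)
  out$diet_group <- rep(c("animal-dominated", "animal-dominated",
                          "plant-dominated", "plant-dominated"), each = 3)
  rownames(out) <- NULL
  out
}

# Random ungrouped design with known structure for evidence/BMA tests.
random_design <- function(n, k, seed, beta = rep(0, k), noise_sd = 1,
                          W = NULL) {
  set.seed(seed)
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  Z <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
  y <- drop(W %*% rep(1, ncol(W)) + Z %*% beta + rnorm(n, 0, noise_sd))
  bma_design(y, W, Z, covariates = colnames(Z),
             cov_cols = as.list(setNames(seq_len(k), colnames(Z))))
}

# Brute-force quadrature of the g-prior marginal likelihood: the
# always-included block is integrated analytically under its flat prior;
# the selectable coefficients and log error variance are integrated on
# dense trapezoid grids. Independent of the closed form under test.
quadrature_evidence <- function(design, cols, g, n_gamma = 161, n_u = 241) {
  y <- design$y; W <- design$W
  n <- length(y); pW <- ncol(W)
  Zs <- design$Z[, cols, drop = FALSE]; k <- ncol(Zs)
  qrW <- qr(W)
  ytil <- qr.resid(qrW, y)
  Ztil <- matrix(apply(Zs, 2, function(z) qr.resid(qrW, z)), nrow = n)
  V <- crossprod(Ztil)
  logdetWW <- 2 * sum(log(abs(diag(qr.R(qrW)))))
  gh <- qr.coef(qr(Ztil), ytil)
  sdg <- sqrt(g * diag(solve(V)) * sum(ytil^2) / n)
  grids <- lapply(seq_len(k), function(j)
    seq(gh[j] - 12 * sdg[j], gh[j] + 12 * sdg[j], length.out = n_gamma))
  gam <- as.matrix(expand.grid(grids))
  R2 <- colSums((ytil - Ztil %*% t(gam))^2)
  Q <- rowSums((gam %*% V) * gam)
  s2hat <- sum(qr.resid(qr(cbind(W, Zs)), y)^2) / n
  us <- seq(log(s2hat) - 14, log(s2hat) + 14, length.out = n_u)
  logdetV <- as.numeric(determinant(V)$modulus)
  lw_u <- vapply(us, function(u) {
    lf <- -(n - pW) / 2 * (log(2 * pi) + u) - 0.5 * logdetWW - R2 / (2 * exp(u)) -
      k / 2 * (log(2 * pi) + log(g) + u) + 0.5 * logdetV - Q / (2 * g * exp(u))
    m <- max(lf)
    m + log(sum(exp(lf - m)))
  }, 0)
  dg <- prod(vapply(grids, function(gr) gr[2] - gr[1], 0))
  du <- us[2] - us[1]
  mu <- max(lw_u)
  mu + log(sum(exp(lw_u - mu) * c(0.5, rep(1, n_u - 2), 0.5)) * du * dg)
}

# Exact PIPs by direct summation over all subsets, using only the
# closed-form evidence (shared by the enumeration and MC3 agreement tests).
pip_by_enumeration <- function(fit) sort(fit$pip)
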