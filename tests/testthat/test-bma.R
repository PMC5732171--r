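test_that("enumeration visits all 2^k models and the posterior normalises", {
  d <- random_design(n = 40, k = 11, seed = 31, beta = c(1, rep(0, 10)),
                     noise_sd = 1)
  fit <- bma_fit(d)
  expect_equal(nrow(fit$models), 2048)
  expect_equal(sum(fit$models$post_prob), 1, tolerance = 1e-12)
  expect_true(all(fit$pip >= 0 & fit$pip <= 1))
  # enumeration refuses k above the cap and points at the sampler
  expect_error(bma_fit(d, enumeration_cap = 8), "mc3",
               class = "npheight_domain_error")
})

test_that("a strong covariate earns a high PIP and pure nulls stay low", {
  # one true covariate with standardized effect 0.8 among 9 nulls, n = 240
  set.seed(77)
  n <- 240
  Z <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- drop(5 + 0.8 * Z[, 1] + rnorm(n, 0, 1))
  d <- bma_design(y, W = matrix(1, n, 1), Z = Z, covariates = colnames(Z),
                  cov_cols = as.list(setNames(1:10, colnames(Z))))
  fit <- bma_fit(d)
  expect_gt(fit$pip[["x1"]], 0.95)
  expect_lt(median(fit$pip[-1]), 0.3)
  # conditional mean of the true coefficient is near its generating value
  cm <- fit$cond$cond_mean[fit$cond$covariate == "x1"]
  expect_equal(cm, 0.8, tolerance = 0.25)
})

test_that("MC3 agrees with exact enumeration and is seed-reproducible", {
  d <- random_design(n = 60, k = 6, seed = 41, beta = c(0.8, -0.5, 0, 0, 0, 0),
                     noise_sd = 1)
  exact <- bma_fit(d, method = "enumerate")
  mc3 <- bma_fit(d, method = "mc3", n_draws = 50000, seed = 99)
  expect_lt(max(abs(mc3$pip - exact$pip)), 0.02)
  expect_equal(mc3$sigma2$mean, exact$sigma2$mean, tolerance = 0.02)
  # fixed seed -> identical chain and identical posterior
  mc3b <- bma_fit(d, method = "mc3", n_draws = 50000, seed = 99)
  expect_identical(mc3$pip, mc3b$pip)
  expect_identical(mc3$diagnostics$pip_freq, mc3b$diagnostics$pip_freq)
  expect_error(bma_fit(d, method = "mc3", n_draws = 10),
               class = "npheight_configuration_error")
})

test_that("a noiseless single-covariate posterior concentrates on the true model", {
  set.seed(51)
  n <- 30
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- drop(1 + 2 * Z[, 1])  # no noise
  d <- bma_design(y, W = matrix(1, n, 1), Z = Z, covariates = colnames(Z),
                  cov_cols = as.list(setNames(1:3, colnames(Z))))
  mc3 <- bma_fit(d, method = "mc3", n_draws = 5000, seed = 1)
  expect_gt(mc3$pip[["x1"]], 0.999)
  den <- coefficient_density(mc3, "x1")
  expect_lt(den$point_mass, 0.001)
  # conditional mean is the g-prior-shrunk least-squares coefficient
  expect_equal(den$cond_mean, 2 * mc3$g / (1 + mc3$g), tolerance = 1e-6)
  # with PIP ~ 1 the continuous component carries (almost) the whole mass
  expect_equal(sum(den$grid$density) * diff(den$grid$value[1:2]), den$pip,
               tolerance = 0.02)
})

test_that("the coefficient posterior is a spike plus conditional-component mixture", {
  d <- random_design(n = 80, k = 4, seed = 61, beta = c(0.6, 0, 0, 0),
                     noise_sd = 1)
  fit <- bma_fit(d)
  for (cv in c("x1", "x3")) {
    den <- coefficient_density(fit, cv)
    expect_equal(den$point_mass, 1 - fit$pip[[cv]], tolerance = 1e-12)
    # mixture mean identity, checked against draws from the two-part mixture
    set.seed(8)
    nsim <- 2e5
    inc <- runif(nsim) < den$pip
    draws <- ifelse(inc, rnorm(nsim, den$cond_mean, den$cond_sd), 0)
    mix_mean <- den$pip * den$cond_mean
    expect_lt(abs(mean(draws) - mix_mean), 4 * sd(draws) / sqrt(nsim) + 1e-12)
    # and the model-averaged (unconditional) mean stored in the fit agrees
    expect_equal(unname(fit$uncond_mean[cv]), mix_mean, tolerance = 1e-10)
  }
  expect_error(coefficient_density(fit, "nope"), class = "npheight_domain_error")
})

test_that("results are invariant to row order and equivariant to group relabelling", {
  cfg <- panel_config(n_countries = 14, seed = 9)
  sim <- simulate_panel(cfg)
  comp <- average_food_group_concentration(sim$composition_tables, sim$group_map)
  ap <- assemble_analysis_panel(build_intake_panel(sim$intake, comp),
                                sim$heights, sim$covariates)
  covs <- c("N", "NP", "GDP", "Cal")
  fit <- bma_fit(build_levels_design(ap, covariates = covs))

  set.seed(2)
  fit_perm <- bma_fit(build_levels_design(ap[sample(nrow(ap)), ],
                                          covariates = covs))
  expect_equal(fit_perm$pip, fit$pip, tolerance = 1e-10)
  expect_equal(fit_perm$cond$cond_mean, fit$cond$cond_mean, tolerance = 1e-8)

  # swapping the group labels swaps the group-specific summaries exactly
  swapped <- ap
  swapped$diet_group <- ifelse(ap$diet_group == "animal-dominated",
                               "plant-dominated", "animal-dominated")
  fit_sw <- bma_fit(build_levels_design(swapped, covariates = covs))
  expect_equal(fit_sw$pip, fit$pip, tolerance = 1e-10)
  a <- fit$cond[fit$cond$group == "animal-dominated", ]
  b <- fit_sw$cond[fit_sw$cond$group == "plant-dominated", ]
  expect_equal(a$cond_mean, b$cond_mean, tolerance = 1e-8)
  expect_equal(a$cond_sd, b$cond_sd, tolerance = 1e-8)
})

test_that("bma fit methods expose coefficients, fitted values and residuals", {
  d <- random_design(n = 50, k = 3, seed = 71, beta = c(1, 0, 0), noise_sd = 0.5)
  fit <- bma_fit(d)
  expect_length(coef(fit), ncol(d$W) + ncol(d$Z))
  expect_equal(fitted(fit) + residuals(fit), d$y, tolerance = 1e-12)
  # fitted values track the strong signal
  expect_gt(cor(fitted(fit), d$y), 0.8)
  s <- summary(fit)
  expect_s3_class(s, "summary.bma")
  expect_true(all(c("lo2sd", "hi2sd") %in% names(s$cond)))
})
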