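make_small_inputs <- function(seed = 30, n_plots = 5, n_sub = 2) {
  set.seed(seed)
  cfg <- simulation_config(n_plots = n_plots, n_subplots_per_plot = n_sub,
                           seed = seed)
  land <- generate_landscape(cfg)
  pool <- generate_species_pool(cfg)
  cen <- generate_tree_censuses(land, pool, cfg)
  idx <- stats::setNames(pool$true_optimum, pool$species_id)
  trees <- filter_census_trees(cen$trees)
  cti <- cti_table(trees, idx)
  flags <- stats::setNames(pool$conifer, pool$species_id)
  key <- interaction(trees$plot_id, trees$subplot_id, drop = TRUE)
  cf <- do.call(rbind, lapply(split(trees, key), function(s) {
    data.frame(plot_id = s$plot_id[1], subplot_id = s$subplot_id[1],
               x11 = conifer_basal_fraction(s[s$size_class == "main", ], flags))
  }))
  cov <- build_covariates(land[order(land$plot_id, land$subplot_id), ], cf,
                          coding = "weighted_effect")
  list(cti = cti, cov = cov, land = land)
}

test_that("design rows pair timepoints and zero T1 interactions", {
  inp <- make_small_inputs()
  des <- build_design(inp$cti, inp$cov, "all")
  defined <- sum(!is.na(inp$cti$cti_degC[inp$cti$variant == "all"]))
  expect_equal(nrow(des), defined)
  icols <- paste0("i", 2:11)
  expect_true(all(as.matrix(des[des$k == 0, icols]) == 0))
  expect_equal(unname(as.matrix(des[des$k == 1, icols])),
               unname(as.matrix(des[des$k == 1, paste0("x", 2:11)])))
  # counterfactual variants share the baseline response
  dm <- build_design(inp$cti, inp$cov, "mortality")
  shared <- merge(des[des$k == 0, c("plot_id", "subplot_id", "Y")],
                  dm[dm$k == 0, c("plot_id", "subplot_id", "Y")],
                  by = c("plot_id", "subplot_id"))
  expect_equal(shared$Y.x, shared$Y.y)
  expect_error(build_design(inp$cti, inp$cov, "biomass"), "variant")
  unscaled <- inp$cov
  attr(unscaled, "standardized") <- FALSE
  expect_error(build_design(inp$cti, unscaled, "all"), "standardized")
})

test_that("Matern kernel hits its closed forms and stays PSD", {
  set.seed(31)
  xy <- matrix(runif(60), 30, 2) * 50
  dmat <- as.matrix(dist(xy))
  S <- matern_cov(dmat, sigma_u = 0.7, rho = 20, nu = 1)
  expect_equal(unname(diag(S)), rep(0.49, 30))
  expect_equal(S, t(S))
  # strictly decreasing in distance
  dd <- seq(0, 100, by = 1)
  vals <- matern_cov(matrix(dd, 1), 1, 15, 1)
  expect_true(all(diff(as.numeric(vals)) < 0))
  # nu = 0.5 is the exponential kernel
  e <- matern_cov(dmat, 0.7, 20, 0.5)
  expect_equal(e, 0.49 * exp(-dmat / 20), tolerance = 1e-10)
  # PSD after jitter
  S2 <- S + diag(1e-8 * 0.49, 30)
  expect_silent(chol(S2))
  expect_error(matern_cov(dmat - 1, 1, 1, 1), "nonnegative")
  expect_error(matern_cov(dmat, 1, -1, 1), "positive")
})

test_that("with variance components fixed at zero the fit collapses to OLS", {
  sim <- simulate_from_model(n_plots = 25, n_subplots = 4,
                             beta = c(8, 0.05, rep(0, 20)),
                             sigma_u = 0, d = 0, sigma = 0.3, seed = 32)
  fit <- fit_cti_model(sim$design, sim$coords,
                       model_spec(fixed = list(sigma_u = 0, d = 0)))
  X <- cbind(1, sim$design$k, as.matrix(sim$design[paste0("x", 2:11)]),
             as.matrix(sim$design[paste0("i", 2:11)]))
  ols <- qr.solve(X, sim$design$Y)
  expect_lt(max(abs(fit$beta - ols)), 1e-8)
})

test_that("fits are location-equivariant and permutation-invariant", {
  sim <- simulate_from_model(n_plots = 40, n_subplots = 2,
                             beta = c(8, 0.05, rep(0, 20)), seed = 33)
  spec <- model_spec()
  fit <- fit_cti_model(sim$design, sim$coords, spec)
  shifted <- sim$design
  shifted$Y <- shifted$Y + 2.5
  fit_s <- fit_cti_model(shifted, sim$coords, spec)
  expect_lt(abs(fit_s$beta[["beta0"]] - fit$beta[["beta0"]] - 2.5), 1e-8)
  expect_lt(max(abs(fit_s$beta[-1] - fit$beta[-1])), 1e-8)
  set.seed(33)
  perm <- sim$design[sample.int(nrow(sim$design)), ]
  fit_p <- fit_cti_model(perm, sim$coords, spec)
  expect_lt(max(abs(fit_p$summary$mean[1:22] - fit$summary$mean[1:22])), 1e-10)
})

test_that("a vanishing spatial range matches an iid-plot-effect mixed model", {
  # as rho -> 0 the Matern field degenerates to independent plot effects, so
  # the fit should agree with a conventional nested random-intercept model
  # (lme4 as the independent route)
  sim <- simulate_from_model(n_plots = 60, n_subplots = 3,
                             beta = c(8, 0.05, rep(0, 20)),
                             sigma_u = 0.3, rho = 0.01, d = 0.2, sigma = 0.3,
                             seed = 34)
  f_small <- fit_cti_model(sim$design, sim$coords,
                           model_spec(fixed = list(rho = 1e-6)))
  d <- sim$design
  d$sub <- paste(d$plot_id, d$subplot_id)
  form <- stats::as.formula(paste(
    "Y ~ k +", paste(c(paste0("x", 2:11), paste0("i", 2:11)), collapse = " + "),
    "+ (1 | plot_id) + (1 | sub)"))
  lmm <- lme4::lmer(form, data = d, REML = TRUE)
  expect_lt(max(abs(f_small$beta - lme4::fixef(lmm))), 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(f_small$hyper[["sigma_u"]],
               vc$sdcor[vc$grp == "plot_id"], tolerance = 0.05)
})

test_that("the fitted model recovers planted effects from its own draws", {
  sim <- simulate_from_model(n_plots = 150, n_subplots = 4,
                             beta = c(8, 0.05, rep(0, 10), 0.03, rep(0, 9)),
                             sigma_u = 0.3, rho = 30, d = 0.2, sigma = 0.3,
                             seed = 35)
  fit <- fit_cti_model(sim$design, sim$coords)
  s <- fit$summary
  b1 <- s[s$term == "beta1", ]
  b12 <- s[s$term == "beta12", ]
  expect_lt(abs(b1$mean - 0.05), 4 * b1$sd)
  expect_lt(abs(b12$mean - 0.03), 4 * b12$sd)
  expect_gt(fit$hyper[["sigma_u"]], 0.05)
})

test_that("mean thermophilization reads beta1 under weighted effect coding only", {
  sim <- simulate_from_model(n_plots = 30, n_subplots = 2,
                             beta = c(8, 0.08, rep(0, 20)), seed = 36)
  fit <- fit_cti_model(sim$design, sim$coords)
  th <- mean_thermophilization(fit)
  expect_equal(th$rate_per_year, th$estimate / 10)
  expect_equal(th$estimate, fit$summary$mean[fit$summary$term == "beta1"])
  dummy_fit <- fit
  dummy_fit$coding <- "dummy"
  expect_error(mean_thermophilization(dummy_fit), "weighted")
})

test_that("effect tables carry 22 coefficients plus hyperparameters per variant", {
  sim <- simulate_from_model(n_plots = 20, n_subplots = 2, seed = 37)
  fit <- fit_cti_model(sim$design, sim$coords)
  tab <- effect_table(list(all = fit))
  expect_equal(sum(grepl("^beta", tab$term)), 22L)
  expect_equal(nrow(tab), 26L)
  expect_identical(tab, effect_table(list(all = fit)))
  expect_error(effect_table(list()), "at least one")
})

test_that("mcmc inference broadly agrees with empirical Bayes", {
  sim <- simulate_from_model(n_plots = 40, n_subplots = 2,
                             beta = c(8, 0.1, rep(0, 20)),
                             sigma_u = 0.2, rho = 25, d = 0.15, sigma = 0.25,
                             seed = 38)
  eb <- fit_cti_model(sim$design, sim$coords)
  mc <- fit_cti_model(sim$design, sim$coords,
                      model_spec(inference_method = "mcmc", mcmc_iter = 600,
                                 mcmc_burnin = 200, seed = 39))
  b_eb <- eb$summary[eb$summary$term == "beta1", ]
  b_mc <- mc$summary[mc$summary$term == "beta1", ]
  expect_lt(abs(b_eb$mean - b_mc$mean), 3 * b_eb$sd)
  expect_gt(mc$acceptance_rate, 0.05)
})
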