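test_that("design construction codes the fixed and random structures", {
  g <- generate_experiment(tiny_config(n_studies = 3, seed = 13))
  tb <- total_biomass_view(g$table)
  d <- build_design(tb, model_spec())
  expect_equal(length(d$blocks), 3L)        # one block per study
  expect_equal(d$n, nrow(tb))
  lnN <- d$X[, "ln_richness"]
  expect_true(all(lnN[d$index$sown_richness == 1] == 0))
  expect_equal(lnN, log(d$index$sown_richness), ignore_attr = TRUE)

  # three-level coding: two indicator columns, control as reference
  tb3 <- tb
  treated <- tb3$treatment != "control"
  tb3$treatment[treated] <- rep_len(c("NPK", "NH4NO3"), sum(treated))
  d3 <- build_design(tb3, model_spec(treatment_coding = "three_level"))
  expect_true(all(c("treatmentNPK", "treatmentNH4NO3") %in% colnames(d3$X)))
  expect_equal(sum(d3$term_of_col == "treatment"), 2L)
  tb3$treatment[treated][1] <- "urea"
  expect_error(build_design(tb3, model_spec(treatment_coding = "three_level")),
               "unknown treatment label")

  tbneg <- tb
  tbneg$total_biomass[1] <- -5
  expect_error(build_design(tbneg, model_spec()), "negative total biomass")
  tb1 <- tb[tb$study_id == tb$study_id[1], ]
  expect_error(build_design(tb1, model_spec()), "two studies")
  expect_error(model_spec(random_terms = c("study", "study_time"),
                          residual_correlation = "ar1"), "plot random term")
})

test_that("fixed effects reduce to ordinary least squares when variances
           vanish", {
  cfg <- calib_config(seed = 17, dry = zero_dry())
  cfg$vc[] <- 0
  cfg$rho <- 0
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  ols <- stats::lm(sqrt(total_biomass) ~ log(sown_richness) *
                     I(treatment != "control"), data = tb)
  # forced sigma^2 I covariance: exact agreement
  fit0 <- reml_fit(build_design(tb, model_spec(
    random_terms = character(0), residual_correlation = "independent")))
  expect_equal(unname(fit0$beta_hat), unname(stats::coef(ols)),
               tolerance = 1e-8)
  # estimated covariance on null data: agreement to sampling noise
  fit <- reml_fit(build_design(tb, model_spec()))
  expect_equal(unname(fit$beta_hat), unname(stats::coef(ols)),
               tolerance = 0.01)
})

test_that("a balanced one-way layout matches the closed-form REML
           estimators", {
  set.seed(5)
  g <- 8L
  m <- 4L
  group <- rep(sprintf("g%d", 1:g), each = m)
  y <- 10 + rep(rnorm(g, 0, 2), each = m) + rnorm(g * m, 0, 1.5)
  df <- data.frame(study_id = group,
                   plot_id = sprintf("p%d", seq_len(g * m)), year = 1L,
                   sown_richness = 1L, treatment = "control", value = y,
                   stringsAsFactors = FALSE)
  spec <- model_spec("value", fixed_terms = character(0),
                     random_terms = "study",
                     residual_correlation = "independent")
  fit <- reml_fit(build_design(df, spec))
  cf <- oneway_reml(y, group, m)
  expect_equal(unname(fit$vc_hat["study"]), cf$vc_group, tolerance = 1e-6)
  expect_equal(fit$sigma2, cf$sigma2, tolerance = 1e-6)
  expect_equal(unname(fit$beta_hat[1]), mean(tapply(y, group, mean)),
               tolerance = 1e-6)
})

test_that("the restricted log-likelihood matches a dense-matrix evaluation", {
  cfg <- sim_config(n_studies = 2, richness_levels = c(1, 2, 4),
                    plots_per_richness = 2, mono_plots_per_species = 1,
                    n_years = 3, pool_size = 4, seed = 23)
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  expect_lte(nrow(tb), 200)
  vc_names <- c("study", "study_ln_richness", "study_treatment",
                "study_ln_richness_treatment", "study_time", "plot")
  pts <- list(
    list(vc = stats::setNames(c(2, 0.5, 0.8, 0.1, 1.2, 4), vc_names),
         s2 = 3, rho = 0.25),
    list(vc = stats::setNames(c(10, 2, 2, 0.01, 4, 14), vc_names),
         s2 = 9, rho = -0.3),
    list(vc = stats::setNames(rep(1, 6), vc_names), s2 = 1, rho = 0))
  for (corr in c("ar1", "compound_symmetry", "independent")) {
    d <- build_design(tb, model_spec(residual_correlation = corr))
    for (pt in pts) {
      mine <- reml_loglik(d, pt$vc, pt$s2, pt$rho)
      dense <- dense_reml_loglik(tb, as.list(pt$vc), pt$s2, pt$rho, corr)
      expect_equal(mine, dense, tolerance = 1e-8)
    }
  }
})

test_that("the fit agrees with nlme on a jointly expressible sub-model", {
  skip_if_not_installed("nlme")
  cfg <- sim_config(n_studies = 6, richness_levels = c(1, 2, 4, 8),
                    plots_per_richness = 2, mono_plots_per_species = 1,
                    n_years = 4, pool_size = 8, seed = 3)
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  spec <- model_spec(random_terms = c("study", "plot"),
                     residual_correlation = "ar1")
  fit <- reml_fit(build_design(tb, spec))
  tb$y <- sqrt(tb$total_biomass)
  tb$lnN <- log(tb$sown_richness)
  tb$tr <- as.numeric(tb$treatment != "control")
  lf <- nlme::lme(y ~ lnN * tr, random = ~ 1 | study_id / plot_id,
                  correlation = nlme::corAR1(form = ~ year |
                                               study_id / plot_id),
                  data = tb, method = "REML")
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
  expect_equal(unname(fit$beta_hat), unname(nlme::fixef(lf)),
               tolerance = 1e-5)
  expect_equal(unname(fit$rho_hat),
               unname(stats::coef(lf$modelStruct$corStruct,
                                  unconstrained = FALSE)),
               tolerance = 1e-4)
  vc_nlme <- as.numeric(nlme::VarCorr(lf)[c(2, 4), 1])
  expect_equal(unname(fit$vc_hat), vc_nlme, tolerance = 1e-3)
  expect_equal(fit$sigma2, lf$sigma^2, tolerance = 1e-3)
})

test_that("the returned optimum is a local maximum of the restricted
           likelihood", {
  cfg <- calib_config(seed = 29)
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  d <- build_design(tb, model_spec())
  fit <- reml_fit(d)
  set.seed(1)
  ll0 <- reml_loglik(d, fit$vc_hat, fit$sigma2, fit$rho_hat)
  expect_equal(ll0, fit$reml_loglik, tolerance = 1e-6)
  for (i in 1:100) {
    vc <- pmax(fit$vc_hat, 1e-4) * exp(stats::runif(d$K, -0.4, 0.4))
    s2 <- fit$sigma2 * exp(stats::runif(1, -0.4, 0.4))
    rho <- max(min(fit$rho_hat + stats::runif(1, -0.1, 0.1), 0.95), -0.95)
    ll <- reml_loglik(d, vc, s2, rho)
    if (is.finite(ll)) expect_lte(ll, ll0 + 1e-6)
  }
})

test_that("sequential Wald tests detect overwhelming signal and refuse
           unconverged fits", {
  cfg <- calib_config(seed = 37, dry = zero_dry())
  cfg$beta[["treatment"]] <- 30
  cfg$vc[] <- 0
  cfg$noise_sd <- 1
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  fit <- reml_fit(build_design(tb, model_spec()))
  w <- wald_sequential(fit)
  expect_lt(w$p_value[w$term == "treatment"], 1e-6)
  expect_equal(w$term[1], "(Intercept)")
  expect_equal(attr(w, "order"), w$term)

  fit$converged <- FALSE
  expect_error(wald_sequential(fit), "converge")
})

test_that("AIC comparison selects structures and reports exact ties", {
  cfg <- calib_config(seed = 41)
  cfg$rho <- 0.6
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  fa <- reml_fit(build_design(tb, model_spec()),
                 control = list(hessian = FALSE))
  cmp_self <- compare_covariance(fa, fa)
  expect_equal(cmp_self$delta_aic, 0)
  expect_true(cmp_self$tie)
  expect_equal(cmp_self$selected, "ar1")
  fc <- reml_fit(build_design(tb, model_spec(
    residual_correlation = "compound_symmetry")),
    control = list(hessian = FALSE))
  cmp <- compare_covariance(fa, fc)
  expect_equal(unname(cmp$aic), c(fa$aic, fc$aic))
  tb2 <- tb[tb$year == 1, ]
  fo <- reml_fit(build_design(tb2, model_spec(
    residual_correlation = "independent")), control = list(hessian = FALSE))
  expect_error(compare_covariance(fa, fo), "share")
})

test_that("fitted lines back-transform by squaring and per-study lines
           average to the pooled line", {
  cfg <- calib_config(seed = 43)
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  fit <- reml_fit(build_design(tb, model_spec()))
  pooled <- fitted_lines(fit, level = "pooled")
  at1 <- pooled[pooled$sown_richness == 1 & pooled$treatment == "control", ]
  expect_equal(at1$fit_sqrt, unname(fit$beta_hat["(Intercept)"]))
  expect_equal(pooled$fit_response, pooled$fit_sqrt^2)
  per <- fitted_lines(fit, level = "per_study")
  avg <- stats::aggregate(fit_sqrt ~ sown_richness + treatment, per, mean)
  key <- paste(avg$sown_richness, avg$treatment)
  pkey <- paste(pooled$sown_richness, pooled$treatment)
  expect_equal(avg$fit_sqrt, pooled$fit_sqrt[match(key, pkey)],
               tolerance = 1e-6)
  expect_error(fitted_lines(fit, richness = c(0.5, 2)), "richness")
})

test_that("the AR(1) coefficient is recovered from repeated measures", {
  cfg <- calib_config(seed = 47, n_years = 6)
  cfg$rho <- 0.5
  ests <- sapply(befpart:::.study_seeds(47, 10), function(s) {
    cfg$seed <- s
    tb <- total_biomass_view(generate_experiment(cfg)$table)
    reml_fit(build_design(tb, model_spec()),
             control = list(n_starts = 1L, hessian = FALSE))$rho_hat
  })
  expect_lt(abs(mean(ests) - 0.5), 0.1)
})
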