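test_that("species pool monoculture means have log-normal scatter and the
           configured treatment response", {
  # CV of a log-normal with sdlog 0.5 is sqrt(exp(0.25) - 1)
  cfg <- sim_config(n_studies = 1, richness_levels = c(1, 2),
                    plots_per_richness = 1, mono_plots_per_species = 1,
                    n_years = 1, pool_size = 10000, mono_sdlog = 0.5,
                    vc = stats::setNames(rep(0, 6), names(sim_config()$vc)),
                    rho = 0, noise_sd = 0, seed = 11)
  pool <- generate_species_pool(cfg)
  ctrl <- pool[pool$treatment == "control" & pool$year == 1, ]
  cv <- stats::sd(ctrl$mean_mono_biomass) / mean(ctrl$mean_mono_biomass)
  expect_lt(abs(cv / sqrt(exp(0.25) - 1) - 1), 0.05)

  # explicit multiplier 1: treated and control monoculture means identical
  cfg1 <- do.call(sim_config, c(list(
    n_studies = 2, richness_levels = c(1, 2), plots_per_richness = 1,
    mono_plots_per_species = 1, n_years = 1, pool_size = 4,
    mono_treatment_mult = 1, seed = 4), noisefree_args()))
  p1 <- generate_species_pool(cfg1)
  wide <- merge(p1[p1$treatment == "control", ],
                p1[p1$treatment == "treated", ],
                by = c("study_id", "species_id", "year"))
  expect_equal(wide$mean_mono_biomass.x, wide$mean_mono_biomass.y)

  # default: nutrient addition raises, drought lowers, monoculture biomass
  pn <- generate_species_pool(do.call(sim_config, c(list(
    alteration = "nutrient", n_studies = 2, pool_size = 16, seed = 4),
    noisefree_args())))
  ratio_n <- mean(pn$mean_mono_biomass[pn$treatment == "treated"]) /
    mean(pn$mean_mono_biomass[pn$treatment == "control"])
  expect_gt(ratio_n, 1)
  pd <- generate_species_pool(do.call(sim_config, c(list(
    alteration = "drought", n_studies = 2, pool_size = 16, seed = 4),
    noisefree_args())))
  ratio_d <- mean(pd$mean_mono_biomass[pd$treatment == "treated"]) /
    mean(pd$mean_mono_biomass[pd$treatment == "control"])
  expect_lt(ratio_d, 1)

  expect_error(sim_config(pool_size = 4, richness_levels = c(1, 2, 8)),
               "pool_size")
})

test_that("mixture biomass composition follows the relative-yield inversion", {
  expect_equal(compose_mixture_biomass(c(100, 200), c(0.5, 0.5), c(0.1, 0.1)),
               c(60, 120))
  # a species whose deviation cancels its expected yield is lost
  expect_equal(compose_mixture_biomass(c(100, 200), c(0.5, 0.5),
                                       c(-0.5, 0.1)), c(0, 120))
  # zero deviations: total equals the expected yield
  m <- c(80, 150, 240)
  expect_equal(sum(compose_mixture_biomass(m, rep(1 / 3, 3), rep(0, 3))),
               sum(m / 3))
  expect_error(compose_mixture_biomass(c(1, 2), c(0.7, 0.7), c(0, 0)),
               "sum to 1")
})

test_that("true_partition evaluates the closed-form effects", {
  tp <- true_partition(m = c(100, 200), dry = c(0.1, 0.1), denominator = 150)
  expect_equal(tp$net_std, 0.2)
  expect_equal(tp$ce_std, 0.2)
  expect_equal(tp$se_std, 0)
  tp0 <- true_partition(m = c(100, 200), dry = c(0, 0), denominator = 150)
  expect_equal(c(tp0$net_raw, tp0$ce_raw, tp0$se_raw), c(0, 0, 0))
  # positive coupling between monoculture mass and deviation: selection > 0
  tps <- true_partition(m = c(50, 100, 400), dry = c(-0.1, 0, 0.1))
  expect_gt(tps$se_raw, 0)
  tpn <- true_partition(m = c(50, 100, 400), dry = c(0.1, 0, -0.1))
  expect_lt(tpn$se_raw, 0)
})

test_that("the noise-free limit reproduces the squared fixed-effect surface", {
  cfg <- do.call(sim_config, c(list(
    n_studies = 2, richness_levels = c(1, 2, 4), plots_per_richness = 2,
    mono_plots_per_species = 1, n_years = 2, pool_size = 4, mono_sdlog = 0,
    dry = zero_dry(), beta = c(intercept = 14, ln_richness = 3,
                               treatment = 3.4, interaction = 0),
    seed = 9), noisefree_args()))
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  lnN <- log(tb$sown_richness)
  tr <- as.numeric(tb$treatment != "control")
  expect_equal(tb$total_biomass, (14 + 3 * lnN + 3.4 * tr)^2,
               tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed and stable under
           added studies", {
  g1 <- generate_experiment(tiny_config(seed = 21))
  g2 <- generate_experiment(tiny_config(seed = 21))
  expect_identical(g1$table$records, g2$table$records)
  expect_identical(g1$truth$plot_truth, g2$truth$plot_truth)
  # per-study sub-streams: studies 1..3 unchanged when a fourth is added
  g4 <- generate_experiment(tiny_config(n_studies = 4, seed = 21))
  r4 <- g4$table$records[g4$table$records$study_id %in%
                           unique(g1$table$records$study_id), ]
  rownames(r4) <- NULL
  expect_identical(r4, g1$table$records)
})

test_that("residuals carry the configured AR(1) correlation across years", {
  cfg <- do.call(sim_config, c(list(
    n_studies = 2, richness_levels = c(1, 2), plots_per_richness = 150,
    mono_plots_per_species = 1, n_years = 8, pool_size = 2, mono_sdlog = 0,
    dry = zero_dry(), seed = 31), noisefree_args()))
  cfg$rho <- 0.6
  cfg$noise_sd <- 3
  tb <- total_biomass_view(generate_experiment(cfg)$table)
  lnN <- log(tb$sown_richness)
  tr <- as.numeric(tb$treatment != "control")
  beta <- cfg$beta
  e <- sqrt(tb$total_biomass) -
    (beta[["intercept"]] + beta[["ln_richness"]] * lnN +
       beta[["treatment"]] * tr)
  tb$e <- e
  wide <- stats::reshape(tb[c("study_id", "plot_id", "year", "e")],
                         idvar = c("study_id", "plot_id"),
                         timevar = "year", direction = "wide")
  em <- as.matrix(wide[, -(1:2)])
  lag1 <- stats::cor(as.vector(em[, -ncol(em)]), as.vector(em[, -1]))
  expect_lt(abs(lag1 - 0.6), 0.05)
})

test_that("relative-yield truncation is reported and bounded", {
  cfg <- tiny_config(seed = 2,
                     dry = list(mean_slope = -1.5, treatment_shift = 0,
                                selection = 0, species_sd = 0.5))
  g <- generate_experiment(cfg)
  expect_gt(g$truth$truncation_rate, 0)
  expect_lte(g$truth$truncation_rate, 1)
  # default conditions keep truncation rare
  gd <- generate_experiment(sim_config(alteration = "nutrient", seed = 2))
  expect_lt(gd$truth$truncation_rate, 0.01)
})
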