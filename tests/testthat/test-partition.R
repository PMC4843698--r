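test_that("monoculture means are averaged per stratum and threshold-flagged", {
  records <- data.frame(
    study_id = "s", plot_id = c("p1", "p2", "p3", "p4"), year = 1L,
    sown_richness = 1L, treatment = "control",
    species_id = c("A", "A", "B", "C"), sown_proportion = 1,
    biomass = c(90, 110, 2.0, 3.0), stringsAsFactors = FALSE)
  cov <- data.frame(study_id = "s", plot_id = c("p1", "p2", "p3", "p4"),
                    alteration_type = "nutrient", stringsAsFactors = FALSE)
  monos <- mean_monoculture_biomass(experiment_table(records, cov))
  a <- monos[monos$species_id == "A", ]
  expect_equal(a$mean_mono_biomass, 100)
  expect_equal(a$n_mono_plots, 2L)
  expect_true(monos$excluded[monos$species_id == "B"])   # 2.0 < 2.5
  expect_false(monos$excluded[monos$species_id == "C"])  # 3.0 >= 2.5
})

test_that("partition_plot reproduces the worked arithmetic examples", {
  monos <- data.frame(study_id = "s", treatment = "control", year = 1L,
                      species_id = c("A", "B"),
                      mean_mono_biomass = c(100, 200), n_mono_plots = 1L,
                      excluded = FALSE, stringsAsFactors = FALSE)
  pr <- data.frame(study_id = "s", plot_id = "p", year = 1L,
                   sown_richness = 2L, treatment = "control",
                   species_id = c("A", "B"), sown_proportion = 0.5,
                   biomass = c(60, 120), stringsAsFactors = FALSE)
  r1 <- partition_plot(pr, monos)
  expect_equal(c(r1$net_raw, r1$ce_raw, r1$se_raw), c(30, 30, 0))

  pr$biomass <- c(70, 100)
  r2 <- partition_plot(pr, monos)
  expect_equal(c(r2$net_raw, r2$ce_raw, r2$se_raw), c(20, 30, -10))
  expect_equal(r2$net_raw, r2$ce_raw + r2$se_raw)

  pr$biomass <- c(50, 100)  # each species exactly at its expected yield
  r3 <- partition_plot(pr, monos)
  expect_equal(c(r3$net_raw, r3$ce_raw, r3$se_raw), c(0, 0, 0))
})

test_that("species below the monoculture threshold are dropped and the
           partition recomputed over the survivors", {
  monos <- data.frame(study_id = "s", treatment = "control", year = 1L,
                      species_id = c("A", "B", "C"),
                      mean_mono_biomass = c(100, 200, 2.0),
                      n_mono_plots = 1L,
                      excluded = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  pr <- data.frame(study_id = "s", plot_id = "p", year = 1L,
                   sown_richness = 3L, treatment = "control",
                   species_id = c("A", "B", "C"),
                   sown_proportion = 1 / 3, biomass = c(40, 80, 5),
                   stringsAsFactors = FALSE)
  r <- partition_plot(pr, monos)
  expect_equal(r$n_used, 2L)
  expect_match(r$excluded_species, "C\\(below_threshold\\)")
  # equal to a two-species partition with renormalized proportions
  direct <- oracle_partition(c(40, 80), c(100, 200), c(0.5, 0.5))
  expect_equal(r$net_raw, direct$net)
  expect_equal(r$ce_raw, direct$ce)
  expect_equal(r$se_raw, direct$se)
})

test_that("species without monoculture data are dropped; plots with fewer
           than two usable species are degenerate", {
  monos <- data.frame(study_id = "s", treatment = "control", year = 1L,
                      species_id = "A", mean_mono_biomass = 100,
                      n_mono_plots = 1L, excluded = FALSE,
                      stringsAsFactors = FALSE)
  pr <- data.frame(study_id = "s", plot_id = "p", year = 1L,
                   sown_richness = 2L, treatment = "control",
                   species_id = c("A", "B"), sown_proportion = 0.5,
                   biomass = c(60, 120), stringsAsFactors = FALSE)
  r <- partition_plot(pr, monos)
  expect_equal(r$status, "no_monoculture_data")
  expect_true(is.na(r$net_raw))
})

test_that("standardization divides by the treatment mean monoculture biomass
           and is scale invariant", {
  tab <- toy_table()
  p <- partition_table(tab)
  expect_equal(p$denominator, 150)
  expect_equal(p$net_std, 0.2)
  # global rescaling: raw effects scale, standardized effects unchanged
  for (c0 in c(0.1, 10)) {
    tab2 <- toy_table()
    tab2$records$biomass <- tab2$records$biomass * c0
    p2 <- partition_table(tab2)
    expect_equal(p2$net_raw, p$net_raw * c0, tolerance = 1e-12)
    expect_equal(p2$net_std, p$net_std, tolerance = 1e-12)
    expect_equal(p2$ce_std, p$ce_std, tolerance = 1e-12)
    expect_equal(p2$se_std, p$se_std, tolerance = 1e-12)
  }
  # a denominator group whose species are all excluded goes degenerate
  monos <- mean_monoculture_biomass(tab)
  monos$excluded <- TRUE
  r <- partition_plot(tab$records[tab$records$plot_id == "mix", ], monos)
  expect_equal(r$status, "degenerate")
})

test_that("species order never changes the partition", {
  set.seed(42)
  for (i in 1:20) {
    rp <- random_plot(sample(2:6, 1))
    r <- partition_plot(rp$pr, rp$monos)
    perm <- sample(nrow(rp$pr))
    r2 <- partition_plot(rp$pr[perm, ], rp$monos)
    expect_equal(r2[c("net_raw", "ce_raw", "se_raw")],
                 r[c("net_raw", "ce_raw", "se_raw")], tolerance = 1e-12)
  }
})

test_that("partition identity and oracle equivalence hold on random plots", {
  set.seed(7)
  for (i in 1:300) {
    rp <- random_plot(sample(2:5, 1))
    r <- partition_plot(rp$pr, rp$monos)
    expect_equal(r$net_raw, r$ce_raw + r$se_raw,
                 tolerance = 1e-9 * max(1, abs(r$net_raw)))
    keep <- !rp$monos$excluded
    o <- oracle_partition(rp$y[keep], rp$m[keep], rp$props[keep])
    expect_equal(r$net_raw, o$net, tolerance = 1e-9)
    expect_equal(r$ce_raw, o$ce, tolerance = 1e-9)
    expect_equal(r$se_raw, o$se, tolerance = 1e-9)
  }
  # structural zeros: constant deviations kill selection, equal monocultures
  # kill selection, zero mean deviation kills complementarity
  tp1 <- true_partition(m = c(100, 250, 400), dry = rep(0.07, 3))
  expect_equal(tp1$se_raw, 0, tolerance = 1e-12)
  tp2 <- true_partition(m = rep(150, 3), dry = c(-0.2, 0.05, 0.4))
  expect_equal(tp2$se_raw, 0, tolerance = 1e-12)
  tp3 <- true_partition(m = c(100, 250, 400), dry = c(-0.1, 0.02, 0.08))
  expect_equal(tp3$ce_raw, 0, tolerance = 1e-12)
})

test_that("partition_table skips monocultures and matches the generator's
           truth on noise-free data", {
  cfg <- do.call(sim_config, c(list(
    n_studies = 3, richness_levels = c(1, 2, 4, 8), plots_per_richness = 2,
    mono_plots_per_species = 1, n_years = 2, pool_size = 8, seed = 5),
    noisefree_args()))
  g <- generate_experiment(cfg)
  p <- partition_table(g$table)
  expect_true(all(p$sown_richness >= 2))
  m <- merge(p, g$truth$plot_truth, by = c("study_id", "plot_id"),
             suffixes = c("", ".true"))
  expect_equal(nrow(m), nrow(p))
  expect_equal(m$net_std, m$net_std.true, tolerance = 1e-12)
  expect_equal(m$ce_std, m$ce_std.true, tolerance = 1e-12)
  expect_equal(m$se_std, m$se_std.true, tolerance = 1e-12)

  # monocultures only: empty result
  mono_only <- g$table
  keep <- mono_only$records$sown_richness == 1L
  mono_only$records <- mono_only$records[keep, ]
  expect_equal(nrow(partition_table(mono_only)), 0L)
})
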