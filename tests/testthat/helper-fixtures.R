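# Shared fixtures and independent oracles used across the test files.

# hand-built table: one 2-species mixture plot plus two monocultures, one year
toy_table <- function() {
  records <- data.frame(
    study_id = "s1",
    plot_id = c("mix", "mix", "monoA", "monoB"),
    year = 1L,
    sown_richness = c(2L, 2L, 1L, 1L),
    treatment = "control",
    species_id = c("A", "B", "A", "B"),
    sown_proportion = c(0.5, 0.5, 1, 1),
    biomass = c(60, 120, 100, 200),
    stringsAsFactors = FALSE)
  covariates <- data.frame(
    study_id = "s1", plot_id = c("mix", "monoA", "monoB"),
    alteration_type = "nutrient", n_added = 10,
    drought_duration_days = NA_integer_, fertilizer = "NPK",
    stringsAsFactors = FALSE)
  experiment_table(records, covariates, provenance = "toy")
}

# small, fast generator settings for property tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_studies = 3, richness_levels = c(1, 2, 4),
         plots_per_richness = 1, mono_plots_per_species = 1,
         n_years = 2, pool_size = 4), list(...))
  do.call(sim_config, args)
}

# the reduced, correctly specified design used for estimator calibration
calib_config <- function(...) {
  args <- utils::modifyList(
    list(n_studies = 6, richness_levels = c(1, 2, 4, 8),
         plots_per_richness = 1, mono_plots_per_species = 1,
         n_years = 3, pool_size = 8, rho = 0.1, mono_sdlog = 0), list(...))
  do.call(sim_config, args)
}

# a config with every stochastic layer switched off: totals equal the squared
# fixed-effect surface exactly
noisefree_args <- function() {
  list(vc = stats::setNames(rep(0, 6),
                            c("study", "study_ln_richness", "study_treatment",
                              "study_ln_richness_treatment", "study_time",
                              "plot")),
       rho = 0, noise_sd = 0)
}

zero_dry <- function() {
  list(mean_slope = 0, treatment_shift = 0, selection = 0, species_sd = 0)
}

# independent partition oracle: net from raw sums, ce from the definition,
# se as the remainder
oracle_partition <- function(y, m, ry_e) {
  ry_e <- ry_e / sum(ry_e)
  net <- sum(y) - sum(ry_e * m)
  dry <- y / m - ry_e
  ce <- length(y) * mean(dry) * mean(m)
  list(net = net, ce = ce, se = net - ce)
}

# dense-matrix evaluation of the Gaussian restricted log-likelihood, built
# directly from the long data frame with explicit Z matrices and a full n x n
# covariance; independent of the package's block/Woodbury code path
dense_reml_loglik <- function(df, vc, sigma2, rho,
                              corr = c("ar1", "compound_symmetry",
                                       "independent")) {
  corr <- match.arg(corr)
  df <- df[order(df$study_id, df$plot_id, df$year), ]
  n <- nrow(df)
  lnN <- log(df$sown_richness)
  tr <- as.numeric(df$treatment != "control")
  X <- cbind(1, lnN, tr, lnN * tr)
  y <- sqrt(df$total_biomass)
  study <- factor(df$study_id)
  plotf <- factor(paste(df$study_id, df$plot_id))
  styear <- factor(paste(df$study_id, df$year))
  Zs <- stats::model.matrix(~ 0 + study)
  Zlist <- list(
    study = Zs,
    study_ln_richness = Zs * lnN,
    study_treatment = Zs * tr,
    study_ln_richness_treatment = Zs * lnN * tr,
    study_time = stats::model.matrix(~ 0 + styear),
    plot = stats::model.matrix(~ 0 + plotf))
  V <- matrix(0, n, n)
  for (k in seq_along(Zlist)) {
    V <- V + vc[[names(Zlist)[k]]] * tcrossprod(Zlist[[k]])
  }
  same_plot <- outer(as.character(plotf), as.character(plotf), "==")
  lag <- abs(outer(df$year, df$year, "-"))
  R <- switch(corr,
    ar1 = rho^lag,
    compound_symmetry = ifelse(lag == 0, 1, rho),
    independent = ifelse(lag == 0, 1, 0))
  R[!same_plot] <- 0
  diag(R) <- 1
  V <- V + sigma2 * R
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  p <- ncol(X)
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) + q)
}

# closed-form REML for the balanced one-way random-effects layout
oneway_reml <- function(y, g, m) {
  ybar_g <- tapply(y, g, mean)
  msw <- sum((y - ybar_g[g])^2) / (length(y) - length(ybar_g))
  msb <- m * stats::var(ybar_g)
  list(sigma2 = msw, vc_group = (msb - msw) / m)
}

# random mixture plot + matching monoculture table for partition properties
random_plot <- function(n_sp, seed_offset = 0) {
  m <- stats::runif(n_sp, 3, 300)
  props <- stats::runif(n_sp, 0.2, 1)
  props <- props / sum(props)
  y <- stats::runif(n_sp, 0, 2 * m)
  monos <- data.frame(study_id = "s", treatment = "control", year = 1L,
                      species_id = sprintf("sp%d", seq_len(n_sp)),
                      mean_mono_biomass = m, n_mono_plots = 1L,
                      excluded = m < 2.5, stringsAsFactors = FALSE)
  pr <- data.frame(study_id = "s", plot_id = "p", year = 1L,
                   sown_richness = n_sp, treatment = "control",
                   species_id = sprintf("sp%d", seq_len(n_sp)),
                   sown_proportion = props, biomass = y,
                   stringsAsFactors = FALSE)
  list(pr = pr, monos = monos, y = y, m = m, props = props)
}
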