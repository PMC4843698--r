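#' Configuration for the synthetic multi-site experiment generator
#'
#' Defines a simulated set of grassland diversity experiments in which a sown
#' species-richness gradient is crossed with a resource-alteration treatment
#' (nutrient addition or drought). The generator's ground truth has two
#' layers: a square-root-scale linear mixed model that drives total plot
#' biomass (fixed effects for ln richness, treatment and their interaction;
#' study-level random effects; a plot effect; AR(1) residuals across years),
#' and a relative-yield layer that distributes each mixture's total biomass
#' over its member species so that true complementarity and selection
#' effects are known by construction.
#'
#' Default magnitudes are chosen to resemble published multi-site grassland
#' syntheses on the square-root biomass scale: for nutrient studies an
#' intercept of 14 (monoculture control biomass near 196 g m^-2), a richness
#' slope of 3, a treatment effect of +3.4 and zero interaction, with variance
#' components (study 14.7, study x richness 2.1, study x treatment 2.0,
#' study x richness x treatment 0, study x time 4.2, plot 13.9) and AR(1)
#' correlation 0.10; drought defaults are (9.5, 2.0, -1.2, 0) with variance
#' components (9.7, 0.9, 0.1, 0, 2.9, 11.5) and correlation 0.05.
#'
#' @param n_studies number of independent studies (sites); defaults to 10 for
#'   nutrient runs and 6 for drought runs, the typical counts of multi-site
#'   grassland syntheses of these alterations.
#' @param richness_levels sown richness gradient, ascending, must contain 1.
#' @param plots_per_richness mixture plots per richness level per treatment.
#' @param mono_plots_per_species monoculture plots per species per treatment.
#' @param n_years repeated annual harvests per plot.
#' @param pool_size species pool per study; must cover the largest richness.
#' @param alteration `"nutrient"` or `"drought"`.
#' @param beta named numeric: fixed effects `intercept`, `ln_richness`,
#'   `treatment`, `interaction` on the square-root-biomass scale.
#' @param vc named numeric: variances of the random terms `study`,
#'   `study_ln_richness`, `study_treatment`, `study_ln_richness_treatment`,
#'   `study_time`, `plot` (square-root scale).
#' @param rho AR(1) correlation of within-plot residuals across years.
#' @param noise_sd marginal standard deviation of the AR(1) residual on the
#'   square-root scale.
#' @param nugget_sd optional extra iid observation noise on the square-root
#'   scale (default 0; a nonzero value makes the default AR(1) residual model
#'   deliberately misspecified).
#' @param lognormal_noise misspecification toggle: replace the additive
#'   square-root-scale residual by multiplicative log-normal noise on the
#'   biomass scale (AR(1)-correlated on the log scale, marginal sd
#'   `lognormal_sd`).
#' @param lognormal_sd log-scale sd used when `lognormal_noise = TRUE`.
#' @param dry list of relative-yield truth knobs: `mean_slope` (mean
#'   relative-yield deviation per unit ln richness, scaled by `ln(N)/N` per
#'   species), `treatment_shift` (additive change of that slope under
#'   treatment), `selection` (coupling between a species' log monoculture
#'   mass and its deviation), `species_sd` (iid per-species scatter of the
#'   deviations).
#' @param mono_sdlog log-normal sd of species monoculture means around the
#'   study baseline.
#' @param mono_treatment_mult optional explicit multiplicative treatment
#'   effect on monoculture biomass; by default it is implied by the fixed
#'   effects, `((intercept + treatment)/intercept)^2`.
#' @param seed master seed; each study uses an independent sub-stream derived
#'   from it, so adding studies does not perturb existing ones.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_experiment()], [generate_species_pool()]
#' @export
sim_config <- function(n_studies = NULL,
                       richness_levels = c(1, 2, 4, 8, 16),
                       plots_per_richness = 8,
                       mono_plots_per_species = 4,
                       n_years = 4,
                       pool_size = 16,
                       alteration = c("nutrient", "drought"),
                       beta = NULL,
                       vc = NULL,
                       rho = NULL,
                       noise_sd = 3,
                       nugget_sd = 0,
                       lognormal_noise = FALSE,
                       lognormal_sd = 0.2,
                       dry = list(),
                       mono_sdlog = 0.5,
                       mono_treatment_mult = NULL,
                       seed = 1) {
  alteration <- match.arg(alteration)
  if (is.null(n_studies)) {
    n_studies <- if (alteration == "nutrient") 10 else 6
  }
  if (is.null(beta)) {
    beta <- if (alteration == "nutrient") {
      c(intercept = 14, ln_richness = 3, treatment = 3.4, interaction = 0)
    } else {
      c(intercept = 9.5, ln_richness = 2, treatment = -1.2, interaction = 0)
    }
  }
  beta <- beta[c("intercept", "ln_richness", "treatment", "interaction")]
  if (anyNA(beta)) stop("beta must name intercept, ln_richness, treatment, ",
                        "interaction", call. = FALSE)
  if (beta[["intercept"]] <= 0) stop("intercept must be positive",
                                     call. = FALSE)
  vc_names <- c("study", "study_ln_richness", "study_treatment",
                "study_ln_richness_treatment", "study_time", "plot")
  if (is.null(vc)) {
    vc <- if (alteration == "nutrient") {
      c(14.7, 2.1, 2.0, 0, 4.2, 13.9)
    } else {
      c(9.7, 0.9, 0.1, 0, 2.9, 11.5)
    }
    names(vc) <- vc_names
  }
  vc <- vc[vc_names]
  if (anyNA(vc) || any(vc < 0)) {
    stop("vc must be non-negative and name: ",
         paste(vc_names, collapse = ", "), call. = FALSE)
  }
  if (is.null(rho)) rho <- if (alteration == "nutrient") 0.10 else 0.05
  dry_def <- list(
    mean_slope = 1.0,
    treatment_shift = if (alteration == "nutrient") -0.6 else 0,
    selection = 0.35,
    species_sd = 0.04)
  dry <- utils::modifyList(dry_def, dry)

  richness_levels <- sort(unique(as.integer(richness_levels)))
  stopifnot(n_studies >= 1, plots_per_richness >= 1,
            mono_plots_per_species >= 1, n_years >= 1, pool_size >= 1,
            all(richness_levels >= 1), noise_sd >= 0, nugget_sd >= 0,
            mono_sdlog >= 0)
  if (!1L %in% richness_levels) {
    stop("richness_levels must include 1 (monocultures are needed as ",
         "partition denominators)", call. = FALSE)
  }
  if (pool_size < max(richness_levels)) {
    stop("pool_size (", pool_size, ") is smaller than the largest richness ",
         "level (", max(richness_levels), ")", call. = FALSE)
  }
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  structure(list(
    n_studies = as.integer(n_studies),
    richness_levels = richness_levels,
    plots_per_richness = as.integer(plots_per_richness),
    mono_plots_per_species = as.integer(mono_plots_per_species),
    n_years = as.integer(n_years),
    pool_size = as.integer(pool_size),
    alteration = alteration,
    beta = beta, vc = vc, rho = rho,
    noise_sd = noise_sd, nugget_sd = nugget_sd,
    lognormal_noise = isTRUE(lognormal_noise), lognormal_sd = lognormal_sd,
    dry = dry, mono_sdlog = mono_sdlog,
    mono_treatment_mult = mono_treatment_mult,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_studies, " ", x$alteration, " studies, richness {",
      paste(x$richness_levels, collapse = ","), "}, ", x$n_years,
      " years, pool ", x$pool_size, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# one reproducible sub-seed per study, derived from the master seed
.study_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# sqrt-scale monoculture baseline by treatment (0 = control, 1 = treated)
.mu_mono <- function(config, t) {
  if (is.null(config$mono_treatment_mult)) {
    config$beta[["intercept"]] + config$beta[["treatment"]] * t
  } else {
    config$beta[["intercept"]] * sqrt(config$mono_treatment_mult)^t
  }
}

# study-level draws; the caller must have seeded the RNG. Draw order is part
# of the reproducibility contract: species pool first, then study random
# effects, then year effects.
.study_draws <- function(config) {
  p <- config$pool_size
  # centred so the species multiplier has unit mean on the square-root scale
  # (E[sqrt(lambda)] = 1), keeping the plot-total mixed model unbiased at
  # richness 1
  loglam <- stats::rnorm(p, -config$mono_sdlog^2 / 4, config$mono_sdlog)
  lambda <- exp(loglam)
  z <- if (p > 1L && stats::sd(loglam) > 0) {
    (loglam - mean(loglam)) / stats::sd(loglam)
  } else {
    rep(0, p)
  }
  vc <- config$vc
  list(
    lambda = lambda, z = z,
    b_study = stats::rnorm(1, 0, sqrt(vc[["study"]])),
    b_rich = stats::rnorm(1, 0, sqrt(vc[["study_ln_richness"]])),
    b_treat = stats::rnorm(1, 0, sqrt(vc[["study_treatment"]])),
    b_rt = stats::rnorm(1, 0, sqrt(vc[["study_ln_richness_treatment"]])),
    b_year = stats::rnorm(config$n_years, 0, sqrt(vc[["study_time"]]))
  )
}

# expected (year-free) monoculture biomass matrix, pool_size x 2 treatments
.mono_means_yearfree <- function(config, d) {
  sapply(0:1, function(t) {
    pmax(.mu_mono(config, t) + d$b_study + d$b_treat * t, 0)^2 * d$lambda
  })
}

#' Species pools of a simulated experiment
#'
#' Returns the true monoculture biomass of every species in every study,
#' treatment and year: a log-normal species multiplier around the study's
#' square-root-scale baseline (which includes the study, study x treatment
#' and study x time random effects). Nutrient addition raises and drought
#' lowers the baseline through the treatment fixed effect, unless an explicit
#' `mono_treatment_mult` overrides it.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `study_id`, `species_id`, `treatment`,
#'   `year`, `lambda` (species multiplier) and `mean_mono_biomass` (g m^-2).
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .study_seeds(config$seed, config$n_studies)
  out <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    set.seed(seeds[s])
    d <- .study_draws(config)
    grid <- expand.grid(sp = seq_len(config$pool_size), t = 0:1,
                        year = seq_len(config$n_years))
    base <- .mu_mono(config, grid$t) + d$b_study + d$b_treat * grid$t +
      d$b_year[grid$year]
    out[[s]] <- data.frame(
      study_id = sprintf("st%02d", s),
      species_id = sprintf("sp%02d", grid$sp),
      treatment = ifelse(grid$t == 1, "treated", "control"),
      year = grid$year,
      lambda = d$lambda[grid$sp],
      mean_mono_biomass = pmax(base, 0)^2 * d$lambda[grid$sp],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-species mixture biomass from relative-yield deviations
#'
#' Inverts the relative-yield definitions: the observed yield of species i in
#' mixture is `Y_i = max(0, RY_E,i + dRY_i) * M_i`, where `M_i` is its
#' monoculture biomass, `RY_E,i` its sown proportion and `dRY_i` the
#' deviation of its realized relative yield. Deviations that would push the
#' relative yield below zero are truncated (the species is lost from the
#' mixture).
#'
#' @param m positive monoculture biomasses, g m^-2.
#' @param ry_e sown proportions, summing to 1.
#' @param dry relative-yield deviations.
#' @return numeric vector of per-species mixture biomasses.
#' @export
compose_mixture_biomass <- function(m, ry_e, dry) {
  stopifnot(length(m) == length(ry_e), length(m) == length(dry),
            all(m > 0))
  if (abs(sum(ry_e) - 1) > 1e-8) {
    stop("sown proportions must sum to 1", call. = FALSE)
  }
  pmax(0, ry_e + dry) * m
}

#' Closed-form additive partition at known truth
#'
#' Evaluates the net, complementarity and selection effects directly from
#' known per-species yields (or relative-yield deviations) and monoculture
#' biomasses, applying the same low-monoculture exclusion and proportion
#' renormalization as the data path. Used by the generator to record the
#' ground truth that partitioning a noise-free table must reproduce.
#'
#' @param m monoculture biomasses of the sown species.
#' @param dry relative-yield deviations; ignored when `y` is given.
#' @param y per-species mixture yields; computed from `dry` when omitted.
#' @param ry_e sown proportions (default equal, 1/N).
#' @param denominator standardization denominator (treatment mean monoculture
#'   biomass); defaults to the mean of the non-excluded `m`.
#' @param threshold monoculture exclusion threshold, g m^-2.
#' @return list with `net_raw`, `ce_raw`, `se_raw`, `net_std`, `ce_std`,
#'   `se_std`, `denominator`, `n_used`.
#' @export
true_partition <- function(m, dry = NULL, y = NULL,
                           ry_e = rep(1 / length(m), length(m)),
                           denominator = NULL, threshold = 2.5) {
  stopifnot(all(m >= 0), threshold > 0)
  if (is.null(y)) {
    if (is.null(dry)) stop("supply either y or dry", call. = FALSE)
    y <- compose_mixture_biomass(m, ry_e, dry)
  }
  usable <- m >= threshold
  if (is.null(denominator)) denominator <- mean(m[usable])
  if (sum(usable) < 2L) {
    return(list(net_raw = NA_real_, ce_raw = NA_real_, se_raw = NA_real_,
                net_std = NA_real_, ce_std = NA_real_, se_std = NA_real_,
                denominator = denominator, n_used = sum(usable)))
  }
  yu <- y[usable]
  mu <- m[usable]
  re <- ry_e[usable] / sum(ry_e[usable])
  n <- length(yu)
  d <- yu / mu - re
  net <- sum(yu) - sum(re * mu)
  ce <- n * mean(d) * mean(mu)
  se <- n * (mean(d * mu) - mean(d) * mean(mu))
  list(net_raw = net, ce_raw = ce, se_raw = se,
       net_std = net / denominator, ce_std = ce / denominator,
       se_std = se / denominator,
       denominator = denominator, n_used = n)
}

#' Generate a synthetic multi-site diversity experiment
#'
#' Draws a full experiment table plus its ground truth. Total plot biomass is
#' the square of a square-root-scale linear predictor: fixed effects
#' (intercept, ln richness, treatment, interaction) + study-level random
#' effects (study, study x ln richness, study x treatment, study x ln
#' richness x treatment, study x year) + a plot effect + AR(1) residuals
#' across years. Monoculture plot totals additionally carry the species'
#' log-normal multiplier, so species differ in monoculture as real species
#' do. Mixture totals are distributed over member species proportionally to
#' `max(0, RY_E + dRY) * M`, where the deviations `dRY` encode the injected
#' complementarity (mean deviation increasing with ln richness, shifted by
#' treatment) and selection (coupling to log monoculture mass) structure.
#'
#' The recorded truth holds, per mixture plot, the *noise-free* standardized
#' effects: the partition evaluated on the plot's species shares applied to
#' the noise-free total (fixed effects plus the study's own random effects,
#' no year, plot or residual noise). Running [partition_table()] on a table
#' generated with all variances and noise set to zero reproduces these values
#' exactly.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (an [experiment_table()]) and `truth`
#'   (class `bef_truth`): the config, the fixed-effect/variance/correlation
#'   truth, the species pool, a `plot_truth` data.frame of noise-free
#'   per-plot effects, and the realized relative-yield truncation rate.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .study_seeds(config$seed, config$n_studies)
  Y <- config$n_years
  beta <- config$beta
  vc <- config$vc
  rec_list <- cov_list <- truth_list <- vector("list", config$n_studies)
  n_trunc <- 0L
  n_dry <- 0L

  for (s in seq_len(config$n_studies)) {
    set.seed(seeds[s])
    d <- .study_draws(config)
    study <- sprintf("st%02d", s)
    sp_ids <- sprintf("sp%02d", seq_len(config$pool_size))

    # study-level covariates
    if (config$alteration == "nutrient") {
      n_added <- round(exp(stats::rnorm(1, log(10), 0.4)), 1)
      fert <- sample(c("NPK", "NH4NO3"), 1)
      dur <- NA_integer_
    } else {
      n_added <- NA_real_
      fert <- NA_character_
      dur <- sample(c(28L, 42L, 55L, 140L, 160L), 1)
    }

    # plot design: monocultures for every pool species, mixtures per level
    mono <- expand.grid(sp = seq_len(config$pool_size), t = 0:1,
                        rep = seq_len(config$mono_plots_per_species))
    mix_lv <- config$richness_levels[config$richness_levels >= 2L]
    mix <- if (length(mix_lv) > 0L) {
      expand.grid(N = mix_lv, t = 0:1, rep = seq_len(config$plots_per_richness))
    } else {
      data.frame(N = integer(), t = integer(), rep = integer())
    }
    np_mono <- nrow(mono)
    np_mix <- nrow(mix)
    np <- np_mono + np_mix
    plot_ids <- sprintf("%s.p%03d", study, seq_len(np))
    rich <- c(rep(1L, np_mono), mix$N)
    trt <- c(mono$t, mix$t)
    lnN <- log(rich)

    # plot effects and AR(1) residual matrix (np x Y)
    b_plot <- stats::rnorm(np, 0, sqrt(vc[["plot"]]))
    E <- matrix(0, np, Y)
    E[, 1] <- stats::rnorm(np, 0, config$noise_sd)
    if (Y > 1L) {
      innov_sd <- config$noise_sd * sqrt(max(0, 1 - config$rho^2))
      for (yy in 2:Y) {
        E[, yy] <- config$rho * E[, yy - 1] + stats::rnorm(np, 0, innov_sd)
      }
    }
    if (config$nugget_sd > 0) {
      E <- E + matrix(stats::rnorm(np * Y, 0, config$nugget_sd), np, Y)
    }

    # sqrt-scale linear predictor; monoculture baseline honours an explicit
    # treatment multiplier when one is configured
    fixed <- ifelse(rich == 1L,
                    .mu_mono(config, trt),
                    beta[["intercept"]] + beta[["ln_richness"]] * lnN +
                      beta[["treatment"]] * trt +
                      beta[["interaction"]] * lnN * trt)
    study_part <- d$b_study + d$b_rich * lnN + d$b_treat * trt +
      d$b_rt * lnN * trt
    eta0 <- fixed + study_part + b_plot            # year-free part
    eta <- outer(eta0, rep(1, Y)) +
      outer(rep(1, np), d$b_year) + E
    if (config$lognormal_noise) {
      total <- (eta - E)^2 *
        exp(E * (config$lognormal_sd / max(config$noise_sd, 1e-12)))
    } else {
      total <- eta^2
    }

    m_yf <- .mono_means_yearfree(config, d)        # pool_size x 2
    denom <- vapply(1:2, function(tc) {
      keep <- m_yf[, tc] >= 2.5
      if (any(keep)) mean(m_yf[keep, tc]) else NA_real_
    }, numeric(1))

    # monoculture records: species multiplier acts on the biomass scale
    mono_total <- total[seq_len(np_mono), , drop = FALSE] * d$lambda[mono$sp]
    rec_mono <- data.frame(
      study_id = study,
      plot_id = rep(plot_ids[seq_len(np_mono)], each = Y),
      year = rep(seq_len(Y), np_mono),
      sown_richness = 1L,
      treatment = rep(ifelse(mono$t == 1, "treated", "control"), each = Y),
      species_id = rep(sp_ids[mono$sp], each = Y),
      sown_proportion = 1,
      biomass = as.vector(t(mono_total)),
      stringsAsFactors = FALSE)

    # mixture records and per-plot truth
    rec_mix <- NULL
    truth_rows <- vector("list", np_mix)
    if (np_mix > 0L) {
      mix_pieces <- vector("list", np_mix)
      for (j in seq_len(np_mix)) {
        jj <- np_mono + j
        N <- mix$N[j]
        t <- mix$t[j]
        members <- sample.int(config$pool_size, N)
        eps <- stats::rnorm(N, 0, config$dry$species_sd)
        slope <- config$dry$mean_slope + config$dry$treatment_shift * t
        dry_j <- (log(N) / N) *
          (slope + config$dry$selection * d$z[members]) + eps
        ry_e <- rep(1 / N, N)
        ry <- pmax(0, ry_e + dry_j)
        n_trunc <- n_trunc + sum(ry_e + dry_j < 0)
        n_dry <- n_dry + N
        m_j <- m_yf[members, t + 1]
        w <- ry * m_j
        w <- if (sum(w) > 0) w / sum(w) else rep(1 / N, N)
        tot_j <- total[jj, ]
        mix_pieces[[j]] <- data.frame(
          study_id = study,
          plot_id = plot_ids[jj],
          year = rep(seq_len(Y), each = N),
          sown_richness = N,
          treatment = ifelse(t == 1, "treated", "control"),
          species_id = rep(sp_ids[members], Y),
          sown_proportion = rep(ry_e, Y),
          biomass = as.vector(outer(w, tot_j)),
          stringsAsFactors = FALSE)

        # noise-free truth: fixed + study random effects only
        t0 <- (fixed[jj] + study_part[jj])^2
        tp <- true_partition(m = m_j, y = t0 * w, ry_e = ry_e,
                             denominator = denom[t + 1])
        truth_rows[[j]] <- data.frame(
          study_id = study, plot_id = plot_ids[jj],
          treatment = ifelse(t == 1, "treated", "control"),
          sown_richness = N, n_used = tp$n_used,
          net_raw = tp$net_raw, ce_raw = tp$ce_raw, se_raw = tp$se_raw,
          net_std = tp$net_std, ce_std = tp$ce_std, se_std = tp$se_std,
          denominator = tp$denominator,
          n_truncated = sum(ry_e + dry_j < 0),
          stringsAsFactors = FALSE)
      }
      rec_mix <- do.call(rbind, mix_pieces)
    }

    rec_list[[s]] <- rbind(rec_mono, rec_mix)
    cov_list[[s]] <- data.frame(
      study_id = study, plot_id = plot_ids,
      alteration_type = config$alteration,
      n_added = n_added, drought_duration_days = dur, fertilizer = fert,
      stringsAsFactors = FALSE)
    truth_list[[s]] <- if (np_mix > 0L) do.call(rbind, truth_rows) else NULL
  }

  table <- experiment_table(
    do.call(rbind, rec_list), do.call(rbind, cov_list),
    provenance = sprintf("befpart generator, seed %d", config$seed))
  truth <- structure(list(
    config = config,
    beta = config$beta, vc = config$vc, rho = config$rho,
    dry = config$dry,
    species_pool = generate_species_pool(config),
    plot_truth = do.call(rbind, truth_list),
    truncation_rate = if (n_dry > 0L) n_trunc / n_dry else 0
  ), class = "bef_truth")
  list(table = table, truth = truth)
}

#' @export
print.bef_truth <- function(x, ...) {
  cat("<bef_truth> ", x$config$n_studies, " studies (",
      x$config$alteration, "), ",
      if (is.null(x$plot_truth)) 0L else nrow(x$plot_truth),
      " mixture plots, relative-yield truncation rate ",
      signif(x$truncation_rate, 3), "\n", sep = "")
  invisible(x)
}
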