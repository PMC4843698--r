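#' Configuration for the full analysis pipeline
#'
#' Collects the options of the end-to-end analysis: the alteration type, the
#' partitioning options, and which sensitivity analyses to run (excluding
#' low-/high-diversity communities, recoding the treatment by fertilizer
#' type, and adding a resource-amount covariate with its richness and
#' treatment interactions).
#'
#' @param alteration `"nutrient"` or `"drought"`.
#' @param exclude_monocultures run the sensitivity fit without sown richness
#'   1 plots.
#' @param exclude_high_diversity run the sensitivity fit without plots above
#'   `high_diversity_threshold` sown species.
#' @param high_diversity_threshold richness cut for the high-diversity
#'   exclusion (default 20).
#' @param fertilizer_three_level recode treated plots by fertilizer type
#'   (NPK / NH4NO3); nutrient studies only.
#' @param covariate `"auto"` picks `n_added` for nutrient and
#'   `drought_class` for drought runs; `"none"` disables the covariate
#'   sensitivity fit.
#' @param partition_threshold monoculture exclusion threshold, g m^-2.
#' @param denominator_scope standardization scope, see
#'   [standardize_partition()].
#' @param alpha significance level used when flagging terms in reports.
#' @param seed seed for any resampling step (the deterministic fits ignore
#'   it, but it is recorded in the provenance).
#' @return An object of class `bef_analysis_config`.
#' @export
analysis_config <- function(alteration = c("nutrient", "drought"),
                            exclude_monocultures = TRUE,
                            exclude_high_diversity = TRUE,
                            high_diversity_threshold = 20,
                            fertilizer_three_level = NULL,
                            covariate = c("auto", "none", "n_added",
                                          "drought_class"),
                            partition_threshold = 2.5,
                            denominator_scope = "study_treatment_year",
                            alpha = 0.05,
                            seed = 1) {
  alteration <- match.arg(alteration)
  covariate <- match.arg(covariate)
  if (covariate == "auto") {
    covariate <- if (alteration == "nutrient") "n_added" else "drought_class"
  }
  if (is.null(fertilizer_three_level)) {
    fertilizer_three_level <- alteration == "nutrient"
  }
  if (alteration == "drought" && isTRUE(fertilizer_three_level)) {
    stop("drought runs cannot request the fertilizer-type recode",
         call. = FALSE)
  }
  structure(list(alteration = alteration,
                 exclude_monocultures = exclude_monocultures,
                 exclude_high_diversity = exclude_high_diversity,
                 high_diversity_threshold = high_diversity_threshold,
                 fertilizer_three_level = fertilizer_three_level,
                 covariate = covariate,
                 partition_threshold = partition_threshold,
                 denominator_scope = denominator_scope,
                 alpha = alpha, seed = as.integer(seed)),
            class = "bef_analysis_config")
}

.check_analysable <- function(tb) {
  trt <- unique(tb$treatment)
  if (!"control" %in% trt) {
    stop("refusing to fit: treatment level 'control' is missing",
         call. = FALSE)
  }
  if (!any(trt != "control")) {
    stop("refusing to fit: no treated plots (treatment level 'treated' ",
         "is missing)", call. = FALSE)
  }
  if (length(unique(tb$study_id)) < 2L) {
    stop("refusing to fit: a single study cannot support study-level ",
         "random effects", call. = FALSE)
  }
  if (length(unique(tb$sown_richness)) < 2L) {
    stop("refusing to fit: fewer than two sown richness levels remain",
         call. = FALSE)
  }
  invisible(tb)
}

# one fitted section: AR(1) (or given correlation) fit, its
# compound-symmetry competitor when applicable, sequential Wald table
.fit_section <- function(data, spec, compare_cs = TRUE, control = list()) {
  design <- build_design(data, spec)
  fit <- reml_fit(design, control)
  cmp <- NULL
  if (compare_cs && spec$residual_correlation == "ar1") {
    spec_cs <- spec
    spec_cs$residual_correlation <- "compound_symmetry"
    fit_cs <- reml_fit(build_design(data, spec_cs),
                       utils::modifyList(control, list(hessian = FALSE)))
    cmp <- compare_covariance(fit, fit_cs)
  }
  list(fit = fit, wald = wald_sequential(fit), aic_comparison = cmp,
       n_obs = fit$n_obs, n_plots = fit$n_plots, n_studies = fit$n_studies)
}

#' Fit the productivity model of the main analysis
#'
#' Fits the square-root productivity mixed model (fixed effects ln richness,
#' treatment and their interaction; the full study-level random structure;
#' AR(1) residuals across years) to the plot totals of an experiment table,
#' compares the AR(1) residual structure against compound symmetry by AIC,
#' and reports sequential Wald tests, variance components and fitted
#' richness-response lines (pooled and per study).
#'
#' @param table a validated [experiment_table()].
#' @param config an [analysis_config()].
#' @return list (class `bef_report_section`) with elements `fit`, `wald`,
#'   `aic_comparison`, `lines_pooled`, `lines_study`.
#' @export
run_main <- function(table, config) {
  stopifnot(inherits(table, "bef_table"),
            inherits(config, "bef_analysis_config"))
  rep <- validate_table(table)
  if (has_errors(rep)) {
    stop("validation errors block the analysis; first: ",
         rep$issues$message[rep$issues$severity == "error"][1], " at ",
         rep$issues$locator[rep$issues$severity == "error"][1],
         call. = FALSE)
  }
  tb <- .check_analysable(total_biomass_view(table))
  sec <- .fit_section(tb, model_spec("sqrt_total_biomass"))
  sec$lines_pooled <- fitted_lines(sec$fit, level = "pooled")
  sec$lines_study <- fitted_lines(sec$fit, level = "per_study")
  class(sec) <- "bef_report_section"
  sec
}

#' Fit the partition-effect models
#'
#' Computes the standardized net biodiversity, complementarity and selection
#' effects for every mixture plot-year and fits the same fixed/random mixed
#' model to each of the three responses. Nutrient runs keep the AR(1)
#' residual correlation; drought runs drop the temporal correlation structure
#' (independent residuals), mirroring the convergence-driven simplification
#' used for such data.
#'
#' @param table a validated [experiment_table()] with species-level biomass.
#' @param config an [analysis_config()].
#' @return list (class `bef_report_section`) with elements `net`, `ce`, `se`
#'   (each a fitted section), `partition` (the plot-level partition table)
#'   and `partition_counts`.
#' @export
run_partition_models <- function(table, config) {
  stopifnot(inherits(table, "bef_table"),
            inherits(config, "bef_analysis_config"))
  part <- partition_table(table, threshold = config$partition_threshold,
                          scope = config$denominator_scope)
  counts <- attr(part, "summary")
  if (sum(part$status == "ok") == 0L) {
    stop("refusing to fit: no partitionable mixture plot-years (all ",
         "degenerate or lacking monoculture data)", call. = FALSE)
  }
  corr <- if (config$alteration == "nutrient") "ar1" else "independent"
  out <- list()
  for (resp in c("net_std", "ce_std", "se_std")) {
    spec <- model_spec(resp, residual_correlation = corr)
    out[[sub("_std", "", resp)]] <-
      .fit_section(part, spec, compare_cs = FALSE)
  }
  out$partition <- part
  out$partition_counts <- counts
  class(out) <- "bef_report_section"
  out
}

#' Run the sensitivity analyses
#'
#' Refits the productivity model under the configured perturbations:
#' excluding monocultures, excluding high-diversity communities (sown
#' richness above the threshold), recoding treatment by fertilizer type
#' (three levels, nutrient runs only), and adding the resource covariate
#' (`n_added` or `drought_class`) with its richness and treatment
#' interactions. Every run records its row accounting
#' (`rows_in = rows_out + rows_removed`); a run whose filter leaves fewer
#' than two richness levels is reported as a refusal rather than fitted.
#'
#' @param table a validated [experiment_table()].
#' @param config an [analysis_config()].
#' @return named list (class `bef_report_section`) of sensitivity runs; each
#'   is either a fitted section with row accounting or a list with a
#'   `refusal` message.
#' @export
run_sensitivity <- function(table, config) {
  stopifnot(inherits(table, "bef_table"),
            inherits(config, "bef_analysis_config"))
  tb <- total_biomass_view(table)
  out <- list()
  run_filtered <- function(data, spec) {
    tryCatch({
      .check_analysable(data)
      .fit_section(data, spec, compare_cs = FALSE)
    }, error = function(e) list(refusal = conditionMessage(e)))
  }
  account <- function(sec, kept, total) {
    sec$rows_in <- total
    sec$rows_out <- kept
    sec$rows_removed <- total - kept
    sec
  }
  n_all <- nrow(tb)
  if (isTRUE(config$exclude_monocultures)) {
    keep <- tb$sown_richness > 1L
    out$exclude_monocultures <- account(
      run_filtered(tb[keep, , drop = FALSE], model_spec()), sum(keep), n_all)
  }
  if (isTRUE(config$exclude_high_diversity)) {
    keep <- tb$sown_richness <= config$high_diversity_threshold
    out$exclude_high_diversity <- account(
      run_filtered(tb[keep, , drop = FALSE], model_spec()), sum(keep), n_all)
  }
  if (isTRUE(config$fertilizer_three_level)) {
    tb3 <- tb
    treated <- tb3$treatment != "control"
    fert <- tb3$fertilizer
    if (all(is.na(fert[treated]))) {
      out$fertilizer_three_level <- list(
        refusal = "no fertilizer labels available for the recode")
    } else {
      tb3$treatment[treated] <- fert[treated]
      out$fertilizer_three_level <- account(
        run_filtered(tb3, model_spec(treatment_coding = "three_level")),
        n_all, n_all)
    }
  }
  if (config$covariate != "none") {
    out$covariate <- account(
      run_filtered(tb, model_spec(covariate = config$covariate)),
      n_all, n_all)
    out$covariate$covariate <- config$covariate
  }
  class(out) <- "bef_report_section"
  out
}

#' Run the complete analysis and collect a structured report
#'
#' Orchestrates [run_main()], [run_partition_models()] (when species-level
#' biomass is available) and [run_sensitivity()] on one experiment table.
#'
#' @param table a validated [experiment_table()].
#' @param config an [analysis_config()].
#' @return An object of class `bef_report`: list with `main`, `partition`
#'   (or a `partition_refusal` message), `sensitivity` and `provenance`.
#' @export
run_analysis <- function(table, config) {
  main <- run_main(table, config)
  part <- tryCatch(run_partition_models(table, config),
                   error = function(e) conditionMessage(e))
  sens <- run_sensitivity(table, config)
  structure(list(
    main = main,
    partition = if (is.character(part)) NULL else part,
    partition_refusal = if (is.character(part)) part else NULL,
    sensitivity = sens,
    provenance = list(config = unclass(config), seed = config$seed,
                      n_records = nrow(table$records),
                      provenance = table$provenance)
  ), class = "bef_report")
}

#' @export
print.bef_report <- function(x, ...) {
  cat("<bef_report> (", x$provenance$config$alteration, ")\n", sep = "")
  cat("-- productivity --\n")
  print(x$main$wald)
  if (!is.null(x$main$aic_comparison)) print(x$main$aic_comparison)
  if (!is.null(x$partition)) {
    for (nm in c("net", "ce", "se")) {
      cat("-- ", nm, " (standardized) --\n", sep = "")
      print(x$partition[[nm]]$wald)
    }
  } else if (!is.null(x$partition_refusal)) {
    cat("-- partition skipped: ", x$partition_refusal, "\n", sep = "")
  }
  for (nm in names(x$sensitivity)) {
    s <- x$sensitivity[[nm]]
    if (!is.null(s$refusal)) {
      cat("-- sensitivity ", nm, ": refused (", s$refusal, ")\n", sep = "")
    } else {
      cat("-- sensitivity ", nm, " (rows ", s$rows_out, "/", s$rows_in,
          ") --\n", sep = "")
      print(s$wald)
    }
  }
  invisible(x)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates experiments from a [sim_config()], fits the
#' productivity mixed model to each, and summarizes, per fixed effect, the
#' mean estimate, bias, Monte-Carlo standard error, RMSE, 95% CI coverage and
#' the sequential-Wald rejection rate at `alpha`, plus the recovery of the
#' residual AR(1) correlation.
#'
#' @param config a [sim_config()]; its `beta`, `vc` and `rho` are the truth.
#' @param n_reps number of replicates (>= 2).
#' @param seed master seed; per-replicate generator seeds derive from it.
#' @param alpha test level used for rejection rates.
#' @param control passed to [reml_fit()]; defaults to a single start for
#'   speed.
#' @return An object of class `bef_recovery`: list with `fixed` (per-term
#'   summary data.frame), `rho` (summary list), `draws` (per-replicate
#'   estimates) and counts.
#' @export
recovery_study <- function(config, n_reps, seed = 1, alpha = 0.05,
                           control = list(n_starts = 1L)) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 2)
  rep_seeds <- .study_seeds(seed, n_reps)
  truth <- c("(Intercept)" = unname(config$beta["intercept"]),
             "ln_richness" = unname(config$beta["ln_richness"]),
             "treatment" = unname(config$beta["treatment"]),
             "ln_richness:treatment" = unname(config$beta["interaction"]))
  draws <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    tb <- total_biomass_view(generate_experiment(cfg)$table)
    draws[[r]] <- tryCatch({
      fit <- reml_fit(build_design(tb, model_spec()), control)
      wt <- wald_sequential(fit)
      b <- fit$beta
      data.frame(
        rep = r, term = b$term, estimate = b$estimate,
        lower = b$lower, upper = b$upper,
        covered = b$lower <= truth[b$term] & truth[b$term] <= b$upper,
        p_value = wt$p_value[match(b$term, wt$term)],
        rho_hat = fit$rho_hat, converged = fit$converged,
        stringsAsFactors = FALSE)
    }, error = function(e) NULL)
  }
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  ok <- draws$converged
  fixed <- do.call(rbind, lapply(names(truth), function(tm) {
    d <- draws[draws$term == tm & ok, , drop = FALSE]
    est <- d$estimate
    data.frame(term = tm, truth = unname(truth[tm]),
               mean_estimate = mean(est), bias = mean(est) - truth[tm],
               mc_se = stats::sd(est) / sqrt(length(est)),
               rmse = sqrt(mean((est - truth[tm])^2)),
               coverage = mean(d$covered),
               rejection_rate = mean(d$p_value < alpha),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rho_draws <- draws$rho_hat[ok & draws$term == "(Intercept)"]
  structure(list(
    fixed = fixed,
    rho = list(truth = config$rho, mean_estimate = mean(rho_draws),
               mc_se = stats::sd(rho_draws) / sqrt(length(rho_draws))),
    draws = draws,
    n_reps = n_reps,
    n_converged = sum(ok) / length(truth)
  ), class = "bef_recovery")
}

#' @export
print.bef_recovery <- function(x, ...) {
  cat("<bef_recovery> ", x$n_reps, " replicates (", x$n_converged,
      " converged)\n", sep = "")
  f <- x$fixed
  f[-1] <- lapply(f[-1], signif, 4)
  print(f, row.names = FALSE)
  cat(sprintf("rho: truth %.3f, mean estimate %.3f (MC se %.3g)\n",
              x$rho$truth, x$rho$mean_estimate, x$rho$mc_se))
  invisible(x)
}
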