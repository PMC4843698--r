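#' Mean monoculture biomass per study, treatment, year and species
#'
#' Averages total plot biomass over all monoculture plots (sown richness 1) of
#' each species within a study x treatment x year stratum. These means are the
#' relative-yield denominators of the additive partition. Species whose mean
#' falls below `threshold` are flagged `excluded`, because relative yields
#' explode as the monoculture biomass approaches zero.
#'
#' @param table a [experiment_table()] with species-level records.
#' @param threshold exclusion threshold in g m^-2 (default 2.5).
#' @return data.frame with columns `study_id`, `treatment`, `year`,
#'   `species_id`, `mean_mono_biomass`, `n_mono_plots`, `excluded`, one row
#'   per stratum x species that has at least one monoculture plot.
#' @export
mean_monoculture_biomass <- function(table, threshold = 2.5) {
  stopifnot(inherits(table, "bef_table"))
  r <- table$records
  if (all(r$species_id == "TOTAL")) {
    stop("table records only total plot biomass; ",
         "species-level biomass is required for partitioning", call. = FALSE)
  }
  mono <- r[r$sown_richness == 1L, , drop = FALSE]
  if (nrow(mono) == 0L) {
    stop("table contains no monoculture plots", call. = FALSE)
  }
  agg <- stats::aggregate(
    mono["biomass"],
    by = mono[c("study_id", "treatment", "year", "species_id")],
    FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(
    study_id = agg$study_id, treatment = agg$treatment, year = agg$year,
    species_id = agg$species_id,
    mean_mono_biomass = agg$biomass[, "mean"],
    n_mono_plots = as.integer(agg$biomass[, "n"]),
    stringsAsFactors = FALSE)
  out$excluded <- out$mean_mono_biomass < threshold
  attr(out, "threshold") <- threshold
  out[order(out$study_id, out$treatment, out$year, out$species_id), ,
      drop = FALSE]
}

# fast lookup key shared by the partition functions
.mono_key <- function(study, treatment, year, species) {
  paste(study, treatment, year, species, sep = "\r")
}

#' Additive partition of the net biodiversity effect for one mixture plot-year
#'
#' Computes the net biodiversity effect (observed minus expected mixture
#' yield) and its decomposition into complementarity and selection effects.
#' For each usable species i, the observed relative yield is
#' `RY_O,i = Y_O,i / M_i` with `M_i` the mean monoculture biomass of species i
#' in the plot's study x treatment x year stratum; the expected relative yield
#' `RY_E,i` is the species' sown proportion, renormalized over usable species.
#' With `dRY_i = RY_O,i - RY_E,i` and N the number of usable species:
#' `net = sum(Y_O) - sum(RY_E * M)`, `ce = N * mean(dRY) * mean(M)`,
#' `se = N * cov_pop(dRY, M)` where the covariance divides by N, so that
#' `net = ce + se` holds exactly.
#'
#' Species flagged excluded in the monoculture table (mean below the
#' threshold) or lacking monoculture data in the stratum are dropped and
#' listed; the sown proportions of the survivors are renormalized. Plots with
#' fewer than two usable species are returned with a degenerate status and
#' unset effects.
#'
#' @param plot_records data.frame of the species records of a single mixture
#'   plot-year (columns `study_id`, `plot_id`, `year`, `sown_richness`,
#'   `treatment`, `species_id`, `sown_proportion`, `biomass`).
#' @param monos monoculture table from [mean_monoculture_biomass()].
#' @return One-row data.frame with the raw effects, the species accounting
#'   (`n_used`, `excluded_species`) and a `status` of `"ok"`,
#'   `"no_monoculture_data"` or `"degenerate"`. Standardized columns are
#'   filled by [standardize_partition()].
#' @export
partition_plot <- function(plot_records, monos) {
  pr <- as.data.frame(plot_records)
  stopifnot(nrow(pr) >= 1L)
  if (length(unique(pr$plot_id)) != 1L || length(unique(pr$year)) != 1L) {
    stop("partition_plot expects the records of a single plot-year",
         call. = FALSE)
  }
  if (pr$sown_richness[1] < 2L) {
    stop("partition is defined for mixtures (sown_richness >= 2)",
         call. = FALSE)
  }
  key <- .mono_key(pr$study_id, pr$treatment, pr$year, pr$species_id)
  mkey <- .mono_key(monos$study_id, monos$treatment, monos$year,
                    monos$species_id)
  idx <- match(key, mkey)
  m <- monos$mean_mono_biomass[idx]
  excl_flag <- monos$excluded[idx]
  no_data <- is.na(idx)
  usable <- !no_data & !excl_flag
  dropped <- pr$species_id[!usable]
  reason <- ifelse(no_data[!usable], "no_monoculture_data", "below_threshold")

  base <- data.frame(
    study_id = pr$study_id[1], plot_id = pr$plot_id[1], year = pr$year[1],
    treatment = pr$treatment[1], sown_richness = pr$sown_richness[1],
    n_used = sum(usable),
    net_raw = NA_real_, ce_raw = NA_real_, se_raw = NA_real_,
    denominator = NA_real_,
    net_std = NA_real_, ce_std = NA_real_, se_std = NA_real_,
    excluded_species = paste(sprintf("%s(%s)", dropped, reason),
                             collapse = ";"),
    status = "ok", stringsAsFactors = FALSE)

  if (sum(usable) < 2L) {
    base$status <- if (any(no_data)) "no_monoculture_data" else "degenerate"
    return(base)
  }
  y <- pr$biomass[usable]
  m <- m[usable]
  if (any(m <= 0)) {
    stop("non-positive monoculture mean among usable species; ",
         "use a positive exclusion threshold", call. = FALSE)
  }
  ry_e <- pr$sown_proportion[usable]
  ry_e <- ry_e / sum(ry_e)
  n <- length(y)
  dry <- y / m - ry_e
  base$net_raw <- sum(y) - sum(ry_e * m)
  base$ce_raw <- n * mean(dry) * mean(m)
  base$se_raw <- n * (mean(dry * m) - mean(dry) * mean(m))
  base
}

#' Standardize partition effects by mean monoculture biomass
#'
#' Divides the raw net, complementarity and selection effects by the mean of
#' the (non-excluded) species monoculture means of the corresponding
#' treatment, making the effects dimensionless and comparable across
#' treatments. The averaging scope defaults to study x treatment x year so
#' that studies with different productivity scales are never mixed; coarser
#' scopes are available.
#'
#' @param result one or more rows as returned by [partition_plot()].
#' @param monos monoculture table from [mean_monoculture_biomass()].
#' @param scope one of `"study_treatment_year"` (default),
#'   `"study_treatment"`, `"treatment"`.
#' @return `result` with `denominator` and the `*_std` columns filled; rows
#'   whose denominator group is empty or non-positive get status
#'   `"degenerate"`.
#' @export
standardize_partition <- function(result, monos,
                                  scope = c("study_treatment_year",
                                            "study_treatment", "treatment")) {
  scope <- match.arg(scope)
  ok_mono <- monos[!monos$excluded, , drop = FALSE]
  gkey <- function(study, treatment, year) {
    switch(scope,
      study_treatment_year = paste(study, treatment, year, sep = "\r"),
      study_treatment = paste(study, treatment, sep = "\r"),
      treatment = paste(treatment))
  }
  denom_tab <- tapply(ok_mono$mean_mono_biomass,
                      gkey(ok_mono$study_id, ok_mono$treatment, ok_mono$year),
                      mean)
  d <- denom_tab[gkey(result$study_id, result$treatment, result$year)]
  d <- as.numeric(d)
  usable <- result$status == "ok" & !is.na(d) & d > 0
  result$denominator[usable] <- d[usable]
  result$net_std[usable] <- result$net_raw[usable] / d[usable]
  result$ce_std[usable] <- result$ce_raw[usable] / d[usable]
  result$se_std[usable] <- result$se_raw[usable] / d[usable]
  result$status[result$status == "ok" & !usable] <- "degenerate"
  result
}

#' Partition every mixture plot-year of an experiment table
#'
#' Runs [mean_monoculture_biomass()], [partition_plot()] and
#' [standardize_partition()] over all mixture plot-years.
#'
#' @param table a [experiment_table()] with species-level records.
#' @param threshold monoculture exclusion threshold, g m^-2.
#' @param scope standardization scope, see [standardize_partition()].
#' @return data.frame with one row per mixture plot-year (monocultures are
#'   skipped), carrying raw and standardized effects, the denominator, the
#'   species accounting and a status. Attribute `summary` holds the counts of
#'   ok / degenerate / no-monoculture-data plot-years.
#' @export
partition_table <- function(table, threshold = 2.5,
                            scope = "study_treatment_year") {
  stopifnot(inherits(table, "bef_table"))
  monos <- mean_monoculture_biomass(table, threshold = threshold)
  r <- table$records
  mix <- r[r$sown_richness >= 2L, , drop = FALSE]
  if (nrow(mix) == 0L) {
    out <- partition_empty()
    attr(out, "summary") <- c(ok = 0L, degenerate = 0L,
                              no_monoculture_data = 0L)
    return(out)
  }
  py <- paste(mix$study_id, mix$plot_id, mix$year, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(mix)), py), function(i) {
    partition_plot(mix[i, , drop = FALSE], monos)
  })
  out <- do.call(rbind, pieces)
  out <- standardize_partition(out, monos, scope = scope)
  out <- out[order(out$study_id, out$plot_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    ok = sum(out$status == "ok"),
    degenerate = sum(out$status == "degenerate"),
    no_monoculture_data = sum(out$status == "no_monoculture_data"))
  attr(out, "threshold") <- threshold
  attr(out, "scope") <- scope
  out
}

partition_empty <- function() {
  data.frame(study_id = character(), plot_id = character(), year = integer(),
             treatment = character(), sown_richness = integer(),
             n_used = integer(), net_raw = numeric(), ce_raw = numeric(),
             se_raw = numeric(), denominator = numeric(), net_std = numeric(),
             ce_std = numeric(), se_std = numeric(),
             excluded_species = character(), status = character(),
             stringsAsFactors = FALSE)
}
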