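#' Canonical column names for experiment tables
#'
#' The long-format schema used throughout the package. `records` columns hold
#' one row per study x plot x year x species; `covariates` columns hold one
#' row per study x plot.
#'
#' @format A list with elements `records` and `covariates`, each a character
#'   vector of canonical column names.
#' @export
bef_columns <- list(
  records = c("study_id", "plot_id", "year", "sown_richness", "treatment",
              "species_id", "sown_proportion", "biomass"),
  covariates = c("study_id", "plot_id", "alteration_type", "n_added",
                 "drought_duration_days", "fertilizer")
)

#' Construct a multi-site diversity-experiment table
#'
#' Bundles long-format species-level biomass records (one row per study, plot,
#' year and sown species, biomass in g m^-2) with plot-level covariates
#' (alteration type, nutrient amount, drought duration). This is the container
#' every other stage of the package consumes.
#'
#' @param records data.frame with columns `study_id`, `plot_id`, `year`,
#'   `sown_richness`, `treatment`, `species_id`, `sown_proportion`, `biomass`.
#'   `treatment` is `"control"` together with either `"treated"` or the
#'   fertilizer labels `"NPK"`/`"NH4NO3"`.
#' @param covariates data.frame with columns `study_id`, `plot_id`,
#'   `alteration_type` (`"nutrient"` or `"drought"`), `n_added` (g N m^-2),
#'   `drought_duration_days`, and optionally `fertilizer`. A derived
#'   `drought_class` column (`"short"` below 60 days, `"long"` otherwise) is
#'   added if absent.
#' @param provenance free-text origin of the data (file path or generator
#'   seed).
#' @return An object of class `bef_table`: a list with elements `records`,
#'   `covariates` and `provenance`.
#' @seealso [read_experiment_table()], [validate_table()],
#'   [total_biomass_view()]
#' @export
experiment_table <- function(records, covariates, provenance = "in-memory") {
  records <- as.data.frame(records)
  covariates <- as.data.frame(covariates)
  need_rec <- setdiff(bef_columns$records, names(records))
  if (length(need_rec) > 0L) {
    stop("records is missing required column(s): ",
         paste(need_rec, collapse = ", "), call. = FALSE)
  }
  need_cov <- setdiff(c("study_id", "plot_id", "alteration_type"),
                      names(covariates))
  if (length(need_cov) > 0L) {
    stop("covariates is missing required column(s): ",
         paste(need_cov, collapse = ", "), call. = FALSE)
  }
  if (is.null(covariates$n_added)) covariates$n_added <- NA_real_
  if (is.null(covariates$drought_duration_days)) {
    covariates$drought_duration_days <- NA_integer_
  }
  if (is.null(covariates$fertilizer)) covariates$fertilizer <- NA_character_
  covariates$drought_class <- drought_class(covariates$drought_duration_days)
  records$study_id <- as.character(records$study_id)
  records$plot_id <- as.character(records$plot_id)
  records$species_id <- as.character(records$species_id)
  records$treatment <- as.character(records$treatment)
  covariates$study_id <- as.character(covariates$study_id)
  covariates$plot_id <- as.character(covariates$plot_id)
  structure(list(records = records, covariates = covariates,
                 provenance = provenance),
            class = "bef_table")
}

#' Classify drought duration
#'
#' Droughts shorter than 60 days are `"short"`, all others `"long"`.
#'
#' @param days non-negative numbers of days (NA allowed).
#' @return character vector of `"short"`/`"long"`/`NA`.
#' @export
drought_class <- function(days) {
  ifelse(is.na(days), NA_character_, ifelse(days < 60, "short", "long"))
}

#' @export
print.bef_table <- function(x, ...) {
  r <- x$records
  cat("<bef_table> ", length(unique(r$study_id)), " studies, ",
      length(unique(paste(r$study_id, r$plot_id))), " plots, ",
      nrow(r), " species-level records\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a long-format experiment table from delimited text
#'
#' Reads a delimited text file (comma by default, tab supported) holding one
#' row per study x plot x year x species and maps its columns onto the
#' canonical schema via a dialect. Files that record only total plot biomass
#' (no species column in the dialect) are accepted: each plot-year becomes a
#' single record with `species_id = "TOTAL"` and `sown_proportion = 1`, usable
#' for productivity models but not for partitioning.
#'
#' @param path path to the delimited file (header row required, UTF-8).
#' @param dialect either `NULL` (file already uses canonical column names), a
#'   named list/character vector mapping canonical names to file column names,
#'   or the path of a YAML file with a top-level `columns:` mapping and
#'   optional `sep:` entry.
#' @param sep field separator; overridden by the dialect file's `sep:` if set.
#' @return A validated [experiment_table()]. Attribute
#'   `species_level` is `FALSE` when only plot totals were available.
#' @export
read_experiment_table <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- NULL
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    cfg <- yaml::read_yaml(dialect)
    map <- cfg$columns
    if (!is.null(cfg$sep)) sep <- cfg$sep
  } else if (!is.null(dialect)) {
    map <- as.list(dialect)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  all_canon <- unique(c(bef_columns$records, bef_columns$covariates))
  if (is.null(map)) {
    map <- as.list(stats::setNames(intersect(all_canon, names(raw)),
                                   intersect(all_canon, names(raw))))
  }
  required <- c("study_id", "plot_id", "year", "sown_richness", "treatment",
                "biomass")
  missing_req <- required[!required %in% names(map)]
  if (length(missing_req) > 0L) {
    stop("dialect does not name required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  absent <- unlist(map)[!unlist(map) %in% names(raw)]
  if (length(absent) > 0L) {
    stop("file lacks mapped column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  get_col <- function(canon, default = NULL) {
    if (canon %in% names(map)) raw[[map[[canon]]]] else default
  }
  n <- nrow(raw)
  species_level <- "species_id" %in% names(map)
  records <- data.frame(
    study_id = as.character(get_col("study_id")),
    plot_id = as.character(get_col("plot_id")),
    year = as.integer(get_col("year")),
    sown_richness = as.integer(get_col("sown_richness")),
    treatment = as.character(get_col("treatment")),
    species_id = if (species_level) as.character(get_col("species_id"))
                 else rep("TOTAL", n),
    sown_proportion = if (species_level && "sown_proportion" %in% names(map))
                        as.numeric(get_col("sown_proportion"))
                      else rep(1, n),
    biomass = as.numeric(get_col("biomass")),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.na(records$biomass) & records$biomass < 0)
  if (length(bad) > 0L) {
    stop("negative biomass at file row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(records$study_id, records$plot_id, records$year,
               records$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (study, plot, year, species) at file row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  }
  pk <- !duplicated(paste(records$study_id, records$plot_id, sep = "\r"))
  covariates <- data.frame(
    study_id = records$study_id[pk],
    plot_id = records$plot_id[pk],
    alteration_type = {
      x <- get_col("alteration_type")
      if (is.null(x)) rep(NA_character_, sum(pk)) else as.character(x)[pk]
    },
    n_added = {
      x <- get_col("n_added")
      if (is.null(x)) rep(NA_real_, sum(pk)) else as.numeric(x)[pk]
    },
    drought_duration_days = {
      x <- get_col("drought_duration_days")
      if (is.null(x)) rep(NA_integer_, sum(pk)) else as.integer(x)[pk]
    },
    fertilizer = {
      x <- get_col("fertilizer")
      if (is.null(x)) rep(NA_character_, sum(pk)) else as.character(x)[pk]
    },
    stringsAsFactors = FALSE
  )
  out <- experiment_table(records, covariates, provenance = path)
  attr(out, "species_level") <- species_level
  out
}

#' Write an experiment table to delimited text
#'
#' Flattens records and covariates into a single file with canonical column
#' names so that [read_experiment_table()] recovers the table losslessly.
#'
#' @param table a [experiment_table()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "bef_table"))
  cov <- table$covariates
  flat <- merge(table$records,
                cov[, c("study_id", "plot_id", "alteration_type", "n_added",
                        "drought_duration_days", "fertilizer")],
                by = c("study_id", "plot_id"), sort = FALSE)
  ord <- order(flat$study_id, flat$plot_id, flat$year, flat$species_id)
  flat <- flat[ord, c(bef_columns$records, "alteration_type", "n_added",
                      "drought_duration_days", "fertilizer")]
  utils::write.table(flat, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate an experiment table
#'
#' Checks every schema invariant and returns a report instead of throwing:
#' non-negative biomass, richness and year at least 1, sown proportions
#' summing to 1 within each plot-year, monocultures having exactly one
#' species record per year, every plot having covariates, treatment constant
#' within plot, and consecutive years (gaps are flagged as warnings because
#' autoregressive residual models depend on year spacing).
#'
#' @param table a [experiment_table()].
#' @param tol tolerance for the proportion-sum check.
#' @return An object of class `bef_validation`: list with counts
#'   (`n_studies`, `n_plots`, `n_plot_years`) and a data.frame `issues` with
#'   columns `severity` (`"error"`/`"warning"`), `message`, `locator`.
#' @export
validate_table <- function(table, tol = 1e-9) {
  stopifnot(inherits(table, "bef_table"))
  r <- table$records
  issues <- list()
  add <- function(severity, message, locator) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, message = message, locator = locator,
      stringsAsFactors = FALSE)
  }
  plot_key <- paste(r$study_id, r$plot_id, sep = "/")
  py_key <- paste(plot_key, r$year, sep = "/")

  bad <- which(is.na(r$biomass) | r$biomass < 0)
  for (i in bad) add("error", "negative or missing biomass", py_key[i])
  bad <- which(is.na(r$sown_richness) | r$sown_richness < 1)
  for (i in unique(py_key[bad])) add("error", "sown_richness < 1", i)
  bad <- which(is.na(r$year) | r$year < 1)
  for (i in unique(plot_key[bad])) add("error", "year < 1", i)
  bad <- which(is.na(r$sown_proportion) | r$sown_proportion <= 0 |
                 r$sown_proportion > 1)
  for (i in unique(py_key[bad])) add("error", "sown_proportion outside (0,1]", i)

  psum <- tapply(r$sown_proportion, py_key, sum)
  off <- names(psum)[abs(psum - 1) > tol & !is.na(psum)]
  for (i in off) add("error", sprintf("sown proportions sum to %.6g, not 1",
                                      psum[[i]]), i)

  nsp <- tapply(r$species_id, py_key, function(x) length(unique(x)))
  rich <- tapply(r$sown_richness, py_key, function(x) x[1])
  mono_bad <- names(nsp)[rich == 1 & nsp != 1]
  for (i in mono_bad) {
    add("error", "monoculture plot with more than one species record", i)
  }
  dup <- duplicated(paste(py_key, r$species_id, sep = "/"))
  for (i in unique(py_key[dup])) add("error", "duplicate species record", i)

  cov_key <- paste(table$covariates$study_id, table$covariates$plot_id,
                   sep = "/")
  orphans <- setdiff(unique(plot_key), cov_key)
  for (i in orphans) add("error", "plot lacks covariates", i)

  tr_n <- tapply(r$treatment, plot_key, function(x) length(unique(x)))
  for (i in names(tr_n)[tr_n > 1]) {
    add("error", "treatment varies within plot across years", i)
  }
  yr_gap <- tapply(r$year, plot_key, function(y) {
    y <- sort(unique(y))
    length(y) > 1L && any(diff(y) > 1L)
  })
  for (i in names(yr_gap)[yr_gap]) {
    add("warning", "gap in year sequence within plot", i)
  }

  issues <- if (length(issues) > 0L) do.call(rbind, issues) else
    data.frame(severity = character(), message = character(),
               locator = character(), stringsAsFactors = FALSE)
  structure(list(
    n_studies = length(unique(r$study_id)),
    n_plots = length(unique(plot_key)),
    n_plot_years = length(unique(py_key)),
    issues = issues
  ), class = "bef_validation")
}

#' @export
print.bef_validation <- function(x, ...) {
  cat("<bef_validation> ", x$n_studies, " studies / ", x$n_plots,
      " plots / ", x$n_plot_years, " plot-years\n", sep = "")
  ne <- sum(x$issues$severity == "error")
  nw <- sum(x$issues$severity == "warning")
  cat("  ", ne, " error(s), ", nw, " warning(s)\n", sep = "")
  if (nrow(x$issues) > 0L) {
    print(utils::head(x$issues, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Does a validation report block downstream analysis?
#' @param report a [validate_table()] result.
#' @return `TRUE` if any error-severity issue is present.
#' @export
has_errors <- function(report) {
  stopifnot(inherits(report, "bef_validation"))
  any(report$issues$severity == "error")
}

#' Collapse an experiment table to plot-year totals
#'
#' Sums species biomass within each plot-year and joins the design metadata,
#' yielding the response table for productivity models.
#'
#' @param table a [experiment_table()].
#' @return data.frame with one row per (study, plot, year):
#'   `study_id`, `plot_id`, `year`, `sown_richness`, `treatment`,
#'   `total_biomass` plus the plot covariates.
#' @export
total_biomass_view <- function(table) {
  stopifnot(inherits(table, "bef_table"))
  r <- table$records
  agg <- stats::aggregate(
    r["biomass"],
    by = r[c("study_id", "plot_id", "year", "sown_richness", "treatment")],
    FUN = sum)
  names(agg)[names(agg) == "biomass"] <- "total_biomass"
  out <- merge(agg, table$covariates, by = c("study_id", "plot_id"),
               sort = FALSE)
  out[order(out$study_id, out$plot_id, out$year), , drop = FALSE]
}
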