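#' Specify a hierarchical mixed model for diversity-experiment responses
#'
#' Declares the model fitted throughout the package: a Gaussian linear mixed
#' model with fixed effects for ln(sown richness), treatment and their
#' interaction (tested sequentially, in the listed order), study-level random
#' effects with independent variances (diagonal G), a plot random intercept,
#' and a residual correlation across years within plots that is first-order
#' autoregressive, compound-symmetric or independent.
#'
#' @param response one of `"sqrt_total_biomass"` (square root of total plot
#'   biomass), the standardized partition effects `"net_std"`, `"ce_std"`,
#'   `"se_std"`, or `"value"` (use a `value` column as-is).
#' @param fixed_terms ordered character vector of fixed terms; the intercept
#'   is always included first. Available: `"ln_richness"`, `"treatment"`,
#'   `"ln_richness:treatment"` plus covariate terms added via `covariate`.
#' @param random_terms subset of `"study"`, `"study_ln_richness"`,
#'   `"study_treatment"`, `"study_ln_richness_treatment"`, `"study_time"`,
#'   `"plot"`.
#' @param residual_correlation `"ar1"`, `"compound_symmetry"` or
#'   `"independent"`. A `plot` random term is required unless independent.
#' @param treatment_coding `"binary"` (0 control, 1 treated) or
#'   `"three_level"` (control reference plus NPK and NH4NO3 indicators).
#' @param covariate optional `"n_added"` or `"drought_class"`; appends the
#'   covariate main effect and its interactions with ln richness and
#'   treatment to the fixed terms, in that order.
#' @return An object of class `bef_model_spec`.
#' @export
model_spec <- function(response = c("sqrt_total_biomass", "net_std",
                                    "ce_std", "se_std", "value"),
                       fixed_terms = c("ln_richness", "treatment",
                                       "ln_richness:treatment"),
                       random_terms = c("study", "study_ln_richness",
                                        "study_treatment",
                                        "study_ln_richness_treatment",
                                        "study_time", "plot"),
                       residual_correlation = c("ar1", "compound_symmetry",
                                                "independent"),
                       treatment_coding = c("binary", "three_level"),
                       covariate = NULL) {
  response <- match.arg(response)
  residual_correlation <- match.arg(residual_correlation)
  treatment_coding <- match.arg(treatment_coding)
  all_random <- c("study", "study_ln_richness", "study_treatment",
                  "study_ln_richness_treatment", "study_time", "plot")
  bad <- setdiff(random_terms, all_random)
  if (length(bad) > 0L) {
    stop("unknown random term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  random_terms <- all_random[all_random %in% random_terms]
  if (residual_correlation != "independent" && !"plot" %in% random_terms) {
    stop("a plot random term is required when residual_correlation is not ",
         "independent", call. = FALSE)
  }
  if (!is.null(covariate)) {
    covariate <- match.arg(covariate, c("n_added", "drought_class"))
    fixed_terms <- c(fixed_terms, covariate,
                     paste0("ln_richness:", covariate),
                     paste0("treatment:", covariate))
  }
  known_fixed <- c("ln_richness", "treatment", "ln_richness:treatment",
                   "n_added", "ln_richness:n_added", "treatment:n_added",
                   "drought_class", "ln_richness:drought_class",
                   "treatment:drought_class")
  bad <- setdiff(fixed_terms, known_fixed)
  if (length(bad) > 0L) {
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_terms = random_terms,
                 residual_correlation = residual_correlation,
                 treatment_coding = treatment_coding,
                 covariate = covariate),
            class = "bef_model_spec")
}

#' @export
print.bef_model_spec <- function(x, ...) {
  cat("<bef_model_spec> ", x$response, " ~ ",
      paste(c("1", x$fixed_terms), collapse = " + "), "\n", sep = "")
  cat("  random: ", paste(x$random_terms, collapse = ", "), "\n", sep = "")
  cat("  residual correlation: ", x$residual_correlation, "\n", sep = "")
  invisible(x)
}

# fixed-effect design matrix shared by build_design() and fitted_lines().
# Returns X with one column block per term (intercept first) and the
# term label of every column.
.build_fixed <- function(data, spec) {
  n <- nrow(data)
  lnN <- log(data$sown_richness)
  three <- spec$treatment_coding == "three_level"
  if (three) {
    ok_lab <- c("control", "NPK", "NH4NO3")
    bad <- setdiff(unique(data$treatment), ok_lab)
    if (length(bad) > 0L) {
      stop("unknown treatment label(s) for three-level coding: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tr_npk <- as.numeric(data$treatment == "NPK")
    tr_an <- as.numeric(data$treatment == "NH4NO3")
  }
  tr_bin <- as.numeric(data$treatment != "control")
  cov_col <- function(name) {
    if (name == "n_added") {
      v <- data$n_added
      if (anyNA(v)) stop("n_added covariate has missing values",
                         call. = FALSE)
      as.numeric(v)
    } else {
      v <- data$drought_class
      if (anyNA(v)) stop("drought_class covariate has missing values",
                         call. = FALSE)
      as.numeric(v == "long")
    }
  }
  cols <- list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  labels <- "(Intercept)"
  for (term in spec$fixed_terms) {
    m <- switch(term,
      "ln_richness" = matrix(lnN, ncol = 1,
                             dimnames = list(NULL, "ln_richness")),
      "treatment" = if (three) {
        cbind(treatmentNPK = tr_npk, treatmentNH4NO3 = tr_an)
      } else {
        matrix(tr_bin, ncol = 1, dimnames = list(NULL, "treatment"))
      },
      "ln_richness:treatment" = if (three) {
        cbind("ln_richness:treatmentNPK" = lnN * tr_npk,
              "ln_richness:treatmentNH4NO3" = lnN * tr_an)
      } else {
        matrix(lnN * tr_bin, ncol = 1,
               dimnames = list(NULL, "ln_richness:treatment"))
      },
      "n_added" = matrix(cov_col("n_added"), ncol = 1,
                         dimnames = list(NULL, "n_added")),
      "ln_richness:n_added" = matrix(lnN * cov_col("n_added"), ncol = 1,
        dimnames = list(NULL, "ln_richness:n_added")),
      "treatment:n_added" = matrix(tr_bin * cov_col("n_added"), ncol = 1,
        dimnames = list(NULL, "treatment:n_added")),
      "drought_class" = matrix(cov_col("drought_class"), ncol = 1,
        dimnames = list(NULL, "drought_classlong")),
      "ln_richness:drought_class" = matrix(
        lnN * cov_col("drought_class"), ncol = 1,
        dimnames = list(NULL, "ln_richness:drought_classlong")),
      "treatment:drought_class" = matrix(
        tr_bin * cov_col("drought_class"), ncol = 1,
        dimnames = list(NULL, "treatment:drought_classlong")),
      stop("unhandled fixed term: ", term, call. = FALSE))
    cols[[length(cols) + 1L]] <- m
    labels <- c(labels, rep(term, ncol(m)))
  }
  X <- do.call(cbind, cols)
  list(X = X, term_of_col = labels, tr_bin = tr_bin, lnN = lnN)
}

#' Build REML design structures from a plot-year table
#'
#' Converts a plot-year data.frame (the output of [total_biomass_view()] or
#' [partition_table()], possibly merged with covariates) into the response
#' vector, fixed design matrix, per-study random-effect incidence patterns
#' and year-lag structures consumed by [reml_fit()]. Rows are ordered by
#' study, plot and year so residual correlation blocks are banded by plot;
#' rows with a missing response are dropped.
#'
#' @param data data.frame with columns `study_id`, `plot_id`, `year`,
#'   `sown_richness`, `treatment`, the response column required by `spec`,
#'   and covariate columns when the spec uses them.
#' @param spec a [model_spec()].
#' @return An object of class `bef_design`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "bef_model_spec"))
  data <- as.data.frame(data)
  need <- c("study_id", "plot_id", "year", "sown_richness", "treatment")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$sown_richness < 1)) {
    stop("sown_richness must be >= 1 (ln transform)", call. = FALSE)
  }
  y <- switch(spec$response,
    sqrt_total_biomass = {
      if (!"total_biomass" %in% names(data)) {
        stop("response sqrt_total_biomass needs a total_biomass column",
             call. = FALSE)
      }
      if (any(data$total_biomass < 0, na.rm = TRUE)) {
        stop("negative total biomass; square-root transform undefined",
             call. = FALSE)
      }
      sqrt(data$total_biomass)
    },
    {
      if (!spec$response %in% names(data)) {
        stop("data lacks response column ", spec$response, call. = FALSE)
      }
      data[[spec$response]]
    })
  keep <- is.finite(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  ord <- order(data$study_id, data$plot_id, data$year)
  data <- data[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(data)
  if (n == 0L) stop("no usable rows after dropping missing responses",
                    call. = FALSE)
  studies <- unique(data$study_id)
  if (length(studies) < 2L) {
    stop("at least two studies are required to fit study-level random ",
         "effects", call. = FALSE)
  }

  fx <- .build_fixed(data, spec)
  X <- fx$X
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is singular", call. = FALSE)

  K <- length(spec$random_terms)
  plot_key <- paste(data$study_id, data$plot_id, sep = "\r")
  plot_gamma <- match("plot", spec$random_terms, nomatch = 0L)
  blocks <- vector("list", length(studies))
  for (b in seq_along(studies)) {
    idx <- which(data$study_id == studies[b])
    ns <- length(idx)
    yr <- as.integer(data$year[idx])
    # contiguous plot runs (rows are ordered by study, plot, year)
    runs <- rle(plot_key[idx])
    plot_len <- runs$lengths
    plot_start <- cumsum(c(1L, plot_len[-length(plot_len)]))
    # low-rank study-level random-term columns with their gamma indices
    ucols <- list()
    umap <- integer(0)
    rand <- vector("list", K)
    for (k in seq_len(K)) {
      term <- spec$random_terms[k]
      if (term %in% c("plot")) next
      if (term == "study_time") {
        for (y0 in sort(unique(yr))) {
          ucols[[length(ucols) + 1L]] <- as.numeric(yr == y0)
          umap <- c(umap, k)
        }
        rand[[k]] <- list(a = rep(1, ns))
        next
      }
      a <- switch(term,
        study = rep(1, ns),
        study_ln_richness = fx$lnN[idx],
        study_treatment = fx$tr_bin[idx],
        study_ln_richness_treatment = fx$lnN[idx] * fx$tr_bin[idx])
      ucols[[length(ucols) + 1L]] <- a
      umap <- c(umap, k)
      rand[[k]] <- list(a = a)
    }
    U <- if (length(ucols) > 0L) do.call(cbind, ucols) else
      matrix(numeric(0), ns, 0L)
    blocks[[b]] <- list(X = X[idx, , drop = FALSE], y = y[idx],
                        U = U, map = as.integer(umap),
                        plot_start = as.integer(plot_start),
                        plot_len = as.integer(plot_len),
                        year = yr, plot_gamma = as.integer(plot_gamma),
                        rand = rand)
  }
  max_years <- max(tapply(data$year, plot_key, length))
  structure(list(
    spec = spec, y = y, X = X, blocks = blocks,
    term_of_col = fx$term_of_col,
    terms = unique(fx$term_of_col),
    K = K, p = p, n = n,
    corr = switch(spec$residual_correlation,
                  independent = 0L, ar1 = 1L, compound_symmetry = 2L),
    cs_lo = max(-0.95, -1 / max(max_years - 1, 1) + 1e-3),
    n_studies = length(studies),
    n_plots = length(unique(plot_key)),
    studies = studies,
    index = data.frame(study_id = data$study_id, plot_id = data$plot_id,
                       year = data$year,
                       sown_richness = data$sown_richness,
                       treatment = data$treatment,
                       stringsAsFactors = FALSE)
  ), class = "bef_design")
}

#' @export
print.bef_design <- function(x, ...) {
  cat("<bef_design> n = ", x$n, " plot-years, ", x$n_plots, " plots, ",
      x$n_studies, " studies; p = ", x$p, " fixed columns, K = ", x$K,
      " random terms, residual ", x$spec$residual_correlation, "\n", sep = "")
  invisible(x)
}
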