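# Restricted-likelihood machinery. The marginal covariance is
#   V = sum_k sigma2_k Z_k Z_k' + sigma2_e C(rho),
# block diagonal by study. Internally the residual variance is profiled out:
# with gamma_k = sigma2_k / sigma2_e and W = C(rho) + sum_k gamma_k A_k,
# the restricted log-likelihood is maximized over (log gamma, mapped rho).

# bounded transforms for the residual correlation parameter
.rho_map <- function(x, corr, lo = -0.95) {
  if (corr == 1L) 0.999 * tanh(x)
  else lo + (0.999 - lo) * stats::plogis(x)
}
.rho_unmap <- function(rho, corr, lo = -0.95) {
  if (corr == 1L) atanh(rho / 0.999)
  else stats::qlogis(pmin(pmax((rho - lo) / (0.999 - lo), 1e-8), 1 - 1e-8))
}

# REML pieces at variance ratios gamma and correlation rho; NULL if the
# implied covariance is not positive definite
.pieces <- function(design, gamma, rho) {
  pc <- reml_pieces_cpp(design$blocks, as.numeric(gamma), rho, design$corr,
                        design$p)
  if (!isTRUE(pc$ok)) return(NULL)
  pc
}

# profiled restricted log-likelihood and derived quantities
.profile_ll <- function(design, pc) {
  np <- design$n - design$p
  ch <- tryCatch(chol(pc$XtWiX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), pc$XtWiy))
  quad <- max(pc$ytWiy - sum(pc$XtWiy * beta), 1e-300)
  sigma2 <- quad / np
  logdet_xx <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (np * log(2 * pi) + np * log(sigma2) + pc$logdetW +
                  logdet_xx + np)
  list(ll = ll, beta = beta, sigma2 = sigma2, chol_xtwix = ch)
}

#' Restricted log-likelihood of a mixed-model design
#'
#' Evaluates the Gaussian restricted log-likelihood at given variance
#' components, residual variance and residual correlation. Useful for
#' likelihood probes and for checking the fitted optimum against a direct
#' dense-matrix evaluation.
#'
#' @param design a [build_design()] object.
#' @param vc variance components, in the order of `design$spec$random_terms`.
#' @param sigma2 residual variance (> 0).
#' @param rho residual correlation (ignored for independent residuals).
#' @return The restricted log-likelihood (at the GLS fixed effects implied by
#'   these covariance parameters), or `NA` if the covariance is not positive
#'   definite.
#' @export
reml_loglik <- function(design, vc, sigma2, rho = 0) {
  stopifnot(inherits(design, "bef_design"), sigma2 > 0,
            length(vc) == design$K, all(vc >= 0))
  pc <- .pieces(design, vc / sigma2, rho)
  if (is.null(pc)) return(NA_real_)
  np <- design$n - design$p
  ch <- tryCatch(chol(pc$XtWiX), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  beta <- backsolve(ch, forwardsolve(t(ch), pc$XtWiy))
  quad <- pc$ytWiy - sum(pc$XtWiy * beta)
  -0.5 * (np * log(2 * pi) + np * log(sigma2) + pc$logdetW +
            2 * sum(log(diag(ch))) + quad / sigma2)
}

# rough method-of-moments starting ratios from OLS residuals
.mom_start <- function(design) {
  r <- stats::residuals(stats::lm.fit(design$X, design$y))
  idx <- design$index
  pk <- paste(idx$study_id, idx$plot_id, sep = "\r")
  wv <- tapply(r, pk, stats::var)
  w2 <- mean(wv, na.rm = TRUE)
  if (!is.finite(w2) || w2 <= 0) w2 <- max(stats::var(r) / 2, 1e-6)
  vs <- stats::var(tapply(r, idx$study_id, mean))
  if (!is.finite(vs)) vs <- w2
  g_study <- min(max(vs / w2, 0.02), 50)
  g_plot <- min(max((stats::var(r) - w2) / w2, 0.05), 50)
  vapply(design$spec$random_terms, function(term) {
    switch(term,
      study = g_study,
      study_ln_richness = 0.3 * g_study,
      study_treatment = 0.3 * g_study,
      study_ln_richness_treatment = 0.1 * g_study,
      study_time = 0.3,
      plot = g_plot)
  }, numeric(1))
}

#' Fit a hierarchical mixed model by restricted maximum likelihood
#'
#' Maximizes the restricted likelihood of the Gaussian mixed model declared
#' by the design's [model_spec()]: independent study-level random effects,
#' an optional plot intercept, and AR(1), compound-symmetry or independent
#' residual correlation across years within plots. Variance ratios are
#' optimized on the log scale and the correlation through a bounded
#' transform, with the residual variance profiled out; three starting points
#' (method-of-moments, small, moderate) guard against local optima.
#'
#' Standard errors of the variance components come from the numerical
#' information matrix of the restricted likelihood; components estimated at
#' the zero boundary are flagged and their z ratios suppressed. Denominator
#' degrees of freedom for fixed effects use a Satterthwaite-style
#' approximation (finite-difference gradient of each coefficient's variance
#' with respect to the covariance parameters), falling back to residual
#' degrees of freedom when the information matrix is unusable; the method is
#' recorded in the output. The AIC counts covariance parameters only, so fits
#' sharing a fixed structure are REML-comparable.
#'
#' @param design a [build_design()] object.
#' @param control list; `maxit` (default 500), `reltol` (1e-10), `starts`
#'   (list of extra starting ratio vectors), `n_starts` (default 3; set 1 for
#'   large simulation sweeps), `hessian` (FALSE skips the information matrix,
#'   variance-component standard errors and Satterthwaite df).
#' @return An object of class `bef_fit` with fixed-effect estimates, 95%
#'   confidence intervals, variance components with standard errors and z
#'   ratios, the AR(1)/CS correlation, REML log-likelihood, AIC and
#'   convergence diagnostics.
#' @export
reml_fit <- function(design, control = list()) {
  stopifnot(inherits(design, "bef_design"))
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10, starts = NULL,
                                n_starts = 3L, hessian = TRUE), control)
  K <- design$K
  corr <- design$corr
  has_rho <- corr != 0L
  npar <- K + has_rho

  obj <- function(theta) {
    if (any(!is.finite(theta)) || any(theta[seq_len(K)] > 21)) return(1e10)
    gamma <- exp(theta[seq_len(K)])
    rho <- if (has_rho) .rho_map(theta[K + 1L], corr, design$cs_lo) else 0
    pc <- .pieces(design, gamma, rho)
    if (is.null(pc)) return(1e10)
    pr <- .profile_ll(design, pc)
    if (is.null(pr) || !is.finite(pr$ll)) return(1e10)
    -pr$ll
  }

  starts <- list()
  if (K > 0L) {
    starts <- list(log(.mom_start(design)), rep(log(0.05), K), rep(0, K))
    starts <- starts[seq_len(min(ctl$n_starts, 3L))]
  } else {
    starts <- list(numeric(0))
  }
  if (!is.null(ctl$starts)) starts <- c(starts, lapply(ctl$starts, log))
  if (has_rho) starts <- lapply(starts, function(s) c(s, 0))

  best <- NULL
  conv <- FALSE
  if (npar == 0L) {
    best <- list(par = numeric(0), value = obj(numeric(0)))
    conv <- TRUE
  } else if (npar == 1L) {
    o <- stats::optimize(function(t) obj(t), interval = c(-18, 10),
                         tol = 1e-10)
    best <- list(par = o$minimum, value = o$objective)
    conv <- TRUE
  } else {
    # short probe from every start, then restarted polish from the best one;
    # a restart whose improvement is below tolerance also counts as converged
    # (Nelder-Mead simplices collapse slowly along zero-variance boundaries)
    probes <- lapply(starts, function(s) {
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 100L, reltol = 1e-8))
    })
    vals <- vapply(probes, `[[`, numeric(1), "value")
    o <- probes[[which.min(vals)]]
    conv <- FALSE
    for (attempt in 1:6) {
      o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                         control = list(maxit = ctl$maxit * 2L,
                                        reltol = ctl$reltol))
      improvement <- o$value - o2$value
      o <- o2
      if (o2$convergence == 0 || improvement < 1e-6) {
        conv <- TRUE
        break
      }
    }
    best <- o
  }
  theta <- best$par
  gamma <- exp(theta[seq_len(K)])
  rho <- if (has_rho) .rho_map(theta[K + 1L], corr, design$cs_lo) else 0
  pc <- .pieces(design, gamma, rho)
  pr <- .profile_ll(design, pc)
  if (is.null(pr)) stop("restricted likelihood undefined at the optimum",
                        call. = FALSE)
  sigma2 <- pr$sigma2
  vc_hat <- gamma * sigma2
  beta_hat <- as.numeric(pr$beta)
  names(beta_hat) <- colnames(design$X)
  cov_beta <- sigma2 * chol2inv(pr$chol_xtwix)
  dimnames(cov_beta) <- list(colnames(design$X), colnames(design$X))
  n_covpar <- K + 1L + has_rho
  ll <- -best$value
  aic <- -2 * ll + 2 * n_covpar

  # information matrix on the natural scale (vc, sigma2, rho)
  phi <- c(vc_hat, sigma2, if (has_rho) rho)
  phi_names <- c(design$spec$random_terms, "residual",
                 if (has_rho) "rho")
  names(phi) <- phi_names
  f_phi <- function(ph) {
    vc <- pmax(ph[seq_len(K)], 0)
    s2 <- ph[K + 1L]
    if (s2 <= 0) return(NA_real_)
    r <- if (has_rho) ph[K + 2L] else 0
    reml_loglik(design, vc, s2, r)
  }
  vphi <- NULL
  phi_se <- rep(NA_real_, length(phi))
  if (isTRUE(ctl$hessian)) {
    # information matrix over the interior parameters only: components at the
    # zero boundary are held fixed (their SEs are not meaningful there)
    active <- rep(TRUE, length(phi))
    active[seq_len(K)] <- gamma >= 1e-5
    f_act <- function(pa) {
      ph <- phi
      ph[active] <- pa
      f_phi(ph)
    }
    H <- .num_hessian(f_act, phi[active])
    vsub <- tryCatch({
      v <- solve(-H)
      if (all(is.finite(diag(v))) && all(diag(v) > 0)) v else NULL
    }, error = function(e) NULL)
    if (!is.null(vsub)) {
      vphi <- matrix(0, length(phi), length(phi))
      vphi[active, active] <- vsub
      phi_se[active] <- sqrt(diag(vsub))
    }
  }
  boundary <- c(gamma < 1e-5, FALSE, if (has_rho) FALSE)
  vc_tab <- data.frame(
    component = phi_names,
    estimate = phi,
    se = phi_se,
    z_ratio = ifelse(boundary, NA_real_, phi / phi_se),
    boundary = boundary,
    row.names = NULL, stringsAsFactors = FALSE)

  fit <- structure(list(
    spec = design$spec, design = design,
    beta_hat = beta_hat, cov_beta = cov_beta,
    vc = vc_tab, vc_hat = stats::setNames(vc_hat, design$spec$random_terms),
    sigma2 = sigma2, rho_hat = if (has_rho) rho else NA_real_,
    rho_se = if (has_rho) phi_se[length(phi)] else NA_real_,
    gamma = gamma, phi = phi, vphi = vphi,
    reml_loglik = ll, aic = aic, n_covparams = n_covpar,
    converged = conv && is.finite(ll),
    n_obs = design$n, n_plots = design$n_plots,
    n_studies = design$n_studies
  ), class = "bef_fit")

  dd <- .coef_ddf(fit, compute = isTRUE(ctl$hessian))
  fit$ddf <- dd$df
  fit$ddf_method <- dd$method
  tq <- stats::qt(0.975, dd$df)
  se <- sqrt(diag(cov_beta))
  fit$beta <- data.frame(
    term = colnames(design$X), estimate = beta_hat, se = se,
    df = dd$df, lower = beta_hat - tq * se, upper = beta_hat + tq * se,
    row.names = NULL, stringsAsFactors = FALSE)
  fit
}

# central-difference Hessian
.num_hessian <- function(f, x) {
  k <- length(x)
  h <- pmax(1e-3 * abs(x), 1e-5)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]
      ej[j] <- h[j]
      fpp <- f(x + ei + ej)
      fpm <- f(x + ei - ej)
      fmp <- f(x - ei + ej)
      fmm <- f(x - ei - ej)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  H
}

# Satterthwaite-style denominator df per fixed-effect coefficient:
# df_j = 2 L_j^2 / (g_j' Vphi g_j) with L_j(phi) = [sigma2 (X'W^-1X)^-1]_jj
# and g_j its finite-difference gradient over the covariance parameters.
# Falls back to residual df when the information matrix is unusable.
.coef_ddf <- function(fit, compute = TRUE) {
  design <- fit$design
  p <- design$p
  resid_df <- max(design$n - p, 1)
  fallback <- list(df = rep(resid_df, p),
                   method = rep("residual", p))
  if (!compute || is.null(fit$vphi)) return(fallback)
  K <- design$K
  has_rho <- design$corr != 0L
  phi <- fit$phi
  covdiag_at <- function(ph) {
    vc <- pmax(ph[seq_len(K)], 0)
    s2 <- ph[K + 1L]
    r <- if (has_rho) ph[K + 2L] else 0
    pc <- .pieces(design, if (K > 0) vc / s2 else numeric(0), r)
    if (is.null(pc)) return(rep(NA_real_, p))
    ch <- tryCatch(chol(pc$XtWiX), error = function(e) NULL)
    if (is.null(ch)) return(rep(NA_real_, p))
    s2 * diag(chol2inv(ch))
  }
  k <- length(phi)
  h <- pmax(1e-3 * abs(phi), 1e-5)
  G <- matrix(NA_real_, k, p)   # gradient of each coefficient variance
  for (i in seq_len(k)) {
    e <- numeric(k)
    e[i] <- h[i]
    G[i, ] <- (covdiag_at(phi + e) - covdiag_at(phi - e)) / (2 * h[i])
  }
  L <- diag(fit$cov_beta)
  df <- rep(NA_real_, p)
  method <- rep("satterthwaite", p)
  for (j in seq_len(p)) {
    g <- G[, j]
    denom <- if (all(is.finite(g))) drop(t(g) %*% fit$vphi %*% g) else NA
    dj <- if (is.finite(denom) && denom > 0) 2 * L[j]^2 / denom else NA
    if (is.finite(dj) && dj > 0) {
      df[j] <- min(max(dj, 1), resid_df)
    } else {
      df[j] <- resid_df
      method[j] <- "residual"
    }
  }
  list(df = df, method = method)
}

#' Sequential (type-I) Wald tests of the fixed effects
#'
#' Tests each fixed term added last among its predecessors, in the order the
#' model spec lists them, using the fitted marginal covariance: the data are
#' whitened with the estimated covariance and the sequential sums of squares
#' are read off a QR decomposition. Denominator degrees of freedom are the
#' fitted object's per-coefficient approximation (averaged within multi-column
#' terms); the method used is recorded.
#'
#' @param fit a converged [reml_fit()].
#' @return data.frame (class `bef_wald`) with one row per fixed term:
#'   `term`, `F`, `num_df`, `den_df`, `p_value`. Attribute `ddf_method`
#'   records the approximation used.
#' @export
wald_sequential <- function(fit) {
  stopifnot(inherits(fit, "bef_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; refusing to compute Wald tests",
         call. = FALSE)
  }
  design <- fit$design
  pc <- .pieces(design, fit$gamma,
                if (is.na(fit$rho_hat)) 0 else fit$rho_hat)
  if (is.null(pc)) stop("covariance not positive definite at the fitted ",
                        "parameters", call. = FALSE)
  # sequential (type-I) sums of squares from nested GLS fits: RSS over the
  # whitened data using the leading j columns, j = 0, 1, ..., p
  p <- design$p
  rss <- numeric(p + 1L)
  rss[1] <- pc$ytWiy
  for (j in seq_len(p)) {
    S <- seq_len(j)
    bj <- solve(pc$XtWiX[S, S, drop = FALSE], pc$XtWiy[S])
    rss[j + 1L] <- pc$ytWiy - sum(pc$XtWiy[S] * bj)
  }
  ss_col <- rss[-length(rss)] - rss[-1]
  terms <- unique(design$term_of_col)
  rows <- lapply(terms, function(tm) {
    j <- which(design$term_of_col == tm)
    q <- length(j)
    Fstat <- sum(ss_col[j]) / q / fit$sigma2
    ddf <- mean(fit$ddf[j])
    data.frame(term = tm, F = Fstat, num_df = q, den_df = ddf,
               p_value = stats::pf(Fstat, q, ddf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ddf_method") <- paste(unique(fit$ddf_method), collapse = "+")
  attr(out, "order") <- terms
  class(out) <- c("bef_wald", "data.frame")
  out
}

#' @export
print.bef_wald <- function(x, ...) {
  cat("Sequential Wald tests (denominator df: ", attr(x, "ddf_method"),
      ")\n", sep = "")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 4)
  df$den_df <- signif(df$den_df, 4)
  df$p_value <- format.pval(df$p_value, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare residual covariance structures by AIC
#'
#' Compares two REML fits of the same data, fixed structure and random terms
#' that differ only in the residual correlation structure (e.g. AR(1) versus
#' compound symmetry). Because the AIC counts covariance parameters on top of
#' a shared fixed structure, the fits are REML-comparable.
#'
#' @param fit_a,fit_b two [reml_fit()] objects.
#' @return list (class `bef_cov_comparison`) with the named AIC vector,
#'   `delta_aic` (`fit_a` minus `fit_b`), the `selected` structure (lower
#'   AIC; the first argument on an exact tie) and a `tie` flag.
#' @export
compare_covariance <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "bef_fit"), inherits(fit_b, "bef_fit"))
  if (fit_a$n_obs != fit_b$n_obs ||
      !identical(fit_a$spec$fixed_terms, fit_b$spec$fixed_terms) ||
      !identical(fit_a$spec$random_terms, fit_b$spec$random_terms)) {
    stop("fits must share data, fixed terms and random terms", call. = FALSE)
  }
  labs <- c(fit_a$spec$residual_correlation, fit_b$spec$residual_correlation)
  aic <- stats::setNames(c(fit_a$aic, fit_b$aic), labs)
  tie <- isTRUE(all.equal(fit_a$aic, fit_b$aic, tolerance = 1e-12))
  structure(list(aic = aic, delta_aic = fit_a$aic - fit_b$aic,
                 selected = labs[if (tie) 1L else which.min(aic)],
                 tie = tie),
            class = "bef_cov_comparison")
}

#' @export
print.bef_cov_comparison <- function(x, ...) {
  cat("AIC: ", paste(sprintf("%s = %.2f", names(x$aic), x$aic),
                     collapse = ", "),
      "; selected: ", x$selected, if (x$tie) " (tie)", "\n", sep = "")
  invisible(x)
}

#' Fitted richness-response lines
#'
#' Predicts the response over a richness x treatment grid, either pooled
#' (fixed effects only) or per study (adding the best linear unbiased
#' predictions of the study-level random effects). Predictions are returned
#' on the transformed (square-root) scale together with the back-transformed
#' (squared) scale; interval bounds are computed on the transformed scale
#' only, where the model is linear.
#'
#' @param fit a converged [reml_fit()].
#' @param richness richness grid (default: the design's observed levels).
#' @param level `"pooled"` or `"per_study"`.
#' @return data.frame with `study_id` (`"(pooled)"` for pooled lines),
#'   `sown_richness`, `treatment`, `fit_sqrt`, `se_sqrt`, `lower_sqrt`,
#'   `upper_sqrt` (pooled only) and `fit_response` (squared).
#' @export
fitted_lines <- function(fit, richness = NULL,
                         level = c("pooled", "per_study")) {
  stopifnot(inherits(fit, "bef_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  level <- match.arg(level)
  design <- fit$design
  if (is.null(richness)) richness <- sort(unique(design$index$sown_richness))
  if (any(richness < 1)) stop("grid richness must be >= 1", call. = FALSE)
  tr_levels <- if (fit$spec$treatment_coding == "three_level") {
    c("control", "NPK", "NH4NO3")
  } else {
    c("control", "treated")
  }
  grid <- expand.grid(sown_richness = richness, treatment = tr_levels,
                      stringsAsFactors = FALSE)
  # covariate models predict at the reference covariate value (0 / short)
  grid$n_added <- 0
  grid$drought_class <- "short"
  fx <- .build_fixed(grid, fit$spec)
  est <- drop(fx$X %*% fit$beta_hat)
  if (level == "pooled") {
    se <- sqrt(rowSums((fx$X %*% fit$cov_beta) * fx$X))
    return(data.frame(study_id = "(pooled)", grid[c("sown_richness",
                                                    "treatment")],
                      fit_sqrt = est, se_sqrt = se,
                      lower_sqrt = est - 1.96 * se,
                      upper_sqrt = est + 1.96 * se,
                      fit_response = est^2,
                      stringsAsFactors = FALSE))
  }
  # per-study lines: add BLUPs of the study-level random terms
  winvr <- reml_winv_resid_cpp(design$blocks, fit$gamma,
                               if (is.na(fit$rho_hat)) 0 else fit$rho_hat,
                               design$corr, fit$beta_hat)
  study_terms <- c("study", "study_ln_richness", "study_treatment",
                   "study_ln_richness_treatment")
  out <- vector("list", length(design$studies))
  for (b in seq_along(design$studies)) {
    blk <- design$blocks[[b]]
    u <- stats::setNames(numeric(4), study_terms)
    for (k in seq_len(design$K)) {
      tm <- fit$spec$random_terms[k]
      if (tm %in% study_terms) {
        u[tm] <- fit$gamma[k] * sum(blk$rand[[k]]$a * winvr[[b]])
      }
    }
    lnN <- log(grid$sown_richness)
    tr <- as.numeric(grid$treatment != "control")
    pred <- est + u["study"] + u["study_ln_richness"] * lnN +
      u["study_treatment"] * tr + u["study_ln_richness_treatment"] * lnN * tr
    out[[b]] <- data.frame(study_id = design$studies[b],
                           grid[c("sown_richness", "treatment")],
                           fit_sqrt = pred, se_sqrt = NA_real_,
                           lower_sqrt = NA_real_, upper_sqrt = NA_real_,
                           fit_response = pred^2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.bef_fit <- function(x, ...) {
  cat("Linear mixed model fit by REML (", x$spec$response, "; residual ",
      x$spec$residual_correlation, ")\n", sep = "")
  cat("  n = ", x$n_obs, " plot-years, ", x$n_plots, " plots, ",
      x$n_studies, " studies; REML logLik ", sprintf("%.3f", x$reml_loglik),
      ", AIC(cov) ", sprintf("%.3f", x$aic),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("Fixed effects (95% CI, df: ", paste(unique(x$ddf_method),
                                           collapse = "+"), "):\n", sep = "")
  b <- x$beta
  b$estimate <- signif(b$estimate, 4)
  b$se <- signif(b$se, 3)
  b$df <- signif(b$df, 3)
  b$lower <- signif(b$lower, 4)
  b$upper <- signif(b$upper, 4)
  print(b, row.names = FALSE)
  cat("Variance components:\n")
  v <- x$vc
  v$estimate <- signif(v$estimate, 4)
  v$se <- signif(v$se, 3)
  v$z_ratio <- signif(v$z_ratio, 3)
  print(v, row.names = FALSE)
  if (!is.na(x$rho_hat)) {
    cat(sprintf("Residual correlation (%s): %.4f (se %.4f)\n",
                x$spec$residual_correlation, x$rho_hat, x$rho_se))
  }
  invisible(x)
}
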