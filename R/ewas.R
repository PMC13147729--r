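# Per-CpG linear modelling of M-values on age with covariates,
# empirical-Bayes variance moderation, and BH FDR control.

#' Fit per-probe linear models of M-values on age
#'
#' Ordinary least squares of each probe's M-values on the covariate design
#' (default `~ age + bmi + patient`). All probes share one design matrix, so
#' the fit is a single QR decomposition applied to the whole matrix.
#'
#' @param m probes x subjects M-value matrix.
#' @param covariates covariate `data.frame`, one row per subject, in beta
#'   column order.
#' @param formula model formula over covariate columns; must contain `age`.
#' @return a `probe_fits` data.frame with columns `probe_id`, `slope_age`
#'   (M per year), `sigma2` (residual variance), `df_residual`,
#'   `stdev_unscaled` (age-coefficient sd for unit residual sd), `t_ordinary`,
#'   `mean_m`, `mean_beta`; the design matrix is attached as an attribute.
#' @export
fit_probe_models <- function(m, covariates, formula = ~ age + bmi + patient) {
  if (!is.matrix(m)) stop2("`m` must be a probes x subjects matrix")
  if (ncol(m) != nrow(covariates)) {
    stop2("`covariates` must have one row per beta/M column")
  }
  X <- stats::model.matrix(formula, data = covariates)
  if (!"age" %in% colnames(X)) stop2("model formula must include `age`")
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop2("design matrix is rank deficient; collinear columns: ",
          paste(bad, collapse = ", "))
  }
  if (n <= p) stop2("need at least ", p + 1, " subjects for ", p, " parameters")

  coefs <- qr.coef(qrX, t(m))            # p x n_probes
  fitted <- X %*% coefs
  res <- t(m) - fitted
  df_residual <- n - p
  sigma2 <- colSums(res^2) / df_residual
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  stdev_unscaled <- sqrt(xtx_inv["age", "age"])
  slope <- coefs["age", ]
  se <- stdev_unscaled * sqrt(sigma2)
  t_ord <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf * sign(slope)))

  out <- data.frame(
    probe_id = rownames(m),
    slope_age = unname(slope),
    sigma2 = unname(sigma2),
    df_residual = df_residual,
    stdev_unscaled = stdev_unscaled,
    t_ordinary = unname(t_ord),
    mean_m = rowMeans(m),
    mean_beta = rowMeans(m_to_beta(m)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "design") <- X
  class(out) <- c("probe_fits", "data.frame")
  out
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks each probe's residual variance towards a common prior estimated
#' across all probes, following the scaled-inverse-chi-squared hierarchical
#' model behind the moderated t-statistic. The prior degrees of freedom
#' `d0` and prior variance `s0^2` are estimated by the method of moments on
#' log residual variances (matching the gamma-distribution moments of
#' log-chi-squared variables); the posterior variance is the convex
#' combination `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t uses
#' `d + d0` degrees of freedom.
#'
#' @param fits a `probe_fits` table from [fit_probe_models()].
#' @param prior_df optional forced prior degrees of freedom: `0` recovers
#'   the ordinary t-statistic, `Inf` gives complete shrinkage to `s0^2`.
#' @return list with `table` (fits plus `var_posterior`, `mod_t`, `p_raw`,
#'   `df_total`) and `prior` (`df_prior`, `var_prior`).
#' @export
moderate_statistics <- function(fits, prior_df = NULL) {
  s2 <- fits$sigma2
  d <- fits$df_residual
  if (length(s2) < 2) stop2("need at least 2 probes to estimate the prior")
  if (any(d <= 0)) stop2("all residual df must be positive")
  if (all(s2 == 0)) stop2("all residual variances are zero; variance prior is degenerate")

  s2f <- pmax(s2, 1e-12)  # floor exact zeros before taking logs
  z <- log(s2f)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))

  if (is.null(prior_df)) {
    if (is.finite(evar) && evar > 0) {
      df_prior <- 2 * trigamma_inverse(evar)
      var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    } else {
      df_prior <- Inf
      var_prior <- exp(emean)
    }
  } else {
    df_prior <- prior_df
    var_prior <- if (is.finite(df_prior) && df_prior > 0) {
      exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    } else {
      exp(emean)
    }
  }

  var_post <- if (is.infinite(df_prior)) {
    rep(var_prior, length(s2))
  } else {
    (df_prior * var_prior + d * s2) / (df_prior + d)
  }
  se <- fits$stdev_unscaled * sqrt(var_post)
  mod_t <- ifelse(se > 0, fits$slope_age / se,
                  ifelse(fits$slope_age == 0, 0, Inf * sign(fits$slope_age)))
  df_total <- d + df_prior
  p_raw <- 2 * stats::pt(-abs(mod_t), df = df_total)

  table <- fits
  table$var_posterior <- var_post
  table$mod_t <- mod_t
  table$df_total <- df_total
  table$p_raw <- p_raw
  list(table = table, prior = list(df_prior = df_prior, var_prior = var_prior))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1, order-preserving
#' with the input vector).
#'
#' @param p_raw vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
adjust_fdr <- function(p_raw) {
  if (!is.numeric(p_raw) || any(is.na(p_raw)) ||
      any(p_raw < 0) || any(p_raw > 1)) {
    stop2("`p_raw` must be p-values in [0, 1] with no missing values")
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Run the full per-CpG EWAS
#'
#' Convenience wrapper: probe filtering, beta-to-M transform, per-probe OLS,
#' empirical-Bayes moderation, BH correction, subgroup assignment and
#' intercept-method delta-beta back-transformation.
#'
#' @param dataset a `methylation_dataset`.
#' @param formula model formula (default `~ age + bmi + patient`).
#' @param alpha FDR significance threshold (default 0.05).
#' @param epsilon beta clipping guard for the M transform.
#' @param filter list of filter switches passed to [filter_probes()]
#'   (`detection`, `snp`, `crossreactive`); detection filtering only
#'   applies when the dataset carries a detection p matrix in
#'   `dataset$detp`.
#' @param prior_df optional forced prior df (see [moderate_statistics()]).
#' @return a `moderated_fit_table` data.frame with per-probe columns
#'   `probe_id`, `slope_m_per_year`, `mod_t`, `p_raw`, `p_adj`, `mean_m`,
#'   `mean_beta`, `significant`, `subgroup`, `delta_beta`; the filter
#'   report and shrinkage prior are attached as attributes.
#' @export
run_ewas <- function(dataset, formula = ~ age + bmi + patient, alpha = 0.05,
                     epsilon = 1e-6,
                     filter = list(detection = TRUE, snp = FALSE,
                                   crossreactive = FALSE),
                     prior_df = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop2("`alpha` must lie in (0, 1)")
  }
  flt <- filter_probes(dataset$beta, detp = dataset$detp,
                       annotation = dataset$annotation,
                       detection = isTRUE(filter$detection),
                       snp = isTRUE(filter$snp),
                       crossreactive = isTRUE(filter$crossreactive))
  m <- beta_to_m(flt$beta, epsilon = epsilon)
  fits <- fit_probe_models(m, dataset$covariates, formula = formula)
  mod <- moderate_statistics(fits, prior_df = prior_df)
  tab <- mod$table
  tab$p_adj <- adjust_fdr(tab$p_raw)
  tab$significant <- tab$p_adj < alpha
  tab$subgroup <- assign_subgroups(tab$mean_beta)
  tab$delta_beta <- delta_beta_from_m(tab$mean_m, tab$slope_age)
  names(tab)[names(tab) == "slope_age"] <- "slope_m_per_year"
  attr(tab, "filter_report") <- flt$report
  attr(tab, "prior") <- mod$prior
  attr(tab, "alpha") <- alpha
  class(tab) <- c("moderated_fit_table", "data.frame")
  tab
}

#' Global methylation tests
#'
#' Computes each subject's global mean beta (over all probes and within the
#' UM/HM/FM probe subsets), the Pearson correlation of global methylation
#' with age, and tie-corrected two-sided Mann-Whitney U tests across binary
#' strata (age above/below median, patient status, BMI >= 25).
#'
#' @param beta probes x subjects beta matrix.
#' @param covariates covariate table in beta column order.
#' @param labels optional per-probe subgroup labels (from
#'   [assign_subgroups()]); defaults to labels from probe mean betas.
#' @return list with `global_means` (per subject, per probe set) and
#'   `tests`, a `data.frame` of `probe_set`, `test`, `estimate`, `p_value`,
#'   `note`.
#' @export
global_methylation_tests <- function(beta, covariates, labels = NULL) {
  if (ncol(beta) < 3) stop2("need at least 3 subjects")
  if (is.null(labels)) labels <- assign_subgroups(rowMeans(beta))

  sets <- list(All = rep(TRUE, nrow(beta)),
               UM = labels == "UM", HM = labels == "HM", FM = labels == "FM")
  gm <- vapply(sets, function(keep) {
    if (!any(keep)) return(rep(NA_real_, ncol(beta)))
    colMeans(beta[keep, , drop = FALSE])
  }, numeric(ncol(beta)))
  global_means <- data.frame(subject_id = covariates$subject_id, gm,
                             stringsAsFactors = FALSE)

  strata <- list(
    age_above_median = covariates$age > stats::median(covariates$age),
    patient = covariates$patient == 1,
    overweight = covariates$bmi >= 25
  )
  rows <- list()
  for (set_name in names(sets)) {
    g <- gm[, set_name]
    if (all(is.na(g))) next
    if (stats::sd(g) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        probe_set = set_name, test = "pearson_age", estimate = NA_real_,
        p_value = NA_real_, note = "undefined: constant global means",
        stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(g, covariates$age, method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        probe_set = set_name, test = "pearson_age",
        estimate = unname(ct$estimate), p_value = ct$p.value, note = "",
        stringsAsFactors = FALSE)
    }
    for (str_name in names(strata)) {
      s <- strata[[str_name]]
      if (length(unique(s)) < 2) next
      # normal approximation with tie-corrected variance; no continuity
      # correction, so fully tied groups give p = 1 rather than < 1
      wt <- suppressWarnings(stats::wilcox.test(g[s], g[!s], exact = FALSE,
                                                correct = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        probe_set = set_name, test = paste0("mannwhitney_", str_name),
        estimate = unname(wt$statistic), p_value = wt$p.value, note = "",
        stringsAsFactors = FALSE)
    }
  }
  list(global_means = global_means, tests = do.call(rbind, rows))
}

#' Rerun the EWAS under a sensitivity scenario
#'
#' Supported scenarios: `drop_outliers` (remove subjects whose global mean
#' beta is more than 3 MAD from the median), `drop_patients`,
#' `drop_snp_probes`, `drop_crossreactive`, `add_covariate` (extend the
#' model formula with `extra`, e.g. `"sperm_quality"`). The scenario table
#' is compared with the main analysis by slope sign agreement and Spearman
#' rank correlation over shared probes.
#'
#' @param dataset a `methylation_dataset`.
#' @param scenario one of the scenario names above.
#' @param main optional main-analysis `moderated_fit_table` (computed with
#'   defaults if omitted).
#' @param extra covariate name for `add_covariate`.
#' @param mad_k MAD multiplier for the outlier rule (default 3).
#' @param ... passed to [run_ewas()].
#' @return list with `table` (scenario refit), `comparison`
#'   (`n_common`, `sign_agreement`, `spearman_rho`) and `scenario`.
#' @export
sensitivity_rerun <- function(dataset, scenario, main = NULL, extra = NULL,
                              mad_k = 3, ...) {
  scenario <- match.arg(scenario,
                        c("drop_outliers", "drop_patients", "drop_snp_probes",
                          "drop_crossreactive", "add_covariate"))
  if (is.null(main)) main <- run_ewas(dataset, ...)
  ds <- dataset
  args <- list(...)

  if (scenario == "drop_outliers") {
    g <- colMeans(ds$beta)
    dev <- abs(g - stats::median(g))
    keep <- dev <= mad_k * stats::mad(g)
    ds$beta <- ds$beta[, keep, drop = FALSE]
    ds$covariates <- ds$covariates[keep, , drop = FALSE]
    if (!is.null(ds$detp)) ds$detp <- ds$detp[, keep, drop = FALSE]
  } else if (scenario == "drop_patients") {
    keep <- ds$covariates$patient == 0
    ds$beta <- ds$beta[, keep, drop = FALSE]
    ds$covariates <- ds$covariates[keep, , drop = FALSE]
    if (!is.null(ds$detp)) ds$detp <- ds$detp[, keep, drop = FALSE]
    # patient status is constant in the non-patient subset
    base <- args$formula %||% (~ age + bmi + patient)
    args$formula <- stats::update(base, ~ . - patient)
  } else if (scenario == "drop_snp_probes") {
    args$filter <- utils::modifyList(args$filter %||% list(detection = TRUE),
                                     list(snp = TRUE))
  } else if (scenario == "drop_crossreactive") {
    args$filter <- utils::modifyList(args$filter %||% list(detection = TRUE),
                                     list(crossreactive = TRUE))
  } else if (scenario == "add_covariate") {
    if (is.null(extra)) stop2("`extra` covariate name required for add_covariate")
    base <- args$formula %||% (~ age + bmi + patient)
    args$formula <- stats::update(base, paste("~ . +", extra))
  }

  formula_used <- args$formula %||% (~ age + bmi + patient)
  p_needed <- ncol(stats::model.matrix(formula_used, ds$covariates)) + 1
  if (nrow(ds$covariates) < p_needed) {
    stop2("infeasible scenario `", scenario, "`: only ", nrow(ds$covariates),
          " subjects remain, need at least ", p_needed)
  }

  tab <- do.call(run_ewas, c(list(dataset = ds), args))
  common <- intersect(tab$probe_id, main$probe_id)
  s_new <- tab$slope_m_per_year[match(common, tab$probe_id)]
  s_old <- main$slope_m_per_year[match(common, main$probe_id)]
  comparison <- data.frame(
    n_common = length(common),
    sign_agreement = mean(sign(s_new) == sign(s_old)),
    spearman_rho = suppressWarnings(
      stats::cor(s_new, s_old, method = "spearman"))
  )
  list(table = tab, comparison = comparison, scenario = scenario)
}
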