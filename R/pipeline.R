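#' ANCOVA of the final-visit outcome
#'
#' Least-squares fit of the final-visit outcome on the randomised-arm
#' indicator and baseline (the minimal treatment-policy analysis model).
#' Returns the treatment coefficient and its sampling variance.
#'
#' @param completed a completed [trial_data] object (no missing final-visit
#'   values).
#' @param extra_covariates optional data frame of additional per-patient
#'   analysis covariates.
#' @return list with `estimate`, `variance`, `df` (residual degrees of
#'   freedom of the complete-data fit).
#' @export
ancova_final_visit <- function(completed, extra_covariates = NULL) {
  stopifnot(inherits(completed, "trial_data"))
  J <- completed$n_visits
  y <- completed$outcomes[, J]
  if (anyNA(y)) stop("final-visit outcomes must be complete for ANCOVA")
  if (stats::var(completed$baseline) == 0)
    stop("baseline is constant: ANCOVA adjustment is collinear")
  df <- data.frame(y = y, arm = completed$arm, baseline = completed$baseline)
  if (!is.null(extra_covariates)) df <- cbind(df, extra_covariates)
  fit <- stats::lm(y ~ ., data = df)
  list(estimate = unname(stats::coef(fit)["arm"]),
       variance = unname(stats::vcov(fit)["arm", "arm"]),
       df = fit$df.residual)
}

#' Pool multiple-imputation results by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; the
#' pooled variance is `W + (1 + 1/K) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance. Degrees of freedom use
#' the Barnard-Rubin small-sample adjustment against the complete-data
#' degrees of freedom.
#'
#' @param estimates length-`K` vector of per-imputation estimates.
#' @param variances length-`K` vector of per-imputation sampling variances.
#' @param complete_data_df complete-data degrees of freedom (e.g. `n - 3`
#'   from the ANCOVA).
#' @param conf confidence level.
#' @return list with `estimate`, `se`, `df`, `ci`, `p`, `W`, `B`, `K`,
#'   `mcse` (Monte Carlo SE of the pooled estimate, `sqrt(B/K)`).
#' @export
pool_rubin <- function(estimates, variances, complete_data_df = Inf,
                       conf = 0.95) {
  K <- length(estimates)
  if (K < 2L) stop("Rubin's rules need at least 2 imputations")
  if (length(variances) != K) stop("estimates and variances differ in length")
  if (any(variances <= 0)) stop("non-positive within-imputation variance")
  Q <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / K) * B
  lam <- (1 + 1 / K) * B / Tv
  if (lam > 0) {
    nu_old <- (K - 1) / lam^2
    nu <- if (is.finite(complete_data_df)) {
      nu_obs <- (complete_data_df + 1) / (complete_data_df + 3) *
        complete_data_df * (1 - lam)
      1 / (1 / nu_old + 1 / nu_obs)
    } else nu_old
  } else {
    nu <- if (is.finite(complete_data_df)) complete_data_df else Inf
  }
  se <- sqrt(Tv)
  tq <- stats::qt(1 - (1 - conf) / 2, df = nu)
  list(estimate = Q, se = se, df = nu,
       ci = c(Q - tq * se, Q + tq * se),
       p = 2 * stats::pt(-abs(Q / se), df = nu),
       W = W, B = B, K = K, mcse = sqrt(B / K))
}

mi_result <- function(pooled, per_imp, config) {
  structure(c(pooled, list(estimates = per_imp$estimates,
                           variances = per_imp$variances,
                           config = config)),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI treatment-policy difference: %.3f (SE %.3f), K = %d\n",
              x$estimate, x$se, x$K))
  cat(sprintf("  95%% CI [%.3f, %.3f], df = %.1f, p = %.4g, MC-SE %.4f\n",
              x$ci[1L], x$ci[2L], x$df, x$p, x$mcse))
  if (!is.null(x$config$never_observed) && length(x$config$never_observed))
    cat("  never-observed deviation coefficients (posterior = prior):",
        paste(x$config$never_observed, collapse = ", "), "\n")
  invisible(x)
}

analyse_and_pool <- function(completed, conf = 0.95) {
  res <- lapply(completed, ancova_final_visit)
  est <- vapply(res, `[[`, numeric(1), "estimate")
  vv <- vapply(res, `[[`, numeric(1), "variance")
  pooled <- pool_rubin(est, vv, complete_data_df = res[[1L]]$df, conf = conf)
  list(pooled = pooled, estimates = est, variances = vv)
}

#' Retrieved dropout reference-base centred multiple imputation
#'
#' Runs the full pipeline: verify that the core model is nested in the
#' compliance model, build the extended design (core block + deviation
#' block + baseline block) and its priors, fit the Bayesian
#' repeated-measures multivariate normal model by Gibbs sampling, form `K`
#' completed datasets from the stored missing-cell draws (observed values
#' preserved exactly), analyse each by final-visit ANCOVA and pool with
#' Rubin's rules.
#'
#' @param data a [trial_data] object.
#' @param core a [core_spec].
#' @param compliance a [compliance_spec].
#' @param v deviation-prior variance; `NULL` uses
#'   [default_prior_variance()] with the `mmrm_residual` route.
#' @param adjacent_corr prior correlation between visit-adjacent deviation
#'   coefficients.
#' @param diffuse_variance core-prior variance (default `1e6` times the
#'   sample variance of the observed outcomes).
#' @param gibbs a [gibbs_config]; its `n_draws` is the number of
#'   imputations `K`.
#' @param baseline_interaction cross baseline-by-visit with arm.
#' @param pin_deviation structurally pin all deviation coefficients at
#'   zero (drops their columns): the classic reference-based limit of the
#'   method.
#' @param include_off_treatment keep observed off-treatment outcomes in
#'   the likelihood (default). `FALSE` masks them so the fit uses
#'   on-treatment data only and every post-deviation cell is analysed as
#'   imputed, as in classic reference-based imputation (combine with
#'   `pin_deviation = TRUE` to reproduce it exactly).
#' @return an object of class `mi_result`; `$config` echoes the choices,
#'   the never-observed deviation cells, the seed, and posterior summaries
#'   of the deviation coefficients.
#' @export
run_rdrbc_mi <- function(data, core = core_spec("J2R"),
                         compliance = compliance_spec("historic"),
                         v = NULL, adjacent_corr = 0, diffuse_variance = NULL,
                         gibbs = gibbs_config(), baseline_interaction = TRUE,
                         pin_deviation = FALSE, include_off_treatment = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  fit_data <- data
  if (!include_off_treatment) fit_data <- mask_off_treatment(data)
  design <- build_design(fit_data, core, compliance, baseline_interaction)
  if (pin_deviation) design <- drop_design_columns(design, "deviation")
  if (is.null(v)) v <- default_prior_variance(data)
  priors <- build_priors(design, v = v, diffuse_variance = diffuse_variance,
                         adjacent_corr = adjacent_corr,
                         scale_hint = stats::var(as.vector(data$outcomes),
                                                 na.rm = TRUE))
  draws <- gibbs_fit_impute(fit_data, design, priors, gibbs)
  # with off-treatment rows excluded, post-deviation cells are analysed as
  # imputed (the classic reference-based limit); observed values at the
  # cells that entered the likelihood are always preserved exactly
  completed <- completed_datasets(draws, fit_data)
  out <- analyse_and_pool(completed)
  dev_i <- which(draws$coef$type == "deviation")
  dev_summary <- if (length(dev_i)) {
    data.frame(name = draws$coef$name[dev_i],
               post_mean = colMeans(draws$beta[, dev_i, drop = FALSE]),
               post_var = apply(draws$beta[, dev_i, drop = FALSE], 2L,
                                stats::var),
               row.names = NULL)
  } else NULL
  mi_result(out$pooled, out,
            config = list(core = core$kind, compliance = compliance$kind,
                          v = v, adjacent_corr = adjacent_corr,
                          seed = gibbs$seed, K = gibbs$n_draws,
                          pin_deviation = pin_deviation,
                          include_off_treatment = include_off_treatment,
                          never_observed = draws$never_observed,
                          deviation_posterior = dev_summary))
}

mask_off_treatment <- function(data) {
  J <- data$n_visits
  off <- outer(data$deviation_visit, seq_len(J), `<`)
  data$outcomes[off] <- NA_real_
  data
}

#' Classic reference-based multiple imputation comparator
#'
#' Fits the core reference-based model with no deviation block. With
#' `use_off_treatment_data = FALSE` (the classic method) the observed
#' off-treatment outcomes are excluded from the likelihood and every
#' post-deviation cell is imputed from the core model; with `merge_back`
#' the observed off-treatment values then overwrite their imputations
#' before analysis.
#'
#' @param data a [trial_data] object.
#' @param core a [core_spec] with kind `J2R`, `CIR` or `CR` (others are
#'   accepted but are not classic reference-based choices).
#' @param use_off_treatment_data keep observed off-treatment rows in the
#'   likelihood.
#' @param merge_back overwrite imputed cells with observed off-treatment
#'   values where available.
#' @param v,gibbs,baseline_interaction as in [run_rdrbc_mi] (`v` is unused
#'   here beyond the covariance prior scale since there is no deviation
#'   block).
#' @return an object of class `mi_result`.
#' @export
run_classic_rbi <- function(data, core = core_spec("J2R"),
                            use_off_treatment_data = FALSE, merge_back = FALSE,
                            gibbs = gibbs_config(), baseline_interaction = TRUE,
                            v = NULL) {
  stopifnot(inherits(data, "trial_data"))
  fit_data <- if (use_off_treatment_data) data else mask_off_treatment(data)
  design <- build_design(fit_data, core, compliance = NULL,
                         baseline_interaction = baseline_interaction)
  priors <- build_priors(design, v = 1, # no deviation columns: v is inert
                         scale_hint = stats::var(as.vector(data$outcomes),
                                                 na.rm = TRUE))
  draws <- gibbs_fit_impute(fit_data, design, priors, gibbs)
  completed <- completed_datasets(draws, fit_data)
  if (merge_back) {
    completed <- lapply(completed, merge_observed_off_treatment,
                        original = data)
  } else if (!use_off_treatment_data) {
    # imputations replace the off-treatment observations; pre-deviation
    # observed data are untouched by construction
    completed <- completed
  }
  out <- analyse_and_pool(completed)
  mi_result(out$pooled, out,
            config = list(core = core$kind, compliance = "none (classic RBI)",
                          use_off_treatment_data = use_off_treatment_data,
                          merge_back = merge_back, seed = gibbs$seed,
                          K = gibbs$n_draws, never_observed = character(0)))
}

#' Run a grid of prior variances and methods
#'
#' Convenience wrapper producing a long table of pooled estimates and
#' standard errors over methods (classic reference-based with and without
#' merge-back, and the centred extended model over a grid of prior
#' variances), one row per cell.
#'
#' @param data a [trial_data] object.
#' @param cores named list of [core_spec] objects to use for the extended
#'   model rows.
#' @param compliances list of [compliance_spec] objects.
#' @param v_grid numeric vector of deviation-prior variances.
#' @param gibbs a [gibbs_config].
#' @param classic include the two classic J2R comparator rows.
#' @return data frame with columns `method`, `core`, `compliance`, `v`,
#'   `estimate`, `se`.
#' @export
compare_methods <- function(data, cores = list(J2R = core_spec("J2R")),
                            compliances = list(compliance_spec("historic")),
                            v_grid = c(1, 10, 40, 160, 1000),
                            gibbs = gibbs_config(), classic = TRUE) {
  rows <- list()
  if (classic) {
    for (mb in c(FALSE, TRUE)) {
      r <- run_classic_rbi(data, core_spec("J2R"), merge_back = mb,
                           gibbs = gibbs)
      rows[[length(rows) + 1L]] <- data.frame(
        method = if (mb) "J2R + observed off-treatment" else "J2R only",
        core = "J2R", compliance = NA_character_, v = NA_real_,
        estimate = r$estimate, se = r$se)
    }
  }
  for (cn in names(cores)) for (cm in compliances) {
    if (!check_nesting(cores[[cn]], cm, data$n_visits)$ok) next
    for (v in v_grid) {
      r <- run_rdrbc_mi(data, cores[[cn]], cm, v = v, gibbs = gibbs)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "RD-RBC", core = cn, compliance = cm$kind, v = v,
        estimate = r$estimate, se = r$se)
    }
  }
  do.call(rbind, rows)
}
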