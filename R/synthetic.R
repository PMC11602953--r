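#' Configuration for the synthetic trial generator
#'
#' Describes a two-arm longitudinal trial with `J` post-baseline visits:
#' on-treatment mean profiles, a baseline covariate with per-visit effect,
#' an unstructured residual covariance, a per-arm-and-visit deviation
#' hazard, a per-arm probability of stopping observation at deviation
#' (versus being followed to the end off treatment), and an off-treatment
#' mean rule stating what deviators' outcomes actually do (the generating
#' truth): jump to the reference profile (`j2r_truth`), track parallel to
#' it (`cir_truth`), stay at the on-treatment profile (`mar_truth`), or a
#' custom per-arm deviation table `gamma` added to the reference profile.
#'
#' @param n_per_arm length-2 integer vector (reference, active).
#' @param J number of post-baseline visits.
#' @param mu 2 by `J` matrix of on-treatment means (reference row first),
#'   at baseline equal to its mean.
#' @param Sigma `J` by `J` positive-definite residual covariance.
#' @param dev_hazard 2 by `J-1` matrix: probability of deviating directly
#'   after visit `j` given still on treatment (deviation completely at
#'   random by default).
#' @param q_stop length-2 probability that a deviator stops observation
#'   immediately (otherwise observed to the end off treatment).
#' @param off_rule one of `"j2r_truth"`, `"cir_truth"`, `"mar_truth"`,
#'   `"custom"`.
#' @param gamma for `off_rule = "custom"`: 2 by `J` matrix added to the
#'   reference on-treatment means for off-treatment cells.
#' @param baseline_mean,baseline_sd baseline covariate distribution.
#' @param baseline_coef length-`J` effect of (baseline - baseline_mean) on
#'   the outcome at each visit.
#' @param dnar_coef deviation-not-at-random toggle: logistic shift of the
#'   hazard per unit of the current outcome's deviation from its mean
#'   (0 = deviation completely at random, the setting the analytic module
#'   assumes).
#' @param partial_followup probability that a continuing deviator leaves
#'   the study early anyway at a uniform visit between `D` and `J`
#'   (0 = the all-or-nothing stop/continue layout of the motivating data).
#' @param perforate list of `c(arm, k)` pairs (arm 0/1, deviation visit):
#'   strata forced to have no observed off-treatment data.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_arm = c(88L, 84L), J = 4L,
                             mu = rbind(-(1:4), -2 * (1:4)),
                             Sigma = default_sigma(J),
                             dev_hazard = rbind(c(0.08, 0.062, 0.145),
                                                c(0.071, 0.064, 0.123)),
                             q_stop = c(0.5, 0.5),
                             off_rule = c("j2r_truth", "cir_truth",
                                          "mar_truth", "custom"),
                             gamma = NULL,
                             baseline_mean = 18, baseline_sd = 4,
                             baseline_coef = rep(-0.2, J),
                             dnar_coef = 0, partial_followup = 0,
                             perforate = list()) {
  off_rule <- match.arg(off_rule)
  mu <- as.matrix(mu)
  stopifnot(nrow(mu) == 2L, ncol(mu) == J, nrow(Sigma) == J,
            all(dev_hazard >= 0), all(dev_hazard <= 1),
            all(q_stop >= 0), all(q_stop <= 1),
            length(baseline_coef) == J)
  chol(Sigma)  # errors if not positive definite
  if (off_rule == "custom") {
    if (is.null(gamma)) stop("off_rule = 'custom' needs a gamma table")
    gamma <- as.matrix(gamma)
    stopifnot(nrow(gamma) == 2L, ncol(gamma) == J)
  }
  dev_hazard <- as.matrix(dev_hazard)
  stopifnot(nrow(dev_hazard) == 2L, ncol(dev_hazard) == J - 1L)
  for (pf in perforate)
    if (!(pf[1L] %in% 0:1) || pf[2L] < 1L || pf[2L] > J - 1L)
      stop("perforation stratum out of range")
  structure(list(n_per_arm = as.integer(n_per_arm), J = as.integer(J),
                 mu = mu, Sigma = Sigma, dev_hazard = dev_hazard,
                 q_stop = q_stop, off_rule = off_rule, gamma = gamma,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 baseline_coef = baseline_coef, dnar_coef = dnar_coef,
                 partial_followup = partial_followup, perforate = perforate),
            class = "synthetic_config")
}

#' Default residual covariance for the generator: variances growing over
#' follow-up to about 40 at the final of 4 visits, exchangeable-plus-decay
#' correlation around 0.55.
#' @param J number of visits.
#' @return `J` by `J` covariance matrix.
#' @export
default_sigma <- function(J = 4L) {
  sds <- sqrt(seq(16, 40, length.out = J))
  R <- 0.55^abs(outer(seq_len(J), seq_len(J), `-`))^0.7
  diag(R) <- 1
  diag(sds) %*% R %*% diag(sds)
}

off_mean_row <- function(cfg, t, k) {
  # true mean profile at visits k+1..J for a deviator after visit k
  J <- cfg$J
  j <- (k + 1L):J
  switch(cfg$off_rule,
    j2r_truth = cfg$mu[1L, j],
    cir_truth = cfg$mu[1L, j] + cfg$mu[t + 1L, k] - cfg$mu[1L, k],
    mar_truth = cfg$mu[t + 1L, j],
    custom = cfg$mu[1L, j] + cfg$gamma[t + 1L, j])
}

#' Generate a synthetic trial
#'
#' Draws full multivariate-normal outcome trajectories whose mean follows
#' the on-treatment profile up to the deviation visit and the configured
#' off-treatment rule after it, assigns the deviation visit by the hazard
#' process (independent of the residuals unless `dnar_coef` is nonzero,
#' in which case the hazard shifts with the current outcome), sets the
#' last study visit by the stop/continue draw, masks outcomes after it,
#' and applies any perforation. The generating parameters and the
#' pre-masking complete outcomes are returned alongside the data so tests
#' never re-derive the truth from the realisation.
#'
#' @param cfg a [synthetic_config].
#' @param seed RNG seed.
#' @return list with `data` (a [trial_data]), `truth` (list: `config`,
#'   `complete_outcomes`, `te_true` — the exact treatment-policy contrast
#'   at the final visit implied by the configuration, available in closed
#'   form when `dnar_coef = 0`).
#' @export
generate_trial <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  J <- cfg$J
  N <- sum(cfg$n_per_arm)
  arm <- rep(0:1, cfg$n_per_arm)
  baseline <- stats::rnorm(N, cfg$baseline_mean, cfg$baseline_sd)
  bl_eff <- outer(baseline - cfg$baseline_mean, cfg$baseline_coef)
  E <- MASS::mvrnorm(N, rep(0, J), cfg$Sigma)

  D <- rep(J, N)
  Y <- matrix(NA_real_, N, J)
  on_mu <- cfg$mu[arm + 1L, , drop = FALSE]
  for (j in seq_len(J)) {
    mean_j <- ifelse(D >= j, on_mu[, j],
                     vapply(seq_len(N), function(i)
                       if (D[i] < j) off_mean_row(cfg, arm[i], D[i])[j - D[i]]
                       else on_mu[i, j], numeric(1)))
    Y[, j] <- mean_j + bl_eff[, j] + E[, j]
    if (j < J) {
      still_on <- D >= j + 1L  # == J placeholder; deviation not yet decided
      h <- cfg$dev_hazard[arm + 1L, j]
      if (cfg$dnar_coef != 0) {
        h <- stats::plogis(stats::qlogis(pmin(pmax(h, 1e-8), 1 - 1e-8)) +
                             cfg$dnar_coef * (Y[, j] - on_mu[, j] - bl_eff[, j]))
      }
      dev_now <- still_on & D == J & stats::runif(N) < h
      D[dev_now] <- j
    }
  }

  S <- rep(J, N)
  deviator <- D < J
  stopv <- deviator & stats::runif(N) < cfg$q_stop[arm + 1L]
  S[stopv] <- D[stopv]
  if (cfg$partial_followup > 0) {
    cont <- deviator & !stopv
    part <- cont & stats::runif(N) < cfg$partial_followup
    S[part] <- vapply(which(part), function(i)
      sample(D[i]:J, 1L), integer(1))
  }

  obs <- Y
  obs[outer(S, seq_len(J), `<`)] <- NA_real_
  data <- trial_data(obs, arm, baseline, deviation_visit = D,
                     last_study_visit = S)
  for (pf in cfg$perforate) {
    sel <- data$arm == pf[1L] & data$deviation_visit == pf[2L]
    if (!any(sel)) stop("infeasible perforation: empty stratum (arm ",
                        pf[1L], ", deviation visit ", pf[2L], ")")
    data <- make_perforated(data, list(pf))
  }
  truth <- list(config = cfg, complete_outcomes = Y, seed = seed,
                te_true = if (cfg$dnar_coef == 0) te_true_config(cfg) else NA_real_)
  list(data = data, truth = truth)
}

te_true_config <- function(cfg) {
  # exact treatment-policy contrast at the final visit under the hazard
  # process (deviation independent of residuals)
  J <- cfg$J
  armmean <- function(t) {
    h <- cfg$dev_hazard[t + 1L, ]
    pD <- numeric(J)
    surv <- 1
    for (k in seq_len(J - 1L)) {
      pD[k] <- surv * h[k]
      surv <- surv * (1 - h[k])
    }
    pD[J] <- surv
    mJ <- c(vapply(seq_len(J - 1L), function(k)
      off_mean_row(cfg, t, k)[J - k], numeric(1)), cfg$mu[t + 1L, J])
    sum(pD * mJ)
  }
  armmean(1L) - armmean(0L)
}

#' Force a perforated layout
#'
#' Sets `S = D` for every patient in the listed (arm, deviation-visit)
#' strata, deleting their observed off-treatment outcomes, so the stratum
#' has off-treatment missingness but no observed off-treatment data — the
#' "hole" that makes the corresponding compliance-model parameters
#' non-estimable.
#'
#' @param data a [trial_data] object.
#' @param strata list of `c(arm, k)` pairs.
#' @return a [trial_data] object; idempotent.
#' @export
make_perforated <- function(data, strata) {
  stopifnot(inherits(data, "trial_data"))
  J <- data$n_visits
  for (pf in strata) {
    sel <- data$arm == pf[1L] & data$deviation_visit == pf[2L]
    if (!any(sel)) stop("stratum (arm ", pf[1L], ", deviation visit ",
                        pf[2L], ") is empty")
    data$last_study_visit[sel] <- data$deviation_visit[sel]
    mask <- outer(data$last_study_visit, seq_len(J), `<`) & sel
    data$outcomes[mask] <- NA_real_
  }
  data
}

#' Named scenario presets
#'
#' The four single-visit data-generation scenarios used by the analytic
#' bias/RMSE investigation (all with `n = 100` per arm, 40% deviation,
#' 50% missingness given deviation, unit residual variance), plus
#' `example_trial`, a longitudinal configuration emulating the structure
#' of the antidepressant example data distributed by the DIA missing-data
#' working group: `J = 4` visits, 88 reference and 84 active patients,
#' deviation hazards calibrated to its covered layout, all-or-nothing
#' stop/continue with probability one half.
#'
#' Means `(mu_off_0, mu_on_0, mu_off_1, mu_on_1)` per scenario:
#' `no_effect_dcar` (1,1,1,1); `no_effect_dnar` (1,2,1,2); `j2r` (1,1,1,2);
#' `effect_dcar` (1,1,2,2). The gammas follow from
#' `gamma_t = mu_off_t - mu_on_0`.
#'
#' @param name one of `"no_effect_dcar"`, `"no_effect_dnar"`, `"j2r"`,
#'   `"effect_dcar"`, `"example_trial"`.
#' @return a [simple_scenario] or, for `example_trial`, a
#'   [synthetic_config].
#' @export
scenario_preset <- function(name = c("no_effect_dcar", "no_effect_dnar",
                                     "j2r", "effect_dcar", "example_trial")) {
  name <- match.arg(name)
  if (name == "example_trial") return(synthetic_config())
  m <- switch(name,
    no_effect_dcar = c(1, 1, 1, 1),
    no_effect_dnar = c(1, 2, 1, 2),
    j2r = c(1, 1, 1, 2),
    effect_dcar = c(1, 1, 2, 2))
  simple_scenario(n_per_arm = 100L, p0 = 0.4, p1 = 0.4, q0 = 0.5, q1 = 0.5,
                  mu_off_0 = m[1L], mu_on_0 = m[2L],
                  mu_off_1 = m[3L], mu_on_1 = m[4L], sigma2 = 1)
}
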