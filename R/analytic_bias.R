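#' One-visit two-arm scenario for the exact bias/RMSE calculator
#'
#' In the single-visit setting each arm splits into three groups: observed
#' on-treatment, observed off-treatment and missing (off-treatment,
#' unobserved). Outcomes are normal with variance `sigma2` and group means
#' `mu_on_t` / `mu_off_t`; the missing group shares the off-treatment mean
#' (the missingness process is at random given deviation). The deviations
#' of the off-treatment means from the reference on-treatment mean,
#' `gamma_t = mu_off_t - mu_on_0`, are the parameters the centred method
#' shrinks toward zero with prior relative precision `rho` (prior variance
#' `sigma2 / rho`): in this setting the J2R, CR and CIR cores coincide and
#' all say `gamma_t = 0`.
#'
#' @param n_per_arm patients per arm.
#' @param p0,p1 deviation probabilities (reference, active).
#' @param q0,q1 probability of missingness given deviation.
#' @param mu_on_0,mu_off_0,mu_on_1,mu_off_1 group means (outcome units).
#' @param sigma2 residual variance (the calculator treats it as known).
#' @return object of class `simple_scenario`; `gamma0`/`gamma1` are
#'   derived from the means.
#' @export
simple_scenario <- function(n_per_arm = 100L, p0 = 0.4, p1 = 0.4,
                            q0 = 0.5, q1 = 0.5,
                            mu_on_0 = 1, mu_off_0 = 1,
                            mu_on_1 = 1, mu_off_1 = 1, sigma2 = 1) {
  stopifnot(n_per_arm >= 1, p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1,
            q0 >= 0, q0 <= 1, q1 >= 0, q1 <= 1, sigma2 > 0)
  structure(list(n_per_arm = as.integer(n_per_arm), p0 = p0, p1 = p1,
                 q0 = q0, q1 = q1,
                 mu_on_0 = mu_on_0, mu_off_0 = mu_off_0,
                 mu_on_1 = mu_on_1, mu_off_1 = mu_off_1,
                 gamma0 = mu_off_0 - mu_on_0, gamma1 = mu_off_1 - mu_on_0,
                 sigma2 = sigma2),
            class = "simple_scenario")
}

#' True treatment-policy contrast in the simple setting
#'
#' The expected outcome difference between arms under the treatment-policy
#' strategy: each arm mean mixes the on-treatment mean (weight `1 - p`)
#' and the off-treatment mean (weight `p`; the missing group shares it).
#'
#' @param s a [simple_scenario].
#' @return scalar contrast.
#' @export
te_real <- function(s) {
  stopifnot(inherits(s, "simple_scenario"))
  ((1 - s$p1) * s$mu_on_1 + s$p1 * s$mu_off_1) -
    ((1 - s$p0) * s$mu_on_0 + s$p0 * s$mu_off_0)
}

# Infinite-imputation point estimate as a linear functional of the four
# group sample means. Vectorised over patterns: all count arguments may be
# vectors. Posterior for (mu_on_0, gamma0, gamma1) under flat prior on the
# reference mean and N(0, sigma2/rho) priors on the gammas; `joint`
# estimates the reference mean jointly from all three informative groups,
# `plugin` conditions the shrinkage on the on-treatment reference mean
# alone. Returns weights on (ybar_on0, ybar_off0, ybar_on1, ybar_off1).
estimator_weights <- function(a, b, c_, n_on1, n_miss0, n_miss1, n, rho,
                              method = c("joint", "plugin")) {
  method <- match.arg(method)
  # shrinkage fractions; with rho = 0 and no off-treatment data the gamma
  # posterior is taken at the prior centre (weight 0)
  db <- b + rho
  dc <- c_ + rho
  f0 <- b / pmax(db, .Machine$double.xmin) * (db > 0)
  f1 <- c_ / pmax(dc, .Machine$double.xmin) * (dc > 0)
  if (method == "joint") {
    bs <- rho * f0
    cs <- rho * f1
    s <- a + bs + cs
    inv_s <- (s > 0) / pmax(s, .Machine$double.xmin)
    w0_on0 <- a * inv_s
    w0_off0 <- bs * inv_s
    w0_off1 <- cs * inv_s
  } else {
    w0_on0 <- as.numeric(a > 0)  # reference mean from its own arm only
    w0_off0 <- 0 * a
    w0_off1 <- 0 * a
  }
  # mu_miss_t = (1 - f_t) * mu0_hat + f_t * ybar_off_t
  dA <- (n_miss1 * (1 - f1) - n_miss0 * (1 - f0)) / n
  cbind(on0 = dA * w0_on0 - a / n,
        off0 = dA * w0_off0 - (b + n_miss0 * f0) / n,
        on1 = n_on1 / n,
        off1 = dA * w0_off1 + (c_ + n_miss1 * f1) / n)
}

#' Exact conditional bias and MSE given the deviation/missingness counts
#'
#' Conditional on the per-arm counts (observed on-treatment, observed
#' off-treatment, missing), the infinite-imputation point estimate is a
#' linear function of the independent Gaussian group means, so its bias
#' and mean squared error about the true treatment-policy contrast are
#' available in closed form.
#'
#' @param counts0,counts1 lists/vectors with elements `n_on`,
#'   `n_off_observed`, `n_miss` summing to `n_per_arm`, for the reference
#'   and active arm.
#' @param s a [simple_scenario].
#' @param rho prior precision relative to residual precision.
#' @param method `"joint"` (default) or `"plugin"` reference-mean
#'   handling, see Details of [bias_rmse].
#' @return list with `bias`, `mse`, `variance`.
#' @export
conditional_moments <- function(counts0, counts1, s, rho,
                                method = c("joint", "plugin")) {
  stopifnot(inherits(s, "simple_scenario"))
  cn <- function(cc) {
    cc <- as.list(cc)
    stopifnot(cc$n_on + cc$n_off_observed + cc$n_miss == s$n_per_arm)
    cc
  }
  c0 <- cn(counts0); c1 <- cn(counts1)
  W <- estimator_weights(a = c0$n_on, b = c0$n_off_observed,
                         c_ = c1$n_off_observed, n_on1 = c1$n_on,
                         n_miss0 = c0$n_miss, n_miss1 = c1$n_miss,
                         n = s$n_per_arm, rho = rho, method = method)
  mu <- c(s$mu_on_0, s$mu_off_0, s$mu_on_1, s$mu_off_1)
  bias <- drop(W %*% mu) - te_real(s)
  ng <- c(c0$n_on, c0$n_off_observed, c1$n_on, c1$n_off_observed)
  variance <- sum(ifelse(ng > 0, W[1, ]^2 * s$sigma2 / pmax(ng, 1), 0))
  list(bias = bias, mse = bias^2 + variance, variance = variance)
}

arm_pattern_table <- function(n, p, q, tail_tol = 1e-13) {
  nd <- rep(0:n, times = 0:n + 1L)
  nm <- sequence(0:n + 1L) - 1L
  pr <- stats::dbinom(nd, n, p) * stats::dbinom(nm, nd, q)
  keep <- pr > tail_tol
  data.frame(n_dev = nd[keep], n_miss = nm[keep], prob = pr[keep])
}

#' Exact marginal bias and RMSE of the centred estimator
#'
#' Averages the conditional moments over the joint distribution of the
#' deviation and missingness counts — per arm, deviators are
#' `Binomial(n, p)` and the missing among them `Binomial(n_dev, q)`,
#' independently across arms — by full enumeration of the binomial pmf
#' (patterns of joint probability below `tail_tol` are dropped; total mass
#' lost is far below double precision at the default). The point estimate
#' is the infinite-imputation limit of the centred method with prior
#' relative precision `rho`; `method = "joint"` (default) estimates the
#' reference on-treatment mean jointly from all groups that carry
#' information on it, `"plugin"` shrinks the observed off-treatment
#' deviations about the on-treatment reference mean alone.
#'
#' @param s a [simple_scenario].
#' @param rho prior precision relative to residual precision (scalar or
#'   vector).
#' @param method `"joint"` or `"plugin"`.
#' @param tail_tol per-pattern probability floor.
#' @return data frame with one row per `rho`: `rho`, `bias`, `rmse`,
#'   `coverage_mass` (total pattern probability enumerated).
#' @export
bias_rmse <- function(s, rho, method = c("joint", "plugin"),
                      tail_tol = 1e-13) {
  stopifnot(inherits(s, "simple_scenario"))
  method <- match.arg(method)
  n <- s$n_per_arm
  t0 <- arm_pattern_table(n, s$p0, s$q0, tail_tol)
  t1 <- arm_pattern_table(n, s$p1, s$q1, tail_tol)
  i0 <- rep(seq_len(nrow(t0)), times = nrow(t1))
  i1 <- rep(seq_len(nrow(t1)), each = nrow(t0))
  a <- n - t0$n_dev[i0]
  b <- t0$n_dev[i0] - t0$n_miss[i0]
  nm0 <- t0$n_miss[i0]
  n_on1 <- n - t1$n_dev[i1]
  c_ <- t1$n_dev[i1] - t1$n_miss[i1]
  nm1 <- t1$n_miss[i1]
  w_pat <- t0$prob[i0] * t1$prob[i1]
  mu <- c(s$mu_on_0, s$mu_off_0, s$mu_on_1, s$mu_off_1)
  te <- te_real(s)
  out <- lapply(rho, function(r) {
    W <- estimator_weights(a, b, c_, n_on1, nm0, nm1, n, r, method)
    cb <- W[, 1] * mu[1] + W[, 2] * mu[2] + W[, 3] * mu[3] + W[, 4] * mu[4] - te
    # group weights vanish whenever the group is empty, so pmax is safe
    cv <- (W[, 1]^2 / pmax(a, 1) + W[, 2]^2 / pmax(b, 1) +
             W[, 3]^2 / pmax(n_on1, 1) + W[, 4]^2 / pmax(c_, 1)) * s$sigma2
    data.frame(rho = r, bias = sum(w_pat * cb),
               rmse = sqrt(sum(w_pat * (cb^2 + cv))),
               coverage_mass = sum(w_pat))
  })
  do.call(rbind, out)
}

#' Monte Carlo oracle for the simple-setting estimator
#'
#' Brute-force validation of [bias_rmse]: simulates whole trials (counts
#' binomially, group means normally), applies the same
#' infinite-imputation shrinkage estimator, and averages. Reports Monte
#' Carlo standard errors.
#'
#' @param s a [simple_scenario].
#' @param rho prior relative precision (scalar).
#' @param reps number of simulated trials.
#' @param seed RNG seed.
#' @param method `"joint"` or `"plugin"`.
#' @return list with `bias`, `rmse`, `mc_se` (of the bias), `mc_se_rmse`.
#' @export
mc_oracle <- function(s, rho, reps = 1e5, seed = 1L,
                      method = c("joint", "plugin")) {
  stopifnot(inherits(s, "simple_scenario"), reps >= 1)
  set.seed(seed)
  n <- s$n_per_arm
  nd0 <- stats::rbinom(reps, n, s$p0)
  nm0 <- stats::rbinom(reps, nd0, s$q0)
  nd1 <- stats::rbinom(reps, n, s$p1)
  nm1 <- stats::rbinom(reps, nd1, s$q1)
  a <- n - nd0
  b <- nd0 - nm0
  c_ <- nd1 - nm1
  n_on1 <- n - nd1
  draw_mean <- function(m, ng)
    ifelse(ng > 0, stats::rnorm(reps, m, sqrt(s$sigma2 / pmax(ng, 1))), 0)
  y <- cbind(on0 = draw_mean(s$mu_on_0, a), off0 = draw_mean(s$mu_off_0, b),
             on1 = draw_mean(s$mu_on_1, n_on1),
             off1 = draw_mean(s$mu_off_1, c_))
  W <- estimator_weights(a, b, c_, n_on1, nm0, nm1, n, rho, method)
  est <- rowSums(W * y)
  err <- est - te_real(s)
  list(bias = mean(err), rmse = sqrt(mean(err^2)),
       mc_se = stats::sd(err) / sqrt(reps),
       mc_se_rmse = stats::sd(err^2) / (2 * sqrt(mean(err^2)) * sqrt(reps)))
}
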