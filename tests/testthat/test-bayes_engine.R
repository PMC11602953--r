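test_that("conditional imputation matches the closed conditional-normal form", {
  # 2-visit worked case: Sigma = [[1, .5], [.5, 1]], mean (0, 0), Y1 = 2
  # -> conditional mean 1.0, variance 0.75
  Sigma <- matrix(c(1, .5, .5, 1), 2)
  X <- matrix(0, 2, 1)  # design contributing zero mean
  y <- c(2, NA)
  set.seed(7)
  z_ref <- rnorm(1)
  set.seed(7)
  out <- conditional_impute(beta_draw = 0, sigma_draw = Sigma, y = y,
                            design_rows = X)
  expect_equal(out[1], 2)
  expect_equal(out[2], 1.0 + sqrt(0.75) * z_ref)

  # zero off-diagonal: imputed mean ignores the observed value
  S0 <- diag(c(4, 9))
  set.seed(3); z <- rnorm(1)
  set.seed(3)
  out0 <- conditional_impute(0, S0, c(5, NA), matrix(0, 2, 1))
  expect_equal(out0[2], 3 * z)

  # all visits missing: unconditional draw at the design means
  Xm <- matrix(c(1, 1), 2, 1)
  set.seed(11); zz <- rnorm(2)
  set.seed(11)
  outm <- conditional_impute(2, diag(2), c(NA, NA), Xm)
  expect_equal(outm, 2 + zz)
  expect_error(conditional_impute(0, diag(2), c(1, 2), matrix(0, 2, 1)),
               "no missing")
})

test_that("with no missing data the coefficient posterior matches the conjugate closed form", {
  cfg <- synthetic_config(n_per_arm = c(30, 30), J = 3,
                          mu = rbind(c(1, 2, 3), c(2, 3, 5)),
                          Sigma = diag(3) + 0.5,
                          dev_hazard = matrix(0, 2, 2),
                          baseline_coef = rep(0.5, 3))
  d <- generate_trial(cfg, seed = 5)$data
  expect_false(anyNA(d$outcomes))
  des <- build_design(d, core_spec("J2R"), compliance_spec("historic"))
  pri <- build_priors(des, v = 40, scale_hint = var(as.vector(d$outcomes)))
  Sfix <- diag(3) + 0.5
  dr <- gibbs_fit_impute(d, des, pri,
                         gibbs_config(n_burn = 100, n_draws = 3000, seed = 9,
                                      fix_sigma = Sfix))
  expect_equal(ncol(dr$missing_y), 0L)

  iS <- solve(Sfix)
  p <- nrow(des$coef)
  A <- solve(pri$cov); bvec <- rep(0, p)
  for (j in 1:3) for (jp in 1:3) {
    A <- A + iS[j, jp] * crossprod(des$X[[j]], des$X[[jp]])
    bvec <- bvec + iS[j, jp] *
      crossprod(des$X[[j]], d$outcomes[, jp] - des$offset[, jp])
  }
  postmean <- solve(A, bvec)
  postcov <- solve(A)
  expect_lt(max(abs(colMeans(dr$beta) - postmean) / sqrt(diag(postcov))), 0.15)
  core_i <- which(des$coef$type != "deviation")
  expect_lt(max(abs(diag(cov(dr$beta))[core_i] - diag(postcov)[core_i]) /
                  diag(postcov)[core_i]), 0.15)
})

test_that("chains are bit-for-bit reproducible from the seed", {
  gt <- covered_fixture(seed = 4, n = c(20, 20))
  des <- build_design(gt$data, core_spec("J2R"), compliance_spec("historic"))
  pri <- build_priors(des, v = 40, scale_hint = 25)
  d1 <- gibbs_fit_impute(gt$data, des, pri, fast_gibbs(seed = 5, K = 20))
  d2 <- gibbs_fit_impute(gt$data, des, pri, fast_gibbs(seed = 5, K = 20))
  d3 <- gibbs_fit_impute(gt$data, des, pri, fast_gibbs(seed = 6, K = 20))
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$missing_y, d2$missing_y)
  expect_identical(d1$sigma, d2$sigma)
  expect_false(identical(d1$beta, d3$beta))
})

test_that("pinned J2R imputation follows the closed-form conditional mean", {
  # one active patient missing everything after deviation; deviation
  # coefficients pinned: the posterior-predictive mean of their final
  # visit must equal the J2R conditional mean at the posterior (beta, Sigma)
  gt <- covered_fixture(seed = 9, n = c(40, 40))
  d <- gt$data
  J <- d$n_visits
  i <- which(d$arm == 1L & d$last_study_visit == d$deviation_visit &
               d$deviation_visit < J)[1]
  expect_false(is.na(i))
  Sfix <- default_sigma(J)
  des <- build_design(d, core_spec("J2R"), compliance_spec("historic"))
  des <- rdrcmi:::drop_design_columns(des, "deviation")
  pri <- build_priors(des, v = 1, scale_hint = 25)
  dr <- gibbs_fit_impute(d, des, pri,
                         gibbs_config(n_burn = 100, n_draws = 1500, seed = 2,
                                      fix_sigma = Sfix))
  sel <- dr$miss_map$patient == i & dr$miss_map$visit == J
  expect_true(any(sel))
  pred_mean <- mean(dr$missing_y[, sel])
  # oracle: average over draws of the conditional-normal mean
  k <- d$deviation_visit[i]
  obs_j <- which(!is.na(d$outcomes[i, ]))
  cond_means <- vapply(seq_len(nrow(dr$beta)), function(s) {
    mu_i <- vapply(seq_len(J), function(j)
      sum(des$X[[j]][i, ] * dr$beta[s, ]) + des$offset[i, j], numeric(1))
    B <- Sfix[J, obs_j, drop = FALSE] %*%
      solve(Sfix[obs_j, obs_j, drop = FALSE])
    mu_i[J] + drop(B %*% (d$outcomes[i, obs_j] - mu_i[obs_j]))
  }, numeric(1))
  expect_equal(pred_mean, mean(cond_means),
               tolerance = 3 * sd(dr$missing_y[, sel]) / sqrt(1500) /
                 max(abs(mean(cond_means)), 1))
})

test_that("single-visit shrinkage in the sampler matches the normal-normal closed form", {
  # two-visit trial, no baseline effect, reference fully on treatment;
  # some active patients off at visit 2 and observed: the current-model
  # deviation coefficient's posterior mean is the conjugate shrinkage of
  # the off-on contrast toward zero
  set.seed(31)
  n <- 400
  y1 <- matrix(rnorm(2 * n, 0, 1), n, 2)
  arm <- rep(0:1, each = n / 2)
  off <- arm == 1 & seq_len(n) %% 4 == 0  # quarter of actives deviate
  D <- ifelse(off, 1L, 2L)
  y1[arm == 1, 2] <- y1[arm == 1, 2] + 1
  y1[off, 2] <- y1[off, 2] + 2  # gamma-true = 2 above the J2R mean
  d <- trial_data(y1, arm, baseline = rnorm(n), deviation_visit = D)
  des <- build_design(d, core_spec("J2R"), compliance_spec("current"),
                      baseline_interaction = FALSE)
  v <- 0.5
  pri <- build_priors(des, v = v, scale_hint = 1)
  Sfix <- diag(2)
  dr <- gibbs_fit_impute(d, des, pri,
                         gibbs_config(n_burn = 200, n_draws = 2000, seed = 4,
                                      fix_sigma = Sfix))
  a_i <- which(des$coef$name == "alpha*[1,2]")
  m <- sum(off)
  # closed-form approximation with the core means at their GLS values:
  # posterior mean ~ (m/(m + 1/v)) * (ybar_off2 - mu0_hat2); use the
  # fitted core coefficient draws to centre
  mu02 <- dr$beta[, which(des$coef$name == "mu[0,2]")]
  target <- mean((m / (m + 1 / v)) * (mean(y1[off, 2]) - mu02))
  got <- mean(dr$beta[, a_i])
  expect_equal(got, target, tolerance = 0.1)
})

test_that("mmrm_reference_fit recovers cell means and the covariance", {
  # balanced complete data, baseline dropped: cell means exactly
  set.seed(12)
  y <- matrix(rnorm(16 * 3), 16, 3)
  d <- trial_data(y, rep(0:1, each = 8), baseline = rnorm(16))
  fit <- mmrm_reference_fit(d, baseline = FALSE)
  for (t in 0:1) expect_equal(fit$mu[t + 1, ], colMeans(y[d$arm == t, ]),
                              tolerance = 1e-6, ignore_attr = TRUE)
  # parameter recovery at n = 500 with known Sigma
  Sig <- default_sigma(4)
  cfg <- synthetic_config(n_per_arm = c(250, 250), Sigma = Sig,
                          dev_hazard = matrix(0.05, 2, 3))
  gt <- generate_trial(cfg, seed = 13)
  f2 <- mmrm_reference_fit(gt$data)
  expect_lt(max(abs(f2$sigma - Sig) / (abs(Sig) + 5)), 0.2)
  # degenerate one-patient arm errors
  y3 <- matrix(rnorm(9), 3, 3)
  d3 <- trial_data(y3, c(0, 0, 1), baseline = rnorm(3))
  expect_error(mmrm_reference_fit(d3), "at least 2 patients")
})

test_that("grouped covariance estimates one matrix per arm", {
  gt <- covered_fixture(seed = 15, n = c(25, 25))
  des <- build_design(gt$data, core_spec("J2R"), compliance_spec("historic"))
  pri <- build_priors(des, v = 40, scale_hint = 25)
  dr <- gibbs_fit_impute(gt$data, des, pri,
                         gibbs_config(n_burn = 50, n_draws = 10, seed = 1,
                                      grouped_covariance = TRUE))
  expect_true(is.list(dr$sigma) && length(dr$sigma) == 2L)
  expect_false(identical(dr$sigma[[1]], dr$sigma[[2]]))
})
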