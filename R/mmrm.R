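#' Repeated-measures fit to the on-treatment data
#'
#' Fits the standard MMRM (arm-by-visit cell means, optional
#' baseline-by-visit adjustment, unstructured covariance) to the
#' on-treatment records only (visits `j <= D`, observed). Used as the basis
#' for the default deviation-prior variance (final-visit residual variance)
#' and to initialise the Gibbs sampler. Fitting goes through
#' [nlme::gls()] with `corSymm` correlation and per-visit variance weights
#' (REML); if that fails to converge a moment-based estimate
#' (per-cell means, baseline-adjusted available-case covariance, ridged to
#' positive definiteness) is returned with `converged = FALSE`.
#'
#' @param data a [trial_data] object.
#' @param baseline include the baseline-by-visit adjustment (default TRUE).
#' @return list with `mu` (2 by `J` matrix of cell means at baseline 0,
#'   rows reference/active), `beta_base` (length-`J` baseline slopes, zero
#'   when `baseline = FALSE`), `sigma` (`J` by `J` unstructured residual
#'   covariance), `converged`, `method`.
#' @export
mmrm_reference_fit <- function(data, baseline = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  J <- data$n_visits
  N <- n_patients(data)
  if (min(table(factor(data$arm, levels = 0:1))) < 2L)
    stop("each arm needs at least 2 patients for the repeated-measures fit")

  D <- data$deviation_visit
  long <- data.frame(
    subject = rep(seq_len(N), each = J),
    visit = rep(seq_len(J), N),
    arm = rep(data$arm, each = J),
    baseline = rep(data$baseline, each = J),
    y = as.vector(t(data$outcomes))
  )
  long <- long[long$visit <= rep(D, each = J) & !is.na(long$y), , drop = FALSE]
  for (j in seq_len(J))
    if (!any(long$visit == j)) stop("no on-treatment observations at visit ", j)

  # explicit numeric design columns so coefficients map directly onto cells
  for (t in 0:1) for (j in seq_len(J))
    long[[sprintf("c_%d_%d", t, j)]] <- as.numeric(long$arm == t & long$visit == j)
  terms <- as.vector(outer(seq_len(J), 0:1, function(j, t) sprintf("c_%d_%d", t, j)))
  if (baseline) {
    for (j in seq_len(J))
      long[[sprintf("b_%d", j)]] <- long$baseline * (long$visit == j)
    terms <- c(terms, sprintf("b_%d", seq_len(J)))
  }
  fml <- stats::as.formula(paste("y ~ 0 +", paste(terms, collapse = " + ")))

  fit <- tryCatch(
    nlme::gls(fml, data = long,
              correlation = nlme::corSymm(form = ~ visit | subject),
              weights = nlme::varIdent(form = ~ 1 | visit),
              na.action = stats::na.omit,
              control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                         returnObject = FALSE)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    mu <- matrix(cf[seq_len(2L * J)], nrow = 2L, byrow = TRUE,
                 dimnames = list(c("reference", "active"), NULL))
    beta_base <- if (baseline) unname(cf[2L * J + seq_len(J)]) else rep(0, J)
    # marginal covariance of a patient observed at all J visits
    full_id <- as.character(long$subject[long$subject %in%
      names(which(table(long$subject) == J))][1L])
    sig <- tryCatch({
      v <- nlme::getVarCov(fit, individual = full_id)
      m <- matrix(as.numeric(v), J, J)
      m
    }, error = function(e) NULL)
    if (!is.null(sig))
      return(list(mu = mu, beta_base = beta_base, sigma = sig,
                  converged = TRUE, method = "gls"))
  }
  moment_mmrm(long, J, baseline)
}

moment_mmrm <- function(long, J, baseline) {
  mu <- matrix(0, 2L, J, dimnames = list(c("reference", "active"), NULL))
  beta_base <- rep(0, J)
  res <- long
  res$r <- NA_real_
  for (j in seq_len(J)) {
    sel <- long$visit == j
    if (baseline && stats::var(long$baseline[sel]) > 0) {
      f <- stats::lm(y ~ 0 + factor(arm, levels = 0:1) + baseline,
                     data = long[sel, , drop = FALSE])
      cf <- stats::coef(f)
      mu[, j] <- cf[1:2]
      beta_base[j] <- cf[3L]
      res$r[sel] <- stats::resid(f)
    } else {
      for (t in 0:1) mu[t + 1L, j] <- mean(long$y[sel & long$arm == t])
      res$r[sel] <- long$y[sel] - mu[long$arm[sel] + 1L, j]
    }
  }
  rmat <- matrix(NA_real_, max(long$subject), J)
  rmat[cbind(res$subject, res$visit)] <- res$r
  sig <- stats::cov(rmat, use = "pairwise.complete.obs")
  sig[is.na(sig)] <- 0
  diag(sig)[diag(sig) <= 0] <- stats::var(res$r)
  # ridge towards the diagonal until positive definite
  lam <- 0
  repeat {
    s_try <- (1 - lam) * sig + lam * diag(diag(sig))
    if (!inherits(tryCatch(chol(s_try), error = function(e) e), "error")) break
    lam <- max(lam * 2, 0.05)
    if (lam >= 1) { s_try <- diag(diag(sig)); break }
  }
  list(mu = mu, beta_base = beta_base, sigma = s_try,
       converged = FALSE, method = "moment")
}
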