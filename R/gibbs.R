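#' Configuration for the Gibbs sampler
#'
#' All full conditionals are conjugate (direct sampling), so serial
#' correlation is minimal and `thin = 1` is the default; increase `thin`
#' only if imputations are required to be closer to independent.
#'
#' @param n_burn burn-in sweeps.
#' @param n_draws number of stored draws `K` (= number of imputed data
#'   sets downstream).
#' @param thin store every `thin`-th sweep after burn-in.
#' @param seed integer root seed; the whole chain is reproducible from it.
#' @param grouped_covariance estimate a separate unstructured covariance
#'   per arm (default: one shared matrix).
#' @param fix_sigma optional fixed residual covariance (`J` by `J`, or a
#'   list of two for grouped): skips the covariance update, used mainly for
#'   conjugacy checks.
#' @return an object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_burn = 1000L, n_draws = 200L, thin = 1L, seed = 1L,
                         grouped_covariance = FALSE, fix_sigma = NULL) {
  stopifnot(n_burn >= 0, n_draws >= 1, thin >= 1)
  structure(list(n_burn = as.integer(n_burn), n_draws = as.integer(n_draws),
                 thin = as.integer(thin), seed = as.integer(seed),
                 grouped_covariance = isTRUE(grouped_covariance),
                 fix_sigma = fix_sigma),
            class = "gibbs_config")
}

chol_safe <- function(M, label = "matrix", max_tries = 6L) {
  jit <- 0
  base <- mean(diag(M))
  for (i in seq_len(max_tries)) {
    R <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- if (jit == 0) 1e-10 * max(base, 1) else jit * 100
  }
  stop("failed to factor ", label, " even after jitter")
}

riwish <- function(nu, S) {
  W <- stats::rWishart(1L, nu, chol2inv(chol_safe(S, "IW scale")))[, , 1L]
  chol2inv(chol_safe(W, "Wishart draw"))
}

cond_normal <- function(mu, Sigma, obs_idx, y_obs) {
  # conditional distribution of the complement given y_obs
  m <- setdiff(seq_along(mu), obs_idx)
  if (!length(obs_idx))
    return(list(mean = mu[m], cov = Sigma[m, m, drop = FALSE], miss = m))
  So <- Sigma[obs_idx, obs_idx, drop = FALSE]
  B <- Sigma[m, obs_idx, drop = FALSE] %*% chol2inv(chol_safe(So, "observed block"))
  list(mean = mu[m] + drop(B %*% (y_obs - mu[obs_idx])),
       cov = Sigma[m, m, drop = FALSE] - B %*% Sigma[obs_idx, m, drop = FALSE],
       miss = m)
}

#' Impute one patient's missing visits from the conditional normal
#'
#' Draws the missing sub-vector of a patient's outcome from its
#' multivariate-normal distribution conditional on the observed sub-vector,
#' with mean `design_rows %*% beta + offset` and covariance `sigma`.
#' Deterministic given the R random state.
#'
#' @param beta_draw coefficient vector.
#' @param sigma_draw `J` by `J` covariance.
#' @param y length-`J` outcome vector with `NA` at missing visits.
#' @param design_rows `J` by `p` design matrix for this patient.
#' @param offset length-`J` fixed mean offset (default zero).
#' @return `y` with missing entries replaced by the draw.
#' @export
conditional_impute <- function(beta_draw, sigma_draw, y, design_rows,
                               offset = rep(0, length(y))) {
  if (!anyNA(y)) stop("no missing cells to impute")
  mu <- drop(design_rows %*% beta_draw) + offset
  cn <- cond_normal(mu, sigma_draw, which(!is.na(y)), y[!is.na(y)])
  z <- stats::rnorm(length(cn$miss))
  y[cn$miss] <- cn$mean + drop(crossprod(chol_safe(cn$cov, "conditional cov"), z))
  y
}

engine_init <- function(data, design) {
  J <- design$J
  fit <- tryCatch(mmrm_reference_fit(data), error = function(e) NULL)
  if (is.null(fit)) {
    long <- data.frame(subject = rep(seq_len(n_patients(data)), each = J),
                       visit = rep(seq_len(J), n_patients(data)),
                       arm = rep(data$arm, each = J),
                       baseline = rep(data$baseline, each = J),
                       y = as.vector(t(data$outcomes)))
    long <- long[long$visit <= rep(data$deviation_visit, each = J) &
                   !is.na(long$y), , drop = FALSE]
    fit <- moment_mmrm(long, J, baseline = TRUE)
  }
  coef <- design$coef
  beta <- rep(0, nrow(coef))
  core_i <- which(coef$type == "core")
  # the design centres baseline, so shift the cell means accordingly
  ctr <- if (is.null(design$baseline_center)) 0 else design$baseline_center
  mu0 <- fit$mu + rep(fit$beta_base * ctr, each = 2L)
  beta[core_i] <- c(mu0[1L, ], mu0[2L, ])
  base_i <- which(coef$type == "baseline")
  beta[base_i] <- fit$beta_base[coef$j[base_i]]
  list(beta = beta, sigma = fit$sigma)
}

#' Fit the Bayesian extended model and impute by Gibbs sampling
#'
#' One sweep: (i) draw every missing outcome cell from its conditional
#' multivariate normal given the patient's observed cells and the current
#' coefficients and covariance; (ii) draw the coefficients from their
#' conjugate multivariate-normal full conditional given the completed data
#' and the Gaussian prior; (iii) draw the unstructured covariance (per arm
#' when grouped) from its inverse-Wishart full conditional. After burn-in,
#' every `thin`-th sweep is stored; the stored missing-cell draws are the
#' imputations, exactly as in the MCMC-as-imputation view of the method.
#'
#' @param data a [trial_data] object (its `NA` pattern defines the cells to
#'   impute).
#' @param design a `design_matrices` object from [build_design].
#' @param priors a `prior_spec` object from [build_priors].
#' @param cfg a [gibbs_config].
#' @return An object of class `posterior_draws`: list with `beta`
#'   (draws by coefficients), `sigma` (draws by `J` by `J`, or a list of
#'   two arrays when grouped), `missing_y` (draws by missing cells),
#'   `miss_map` (data frame `patient`, `visit` mapping the columns of
#'   `missing_y`), `coef`, `draw_meta`.
#' @export
gibbs_fit_impute <- function(data, design, priors, cfg = gibbs_config()) {
  stopifnot(inherits(data, "trial_data"), inherits(design, "design_matrices"),
            inherits(priors, "prior_spec"), inherits(cfg, "gibbs_config"))
  set.seed(cfg$seed)
  J <- design$J
  N <- n_patients(data)
  X <- design$X
  p <- nrow(design$coef)
  offset <- design$offset
  Y <- data$outcomes
  miss <- is.na(Y)
  miss_map <- which(miss, arr.ind = TRUE)
  miss_map <- data.frame(patient = miss_map[, 1L], visit = miss_map[, 2L])
  ord <- order(miss_map$patient, miss_map$visit)
  miss_map <- miss_map[ord, , drop = FALSE]
  n_miss <- nrow(miss_map)

  grouped <- cfg$grouped_covariance
  arms <- if (grouped) list(which(data$arm == 0L), which(data$arm == 1L))
          else list(seq_len(N))
  n_grp <- length(arms)

  # visit-slice cross products per covariance group (fixed across sweeps)
  G <- lapply(arms, function(rows)
    lapply(seq_len(J), function(j)
      lapply(seq_len(J), function(jp)
        crossprod(X[[j]][rows, , drop = FALSE], X[[jp]][rows, , drop = FALSE]))))

  P0chol <- chol_safe(priors$cov, "prior covariance")
  P0inv <- chol2inv(P0chol)
  P0m <- drop(P0inv %*% priors$mean)
  nu0 <- priors$iw_df
  S0 <- priors$iw_scale

  init <- engine_init(data, design)
  beta <- init$beta
  fix <- cfg$fix_sigma
  if (!is.null(fix) && !is.list(fix)) fix <- rep(list(fix), n_grp)
  Sig <- if (!is.null(fix)) fix else rep(list(init$sigma), n_grp)

  # group patients with missing data by (covariance group, missingness pattern)
  pat_key <- apply(miss, 1L, function(z) paste(as.integer(z), collapse = ""))
  has_miss <- which(rowSums(miss) > 0L)
  grp_of <- if (grouped) data$arm + 1L else rep(1L, N)
  pat_groups <- split(has_miss, list(grp_of[has_miss], pat_key[has_miss]),
                      drop = TRUE)

  n_keep <- cfg$n_draws
  out_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, design$coef$name))
  out_sigma <- lapply(seq_len(n_grp), function(g) array(NA_real_, c(n_keep, J, J)))
  out_y <- matrix(NA_real_, n_keep, n_miss)
  lin_idx <- (miss_map$visit - 1L) * N + miss_map$patient  # column-major cells

  n_sweeps <- cfg$n_burn + n_keep * cfg$thin
  kept <- 0L
  for (s in seq_len(n_sweeps)) {
    eta <- offset
    for (j in seq_len(J)) eta[, j] <- eta[, j] + drop(X[[j]] %*% beta)

    # (i) impute missing cells, vectorised per missingness pattern
    for (g in pat_groups) {
      Sg <- Sig[[grp_of[g[1L]]]]
      mvis <- which(miss[g[1L], ])
      ovis <- setdiff(seq_len(J), mvis)
      Mm <- eta[g, mvis, drop = FALSE]
      if (length(ovis)) {
        B <- Sg[mvis, ovis, drop = FALSE] %*%
          chol2inv(chol_safe(Sg[ovis, ovis, drop = FALSE], "observed block"))
        condmean <- Mm + (Y[g, ovis, drop = FALSE] -
                            eta[g, ovis, drop = FALSE]) %*% t(B)
        condcov <- Sg[mvis, mvis, drop = FALSE] -
          B %*% Sg[ovis, mvis, drop = FALSE]
      } else {
        condmean <- Mm
        condcov <- Sg[mvis, mvis, drop = FALSE]
      }
      Z <- matrix(stats::rnorm(length(g) * length(mvis)), length(g))
      Y[g, mvis] <- condmean + Z %*% chol_safe(condcov, "conditional cov")
    }

    # (ii) coefficient draw from the conjugate normal full conditional
    A <- P0inv
    b <- P0m
    Yc <- Y - offset
    for (gi in seq_len(n_grp)) {
      iS <- chol2inv(chol_safe(Sig[[gi]], "Sigma"))
      rows <- arms[[gi]]
      for (j in seq_len(J)) for (jp in seq_len(J)) {
        w <- iS[j, jp]
        if (w != 0) {
          A <- A + w * G[[gi]][[j]][[jp]]
          b <- b + w * drop(crossprod(X[[j]][rows, , drop = FALSE], Yc[rows, jp]))
        }
      }
    }
    R <- chol_safe(A, "coefficient precision")
    beta <- backsolve(R, backsolve(R, b, transpose = TRUE) + stats::rnorm(p))

    # (iii) covariance draw(s) from the inverse-Wishart full conditional
    if (is.null(fix)) {
      for (j in seq_len(J)) eta[, j] <- offset[, j] + drop(X[[j]] %*% beta)
      E <- Y - eta
      for (gi in seq_len(n_grp)) {
        rows <- arms[[gi]]
        Sig[[gi]] <- riwish(nu0 + length(rows),
                            S0 + crossprod(E[rows, , drop = FALSE]))
      }
    }

    if (s > cfg$n_burn && (s - cfg$n_burn) %% cfg$thin == 0L) {
      kept <- kept + 1L
      out_beta[kept, ] <- beta
      for (gi in seq_len(n_grp)) out_sigma[[gi]][kept, , ] <- Sig[[gi]]
      out_y[kept, ] <- Y[lin_idx]
    }
  }

  structure(list(
    beta = out_beta,
    sigma = if (grouped) out_sigma else out_sigma[[1L]],
    missing_y = out_y, miss_map = miss_map, coef = design$coef,
    never_observed = design$never_observed,
    draw_meta = list(n_burn = cfg$n_burn, n_draws = n_keep, thin = cfg$thin,
                     seed = cfg$seed, grouped = grouped)),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws, %d coefficients, %d missing cells\n",
              nrow(x$beta), ncol(x$beta), ncol(x$missing_y)))
  if (length(x$never_observed))
    cat("  never-observed deviation coefficients:",
        paste(x$never_observed, collapse = ", "), "\n")
  invisible(x)
}

#' Export posterior draws to CSV (one file of coefficients, one of the
#' vectorised covariance) for external diagnostics.
#' @param draws a `posterior_draws` object.
#' @param stem output path stem.
#' @return the paths written, invisibly.
#' @export
export_draws <- function(draws, stem) {
  p1 <- paste0(stem, "_beta.csv")
  utils::write.csv(as.data.frame(draws$beta), p1, row.names = FALSE)
  sig <- draws$sigma
  if (is.list(sig)) sig <- sig[[1L]]
  J <- dim(sig)[2L]
  flat <- matrix(sig, nrow = dim(sig)[1L])
  colnames(flat) <- as.vector(outer(seq_len(J), seq_len(J),
                                    function(i, j) sprintf("sigma[%d,%d]", i, j)))
  p2 <- paste0(stem, "_sigma.csv")
  utils::write.csv(as.data.frame(flat), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Form completed datasets from posterior draws
#'
#' Inserts each stored draw of the missing cells into the original data,
#' preserving every observed value exactly.
#'
#' @param draws a `posterior_draws` object.
#' @param data the original [trial_data] object.
#' @return list of `K` completed [trial_data] objects.
#' @export
completed_datasets <- function(draws, data) {
  N <- n_patients(data)
  lin_idx <- (draws$miss_map$visit - 1L) * N + draws$miss_map$patient
  lapply(seq_len(nrow(draws$missing_y)), function(k) {
    out <- data
    out$outcomes[lin_idx] <- draws$missing_y[k, ]
    out$last_study_visit <- rep(data$n_visits, N)
    out
  })
}
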