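#' Build the extended imputation model design
#'
#' Assembles, per patient and visit, the mean-model design of the
#' reference-base centred extended model: a core block housing the
#' on-treatment cell means `mu[t, j]` (with the off-treatment rows carrying
#' the core model's implied-mean weights), a baseline block
#' (baseline-by-visit, optionally crossed with randomised arm), and a
#' deviation block of compliance-model indicators that is identically zero
#' on on-treatment rows. The baseline covariate enters centred at its
#' overall mean, so the cell-mean coefficients are interpretable at the
#' average baseline and, crucially, the reference-based off-treatment mean
#' for a deviator (reference cell mean plus own-arm slope times the
#' baseline deviation) never extrapolates the reference intercept across
#' the baseline scale. Deviation cells that never occur in the data are
#' retained (their posterior equals their prior); a report lists the
#' deviation levels with no observed off-treatment outcome, which is
#' exactly where the perforated-data problem lives. Rank deficiency is
#' reported, never fatal.
#'
#' @param data a [trial_data] object.
#' @param core a [core_spec].
#' @param compliance a [compliance_spec], or `NULL` for no deviation block
#'   (the classic reference-based imputation design).
#' @param baseline_interaction cross the baseline-by-visit block with
#'   randomised arm (the complete model); `FALSE` drops the arm interaction.
#' @return An object of class `design_matrices`: list with
#'   `X` (list of `J` matrices, patients by coefficients: the design slice
#'   at each visit), `offset` (patients by visits matrix of fixed mean
#'   offsets: MAR_DELTA deltas and RTB baseline means), `coef` (data frame
#'   with `name`, `type` in core/baseline/deviation, `t`, `k`, `j`),
#'   `never_observed` (deviation coefficient names with no observed data),
#'   `J`, `baseline_means`.
#' @export
build_design <- function(data, core, compliance = compliance_spec("historic"),
                         baseline_interaction = TRUE) {
  stopifnot(inherits(data, "trial_data"), inherits(core, "core_spec"))
  J <- data$n_visits
  N <- n_patients(data)
  if (!is.null(compliance)) {
    nest <- check_nesting(core, compliance, J)
    if (!nest$ok)
      stop(sprintf("core model '%s' is not nested within the '%s' compliance model",
                   core$kind, compliance$kind))
  }
  bm <- c(pooled = mean(data$baseline),
          reference = mean(data$baseline[data$arm == 0L]),
          active = mean(data$baseline[data$arm == 1L]))

  core_coef <- data.frame(name = mu_names(J), type = "core",
                          t = rep(0:1, each = J), k = NA_integer_,
                          j = rep(seq_len(J), 2L))
  if (baseline_interaction) {
    g <- expand.grid(j = seq_len(J), t = 0:1)
    base_coef <- data.frame(name = sprintf("base[%d,%d]", g$t, g$j),
                            type = "baseline", t = g$t, k = NA_integer_, j = g$j)
  } else {
    base_coef <- data.frame(name = sprintf("base[%d]", seq_len(J)),
                            type = "baseline", t = NA_integer_,
                            k = NA_integer_, j = seq_len(J))
  }
  if (!is.null(compliance)) {
    lv <- dev_levels(compliance, J)
    dev_coef <- data.frame(name = lv$name, type = "deviation",
                           t = lv$t, k = lv$k, j = lv$j)
  } else {
    dev_coef <- core_coef[0L, ]
  }
  coef <- rbind(core_coef, base_coef, dev_coef)
  p <- nrow(coef)
  i_dev <- which(coef$type == "deviation")

  X <- lapply(seq_len(J), function(j) matrix(0, N, p,
                                             dimnames = list(NULL, coef$name)))
  offset <- matrix(0, N, J)
  D <- data$deviation_visit
  for (j in seq_len(J)) {
    on <- D >= j
    # core block
    for (t in 0:1) {
      sel <- on & data$arm == t
      X[[j]][sel, mu_col(t, j, J)] <- 1
    }
    off_idx <- which(!on)
    for (i in off_idx) {
      ow <- core_offset_weights(core, data$arm[i], D[i], j, J)
      X[[j]][i, seq_len(2L * J)] <- ow$w
      offset[i, j] <- if (ow$rtb) {
        if (core$rtb_pooled) bm[["pooled"]] else
          bm[[c("reference", "active")[data$arm[i] + 1L]]]
      } else ow$const
    }
    # baseline block (as-randomised arm throughout, per the complete model)
    bl_c <- data$baseline - bm[["pooled"]]
    if (baseline_interaction) {
      for (t in 0:1) {
        sel <- data$arm == t
        X[[j]][sel, 2L * J + t * J + j] <- bl_c[sel]
      }
    } else {
      X[[j]][, 2L * J + j] <- bl_c
    }
    # deviation block: zero on on-treatment rows by construction
    for (ci in i_dev) {
      hit <- !on & data$arm == coef$t[ci] & j == coef$j[ci] &
        (is.na(coef$k[ci]) | D == coef$k[ci])
      X[[j]][hit, ci] <- 1
    }
  }

  never <- character(0)
  if (length(i_dev)) {
    seen <- vapply(i_dev, function(ci) {
      any(vapply(seq_len(J), function(j)
        any(X[[j]][, ci] != 0 & !is.na(data$outcomes[, j])), logical(1)))
    }, logical(1))
    never <- coef$name[i_dev][!seen]
  }
  structure(list(X = X, offset = offset, coef = coef,
                 never_observed = never, J = J, baseline_means = bm,
                 baseline_center = bm[["pooled"]]),
            class = "design_matrices")
}

#' Drop columns from a design (used to pin deviation coefficients at zero)
#' @param design a `design_matrices` object.
#' @param drop character vector of coefficient names or a coefficient type.
#' @return a `design_matrices` object without those columns.
#' @keywords internal
drop_design_columns <- function(design, drop = "deviation") {
  keep <- if (all(drop %in% c("core", "baseline", "deviation")))
    !(design$coef$type %in% drop) else !(design$coef$name %in% drop)
  design$X <- lapply(design$X, function(m) m[, keep, drop = FALSE])
  design$coef <- design$coef[keep, , drop = FALSE]
  design$never_observed <- intersect(design$never_observed, design$coef$name)
  design
}

#' Default prior variance for the deviation parameters
#'
#' Two routes: `mmrm_residual` (the default) takes the final-visit diagonal
#' element of the unstructured residual covariance from a repeated-measures
#' fit to the on-treatment data only (see [mmrm_reference_fit]); `range`
#' takes the square of one sixth of the range of the observed final-visit
#' outcomes. On the scale of one extra patient-visit of likelihood, the
#' `mmrm_residual` value makes the zero-centred prior roughly as strong as
#' one additional patient who follows the core model exactly.
#'
#' @param data a [trial_data] object.
#' @param method `"mmrm_residual"` or `"range"`.
#' @return scalar prior variance, in squared outcome units.
#' @export
default_prior_variance <- function(data, method = c("mmrm_residual", "range")) {
  method <- match.arg(method)
  J <- data$n_visits
  on_final <- data$deviation_visit >= J & !is.na(data$outcomes[, J])
  if (sum(on_final) < 2L)
    stop("fewer than 2 on-treatment final-visit observations")
  if (method == "range") {
    y <- data$outcomes[!is.na(data$outcomes[, J]), J]
    v <- ((max(y) - min(y)) / 6)^2
    if (v == 0) warning("constant final-visit outcome: range-based prior variance is 0")
    return(v)
  }
  fit <- mmrm_reference_fit(data)
  fit$sigma[J, J]
}

#' Build Gaussian priors for the extended model coefficients
#'
#' Core and baseline coefficients receive a diffuse zero-mean prior
#' (variance `diffuse_variance`, effectively flat yet proper so the Gibbs
#' sampler stays conjugate). Deviation coefficients receive the mildly
#' informative zero-centred prior with variance `v`; within each
#' arm-by-deviation-visit group, visit-adjacent deviation coefficients may
#' be given prior correlation `adjacent_corr` (deviations at neighbouring
#' visits are expected to point the same way). The covariance prior for
#' the residual matrix is inverse-Wishart.
#'
#' @param design a `design_matrices` object.
#' @param v deviation-prior variance (squared outcome units).
#' @param diffuse_variance core-prior variance; default `1e6` times the
#'   scale hint `scale_hint` (callers pass the sample variance of the
#'   observed outcomes).
#' @param adjacent_corr prior correlation between visit-adjacent deviation
#'   coefficients, in `[0, 1)`.
#' @param iw_df inverse-Wishart degrees of freedom (default `J + 2`, the
#'   weakest proper choice).
#' @param iw_scale inverse-Wishart scale matrix (default identity times
#'   `scale_hint`).
#' @param scale_hint outcome-scale variance used for the defaults.
#' @return An object of class `prior_spec`: list with `mean`, `cov`,
#'   (coefficient prior), `iw_df`, `iw_scale`, `v`, `coef` echo.
#' @export
build_priors <- function(design, v, diffuse_variance = NULL,
                         adjacent_corr = 0, iw_df = NULL, iw_scale = NULL,
                         scale_hint = 1) {
  stopifnot(v > 0, adjacent_corr >= 0, adjacent_corr < 1)
  coef <- design$coef
  p <- nrow(coef)
  J <- design$J
  if (is.null(diffuse_variance)) diffuse_variance <- 1e6 * scale_hint
  if (is.null(iw_df)) iw_df <- J + 2
  if (is.null(iw_scale)) iw_scale <- diag(scale_hint, J)
  V <- diag(ifelse(coef$type == "deviation", v, diffuse_variance), p)
  dimnames(V) <- list(coef$name, coef$name)
  if (adjacent_corr > 0) {
    idx <- which(coef$type == "deviation")
    for (a in idx) for (b in idx) {
      same_group <- coef$t[a] == coef$t[b] &&
        (identical(coef$k[a], coef$k[b]) || (is.na(coef$k[a]) && is.na(coef$k[b])))
      if (a < b && same_group && abs(coef$j[a] - coef$j[b]) == 1L)
        V[a, b] <- V[b, a] <- adjacent_corr * v
    }
  }
  # positive definiteness check
  ev <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ev)) stop("prior covariance is not positive definite")
  structure(list(mean = stats::setNames(rep(0, p), coef$name), cov = V,
                 iw_df = iw_df, iw_scale = iw_scale, v = v,
                 adjacent_corr = adjacent_corr,
                 diffuse_variance = diffuse_variance, coef = coef),
            class = "prior_spec")
}
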