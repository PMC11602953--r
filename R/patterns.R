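#' Derive per patient-visit pattern covariates
#'
#' Computes the covariates the imputation model is built from, in
#' patient-major long order (patient 1 visits 1..J, then patient 2, ...):
#' * `off_t` — 0 while on randomised treatment (visit <= D), 1 after;
#' * `pattern` — the running compliance pattern: the current visit number
#'   while on treatment and the deviation visit D thereafter (so it is
#'   non-decreasing in visit and constant after deviation);
#' * `j2r_factor` — the as-randomised arm label while on treatment and the
#'   reference level while off treatment;
#' * `trtbyvis` — for history-dependent cores (CIR, LMCF, MAR+delta), the
#'   quantitative treatment-by-visit covariates: per row, the weights on the
#'   on-treatment cell means `mu[t, j]` that encode the core's implied
#'   off-treatment mean (identity weights while on treatment). `NULL` for
#'   cores whose off-treatment mean needs no such encoding beyond the J2R
#'   factor (MAR, J2R, CR, RTB).
#'
#' @param data a [trial_data] object.
#' @param core a [core_spec] object (default MAR: no off-treatment
#'   re-targeting).
#' @return A list of class `pattern_variables` with the fields above plus
#'   `subject`, `visit`, `arm`.
#' @export
derive_patterns <- function(data, core = core_spec("MAR")) {
  stopifnot(inherits(data, "trial_data"))
  J <- data$n_visits
  N <- n_patients(data)
  visit <- rep(seq_len(J), N)
  D <- rep(data$deviation_visit, each = J)
  arm <- rep(data$arm, each = J)
  off_t <- as.integer(visit > D)
  pattern <- pmin(visit, D)
  j2r_factor <- ifelse(off_t == 1L, data$arm_labels[["reference"]],
                       data$arm_labels[arm + 1L])
  trtbyvis <- NULL
  if (core$kind %in% c("CIR", "LMCF", "MAR_DELTA")) {
    trtbyvis <- matrix(0, N * J, 2L * J,
                       dimnames = list(NULL, mu_names(J)))
    for (r in seq_len(N * J)) {
      t_i <- arm[r]; j <- visit[r]; k <- D[(r - 1L) %/% J + 1L]
      if (j <= k) {
        trtbyvis[r, mu_col(t_i, j, J)] <- 1
      } else {
        trtbyvis[r, ] <- core_offset_weights(core, t_i, k, j, J)$w
      }
    }
  }
  structure(list(subject = rep(data$subject_id, each = J), visit = visit,
                 arm = arm, off_t = off_t, pattern = pattern,
                 j2r_factor = j2r_factor, trtbyvis = trtbyvis),
            class = "pattern_variables")
}

group_of <- function(data) {
  J <- data$n_visits
  D <- data$deviation_visit
  S <- data$last_study_visit
  g <- ifelse(D == J, "completer",
              ifelse(S == D, "stop", ifelse(S == J, "continue", "partial")))
  factor(g, levels = c("stop", "continue", "partial", "completer"))
}

#' Summarise trial data by deviation pattern
#'
#' Tabulates, per (arm, deviation visit, stop/continue) stratum, the patient
#' count and the per-visit mean of observed outcomes, and per (arm, visit)
#' the on-treatment / observed off-treatment / missing off-treatment counts.
#' Strata cells with no observed values are reported as `NA`, not zero.
#'
#' @param data a [trial_data] object.
#' @return A list of class `pattern_summary` with data frames `patterns`
#'   (columns `arm`, `deviation_visit`, `group`, `count`, `mean_v1..J`) and
#'   `visit_counts` (columns `arm`, `visit`, `on`, `off_obs`, `off_miss`).
#' @export
pattern_summary <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  J <- data$n_visits
  grp <- group_of(data)
  key <- interaction(data$arm, data$deviation_visit, grp, drop = TRUE)
  pat <- do.call(rbind, lapply(levels(key), function(lv) {
    sel <- key == lv
    m <- colMeans(data$outcomes[sel, , drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    d <- data.frame(arm = data$arm_labels[data$arm[sel][1L] + 1L],
                    deviation_visit = data$deviation_visit[sel][1L],
                    group = as.character(grp[sel][1L]),
                    count = sum(sel), stringsAsFactors = FALSE)
    d[paste0("mean_v", seq_len(J))] <- as.list(m)
    d
  }))
  pat <- pat[order(pat$arm, pat$deviation_visit, pat$group), , drop = FALSE]
  rownames(pat) <- NULL

  vc <- expand.grid(visit = seq_len(J), arm01 = 0:1)
  vc$on <- vc$off_obs <- vc$off_miss <- NA_integer_
  for (r in seq_len(nrow(vc))) {
    sel <- data$arm == vc$arm01[r]
    j <- vc$visit[r]
    on <- data$deviation_visit[sel] >= j
    vc$on[r] <- sum(on)
    vc$off_obs[r] <- sum(!on & !is.na(data$outcomes[sel, j]))
    vc$off_miss[r] <- sum(!on & is.na(data$outcomes[sel, j]))
  }
  vc <- data.frame(arm = data$arm_labels[vc$arm01 + 1L], visit = vc$visit,
                   on = vc$on, off_obs = vc$off_obs, off_miss = vc$off_miss,
                   stringsAsFactors = FALSE)
  structure(list(patterns = pat, visit_counts = vc,
                 arm_labels = data$arm_labels),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("Per-visit on / observed-off / missing-off counts:\n")
  print(x$visit_counts, row.names = FALSE)
  cat("\nStratum means (NA = no observed value):\n")
  print(x$patterns, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export a pattern summary to CSV
#'
#' Writes the stratum-means table and the per-visit count table to two CSV
#' files (suffixes `_patterns.csv` and `_visit_counts.csv`).
#'
#' @param x a [pattern_summary] object.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_pattern_summary <- function(x, stem) {
  p1 <- paste0(stem, "_patterns.csv")
  p2 <- paste0(stem, "_visit_counts.csv")
  utils::write.csv(x$patterns, p1, row.names = FALSE, na = "")
  utils::write.csv(x$visit_counts, p2, row.names = FALSE, na = "")
  invisible(c(p1, p2))
}

#' On-treatment completion proportions
#'
#' Proportion of patients still on randomised treatment at the final visit
#' relative to the first visit, per arm, in percent.
#'
#' @param visit_counts a data frame shaped like
#'   `pattern_summary(data)$visit_counts` (columns `arm`, `visit`, `on`).
#' @return named numeric vector of percentages, one element per arm.
#' @export
completion_proportions <- function(visit_counts) {
  J <- max(visit_counts$visit)
  arms <- unique(visit_counts$arm)
  out <- vapply(arms, function(a) {
    sel <- visit_counts$arm == a
    100 * visit_counts$on[sel & visit_counts$visit == J] /
      visit_counts$on[sel & visit_counts$visit == 1L]
  }, numeric(1))
  names(out) <- arms
  out
}

#' Merge observed off-treatment values back into a completed dataset
#'
#' After imputation every patient-visit that was observed in the original
#' data recovers its observed value; only originally-missing cells keep
#' their imputed values. Used by the classic reference-based comparator
#' ("merge back") and as a safety net for the main pipeline.
#'
#' @param imputed a completed [trial_data] object (no missing outcomes).
#' @param original the original [trial_data] object of the same shape.
#' @return a [trial_data] object.
#' @export
merge_observed_off_treatment <- function(imputed, original) {
  stopifnot(inherits(imputed, "trial_data"), inherits(original, "trial_data"))
  if (!identical(dim(imputed$outcomes), dim(original$outcomes)))
    stop("shape mismatch between imputed and original data")
  y <- imputed$outcomes
  obs <- !is.na(original$outcomes)
  y[obs] <- original$outcomes[obs]
  out <- original
  out$outcomes <- y
  out
}
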