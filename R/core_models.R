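mu_names <- function(J) {
  as.vector(outer(seq_len(J), 0:1, function(j, t) sprintf("mu[%d,%d]", t, j)))
}

mu_col <- function(t, j, J) t * J + j  # column index of mu[t, j] in mu_names order

#' Specify a reference-based core model
#'
#' The core model states what the off-treatment mean would be if the
#' compliance data carried no information: jump to reference (`J2R`), copy
#' increments in reference (`CIR`), copy reference (`CR`), last mean carried
#' forward (`LMCF`), return to baseline (`RTB`), missing at random (`MAR`),
#' or MAR with a fixed per-visit delta (`MAR_DELTA`). With `mu[t, j]` the
#' on-treatment mean for arm `t` at visit `j`, a patient off treatment after
#' visit `k` has core mean at visit `j > k`:
#' * `J2R`: `mu[0, j]`
#' * `CIR`: `mu[0, j] + mu[t, k] - mu[0, k]`
#' * `CR`: applied to off-treatment cells only (`j > k`), which makes it
#'   coincide with `J2R` in this framework (the full copy-reference profile
#'   would also replace the on-treatment cells, which are observed here)
#' * `LMCF`: `mu[t, k]`
#' * `RTB`: the baseline mean (pooled over arms, or within arm)
#' * `MAR`: `mu[t, j]`
#' * `MAR_DELTA`: `mu[t, j] + delta[t, j - k]`
#'
#' @param kind one of `"MAR"`, `"J2R"`, `"CIR"`, `"CR"`, `"LMCF"`, `"RTB"`,
#'   `"MAR_DELTA"`.
#' @param delta for `MAR_DELTA`: a 2-row matrix (reference, active) of
#'   offsets indexed by visits since deviation (`j - k = 1, 2, ...`), in
#'   outcome units, or a vector applied to the active arm only. Defaults to
#'   zero.
#' @param rtb_pooled for `RTB`: pool the baseline mean over both arms
#'   (default) or use the within-arm mean.
#' @return an object of class `core_spec`.
#' @export
core_spec <- function(kind = c("MAR", "J2R", "CIR", "CR", "LMCF", "RTB", "MAR_DELTA"),
                      delta = NULL, rtb_pooled = TRUE) {
  kind <- match.arg(kind)
  if (kind == "MAR_DELTA") {
    if (is.null(delta)) delta <- matrix(0, 2, 1)
    if (is.vector(delta)) delta <- rbind(0, delta)
    delta <- as.matrix(delta)
    if (nrow(delta) != 2L) stop("delta must have one row per arm")
  } else if (!is.null(delta)) {
    stop("delta is only meaningful for kind = 'MAR_DELTA'")
  }
  structure(list(kind = kind, delta = delta, rtb_pooled = isTRUE(rtb_pooled)),
            class = "core_spec")
}

#' Specify a retrieved-dropout compliance model
#'
#' The compliance model indexes the off-treatment means: `current` by
#' on/off status at the current visit (one mean per arm and visit),
#' `historic` by the last-on-treatment visit so far (one mean per arm,
#' deviation visit and visit), `full_pattern` by the subject-level
#' deviation pattern. Because the deviation design only exists on
#' off-treatment rows, where the running pattern equals the subject
#' pattern, `full_pattern` coincides with `historic` here and is provided
#' as a flagged alias.
#'
#' @param kind one of `"historic"`, `"current"`, `"full_pattern"`.
#' @return an object of class `compliance_spec`.
#' @export
compliance_spec <- function(kind = c("historic", "current", "full_pattern")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "compliance_spec")
}

delta_at <- function(core, t, lag) {
  d <- core$delta
  if (is.null(d)) return(0)
  d[t + 1L, min(lag, ncol(d))]  # last delta carried on beyond the stated vector
}

#' Core-implied off-treatment mean as weights on the on-treatment means
#'
#' Returns the linear functional (weights `w` over the `2J` cell means
#' `mu[t, j]`, plus a constant) whose value is the core model's implied
#' off-treatment mean for a patient in arm `t` who deviated after visit
#' `k`, evaluated at visit `j > k`. The constant carries the `MAR_DELTA`
#' offset; for `RTB` the weights are zero and the constant is filled in by
#' the caller from the baseline mean (`rtb = TRUE` marks this).
#'
#' @param core a [core_spec].
#' @param t arm (0 reference, 1 active).
#' @param k deviation visit.
#' @param j visit, `j > k`.
#' @param J number of visits.
#' @return list with `w` (length `2J`), `const`, `rtb` (logical).
#' @keywords internal
core_offset_weights <- function(core, t, k, j, J) {
  if (j <= k) stop("core offset is defined for j > k only")
  w <- numeric(2L * J)
  const <- 0
  rtb <- FALSE
  switch(core$kind,
    J2R = , CR = { w[mu_col(0L, j, J)] <- 1 },
    CIR = {
      w[mu_col(0L, j, J)] <- w[mu_col(t, k, J)] <- 1
      w[mu_col(0L, k, J)] <- w[mu_col(0L, k, J)] - 1
    },
    LMCF = { w[mu_col(t, k, J)] <- 1 },
    MAR = { w[mu_col(t, j, J)] <- 1 },
    MAR_DELTA = {
      w[mu_col(t, j, J)] <- 1
      const <- delta_at(core, t, j - k)
    },
    RTB = { rtb <- TRUE }
  )
  names(w) <- mu_names(J)
  list(w = w, const = const, rtb = rtb)
}

#' Evaluate a core model's implied off-treatment mean
#'
#' @param core a [core_spec].
#' @param mu on-treatment mean matrix, 2 rows (reference, active) by `J`
#'   visits.
#' @param baseline_means named vector with elements `pooled`, `reference`,
#'   `active` (only used for `RTB`; may be `NULL` otherwise).
#' @param t arm (0/1), `k` deviation visit, `j` visit with `j > k`.
#' @param k,j integers.
#' @return the implied mean, a scalar.
#' @export
core_offset_means <- function(core, mu, baseline_means = NULL, t, k, j) {
  mu <- as.matrix(mu)
  J <- ncol(mu)
  ow <- core_offset_weights(core, t, k, j, J)
  if (ow$rtb) {
    if (is.null(baseline_means)) stop("RTB needs baseline_means")
    key <- if (core$rtb_pooled) "pooled" else c("reference", "active")[t + 1L]
    return(unname(baseline_means[[key]]))
  }
  unname(sum(ow$w * c(mu[1L, ], mu[2L, ])) + ow$const)
}

dev_levels <- function(compliance, J) {
  # coefficient labels for the deviation block: (t, k, j) or (t, j)
  if (compliance$kind == "current") {
    g <- expand.grid(j = 2:J, t = 0:1)
    data.frame(t = g$t, k = NA_integer_, j = g$j,
               name = sprintf("alpha*[%d,%d]", g$t, g$j))
  } else {
    g <- expand.grid(j = seq_len(J), k = seq_len(J - 1L), t = 0:1)
    g <- g[g$j > g$k, , drop = FALSE]
    data.frame(t = g$t, k = g$k, j = g$j,
               name = sprintf("gamma*[%d,%d,%d]", g$t, g$k, g$j))
  }
}

#' Check that a core model is nested within a compliance model
#'
#' The extended imputation model is the core model plus free deviation
#' parameters, one per compliance-model level. For the compliance model to
#' be recoverable as the diffuse-prior special case, each on-treatment mean
#' parameter's footprint on the off-treatment cells (and any fixed core
#' constant, e.g. the `MAR_DELTA` offsets) must be absorbable by the
#' deviation columns. Cores whose off-treatment mean depends on the
#' deviation visit `k` (CIR, LMCF, MAR with a nonzero delta) therefore fail
#' with the `current` compliance model, whose deviation levels are shared
#' across `k`, and pass with `historic`, which has one level per cell.
#' The check is numerical: per cell functional, the least-squares residual
#' after projecting onto the deviation columns must vanish (relative
#' tolerance `tol`).
#'
#' @param core a [core_spec].
#' @param compliance a [compliance_spec].
#' @param J number of visits.
#' @param tol relative residual tolerance.
#' @return list with `ok` (logical) and `offending` (data frame of cells
#'   `(t, k, j)` whose core mean cannot be absorbed).
#' @export
check_nesting <- function(core, compliance, J, tol = 1e-8) {
  stopifnot(inherits(core, "core_spec"), inherits(compliance, "compliance_spec"))
  cells <- expand.grid(j = seq_len(J), k = seq_len(J - 1L), t = 0:1)
  cells <- cells[cells$j > cells$k, , drop = FALSE]
  nc <- nrow(cells)
  # off-cell coefficient matrix: 2J mu columns + one constant column
  O <- matrix(0, nc, 2L * J + 1L)
  for (r in seq_len(nc)) {
    ow <- core_offset_weights(core, cells$t[r], cells$k[r], cells$j[r], J)
    # RTB: structural stand-in constants, distinct per arm when not pooled
    cst <- if (ow$rtb) { if (core$rtb_pooled) 1 else 1 + cells$t[r] } else ow$const
    O[r, ] <- c(ow$w, cst)
  }
  lv <- dev_levels(compliance, J)
  Dm <- matrix(0, nc, nrow(lv))
  for (cidx in seq_len(nrow(lv))) {
    hit <- cells$t == lv$t[cidx] & cells$j == lv$j[cidx] &
      (is.na(lv$k[cidx]) | cells$k == lv$k[cidx])
    Dm[hit, cidx] <- 1
  }
  qrD <- qr(Dm)
  res <- O - qr.fitted(qrD, O)
  colnorm <- sqrt(colSums(O^2))
  bad_col <- sqrt(colSums(res^2)) > tol * pmax(colnorm, 1)
  bad_cell <- rowSums(abs(res[, bad_col, drop = FALSE])) > tol
  offending <- cells[bad_cell, c("t", "k", "j"), drop = FALSE]
  rownames(offending) <- NULL
  list(ok = nrow(offending) == 0L, offending = offending)
}

#' Nesting matrix over core and compliance model choices
#'
#' @param J number of visits.
#' @param delta nonzero delta matrix used for the `MAR_DELTA` row.
#' @return logical matrix, cores by compliance kinds.
#' @export
nesting_matrix <- function(J = 4L, delta = rbind(0, seq_len(J - 1L) * 2)) {
  cores <- c("J2R", "CIR", "CR", "LMCF", "RTB", "MAR", "MAR_DELTA")
  comps <- c("current", "historic")
  out <- matrix(NA, length(cores), length(comps), dimnames = list(cores, comps))
  for (co in cores) for (cm in comps) {
    cs <- if (co == "MAR_DELTA") core_spec(co, delta = delta) else core_spec(co)
    out[co, cm] <- check_nesting(cs, compliance_spec(cm), J)$ok
  }
  out
}
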