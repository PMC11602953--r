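#' Longitudinal trial data with treatment-deviation bookkeeping
#'
#' Container for a two-arm longitudinal trial with `J` post-baseline visits.
#' Each patient carries an outcome vector (change from baseline, possibly
#' with missing values), a baseline covariate, the randomised arm, the last
#' visit on randomised treatment `D` (the deviation visit; `J` for patients
#' who complete on treatment) and the last visit with any observed outcome
#' `S` (`J` for study completers). Patients stop treatment no later than
#' they leave the study, so `S >= D` always. Outcomes at visits `D < j <= S`
#' are the observed off-treatment ("retrieved dropout") values; outcomes
#' after `S` are missing. Intermediate missing values at visits `j <= S`
#' are permitted and treated as missing at random by the imputation engine.
#'
#' @param outcomes numeric matrix, one row per patient, `J` columns
#'   (`NA` = missing).
#' @param arm integer vector of 0 (reference) / 1 (active), or a vector of
#'   labels matching `arm_labels`.
#' @param baseline numeric vector of baseline covariate values.
#' @param deviation_visit integer vector `D` in `1..J`, or `NULL` to derive
#'   it as the last visit with an observed outcome (i.e. treat every
#'   observed value as on-treatment).
#' @param last_study_visit integer vector `S` in `1..J`, or `NULL` to derive
#'   it as `max(D, last visit with an observed outcome)`.
#' @param subject_id optional identifiers (default `1..N` as character).
#' @param arm_labels named character vector with elements `reference` and
#'   `active`.
#'
#' @return An object of class `trial_data`: a list with elements
#'   `outcomes`, `arm`, `baseline`, `deviation_visit`, `last_study_visit`,
#'   `subject_id`, `n_visits`, `arm_labels`.
#' @export
trial_data <- function(outcomes, arm, baseline,
                       deviation_visit = NULL, last_study_visit = NULL,
                       subject_id = NULL,
                       arm_labels = c(reference = "reference", active = "active")) {
  outcomes <- as.matrix(outcomes)
  storage.mode(outcomes) <- "double"
  N <- nrow(outcomes)
  J <- ncol(outcomes)
  if (J < 2L) stop("at least two visits are required (J >= 2)")
  if (!all(c("reference", "active") %in% names(arm_labels)))
    stop("arm_labels must name 'reference' and 'active'")
  arm_labels <- arm_labels[c("reference", "active")]

  if (!is.numeric(arm)) {
    lab <- as.character(arm)
    bad <- setdiff(unique(lab), unname(arm_labels))
    if (length(bad)) stop("unknown arm label(s): ", paste(bad, collapse = ", "))
    arm <- as.integer(lab == arm_labels[["active"]])
  }
  arm <- as.integer(arm)
  if (!all(arm %in% c(0L, 1L))) stop("arm must be coded 0 (reference) / 1 (active)")
  if (length(arm) != N) stop("length(arm) != number of patients")
  if (!all(c(0L, 1L) %in% arm)) stop("both arms must be present")

  baseline <- as.numeric(baseline)
  if (length(baseline) != N) stop("length(baseline) != number of patients")
  if (anyNA(baseline)) stop("missing baseline values are not supported")

  last_obs <- apply(outcomes, 1L, function(y) {
    w <- which(!is.na(y))
    if (length(w)) max(w) else 0L
  })
  if (any(last_obs == 0L)) stop("every patient needs at least one observed outcome")

  if (is.null(deviation_visit)) {
    D <- last_obs
  } else {
    D <- as.integer(deviation_visit)
    if (length(D) != N || any(D < 1L | D > J)) stop("deviation_visit must lie in 1..J")
  }
  if (is.null(last_study_visit)) {
    S <- pmax(D, last_obs)
  } else {
    S <- as.integer(last_study_visit)
    if (length(S) != N || any(S < 1L | S > J)) stop("last_study_visit must lie in 1..J")
  }
  if (any(S < D)) stop("last_study_visit < deviation_visit (S < D) for some patients")
  # after leaving the study nothing may be observed (monotone beyond S)
  if (any(last_obs > S)) stop("observed outcomes found after last_study_visit")

  if (is.null(subject_id)) subject_id <- as.character(seq_len(N))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject_id")

  structure(list(outcomes = outcomes, arm = arm, baseline = baseline,
                 deviation_visit = D, last_study_visit = S,
                 subject_id = subject_id, n_visits = J,
                 arm_labels = arm_labels),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  N <- length(x$arm)
  cat(sprintf("trial_data: %d patients (%d %s, %d %s), %d visits\n",
              N, sum(x$arm == 0L), x$arm_labels[["reference"]],
              sum(x$arm == 1L), x$arm_labels[["active"]], x$n_visits))
  nm <- sum(is.na(x$outcomes))
  cat(sprintf("  deviators: %d; missing outcome cells: %d (%.1f%%)\n",
              sum(x$deviation_visit < x$n_visits), nm,
              100 * nm / length(x$outcomes)))
  invisible(x)
}

#' Number of patients in a trial_data object
#' @param x a `trial_data` object.
#' @return integer patient count.
#' @export
n_patients <- function(x) length(x$arm)

default_schema <- function() {
  list(subject = "subject", arm = "arm", visit = "visit", outcome = "outcome",
       baseline = "baseline", offtrt = "offtrt", deviation = "deviation_visit")
}

#' Read long-format trial data from CSV
#'
#' Expects one row per (subject, visit) with columns for subject id, arm
#' label, visit index (1..J), outcome (empty string = missing) and baseline.
#' Treatment status comes either from a per-visit on/off flag column
#' (0 = on treatment, 1 = off) or a per-subject deviation-visit column;
#' when neither is present, the deviation visit is the last observed visit.
#'
#' @param path CSV file path.
#' @param schema named list mapping the roles `subject`, `arm`, `visit`,
#'   `outcome`, `baseline`, and optionally `offtrt` or `deviation`, to
#'   column names. Unspecified roles use the defaults from the writer.
#' @param arm_labels named character vector (`reference`, `active`) giving
#'   the labels used in the arm column.
#' @return a [trial_data] object.
#' @export
load_trial_csv <- function(path, schema = list(),
                           arm_labels = c(reference = "reference", active = "active")) {
  sc <- utils::modifyList(default_schema(), schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("subject", "arm", "visit", "outcome", "baseline")
  miss <- vapply(need, function(r) !(sc[[r]] %in% names(df)), logical(1))
  if (any(miss)) stop("missing column(s): ",
                      paste(unlist(sc[need][miss]), collapse = ", "))

  subj <- as.character(df[[sc$subject]])
  visit <- as.integer(df[[sc$visit]])
  ids <- unique(subj)
  J <- max(visit)
  if (any(visit < 1L)) stop("visit outside 1..J")
  if (anyDuplicated(paste(subj, visit, sep = "\r"))) stop("duplicate (subject, visit) rows")

  idx_i <- match(subj, ids)
  N <- length(ids)
  outcomes <- matrix(NA_real_, N, J)
  outcomes[cbind(idx_i, visit)] <- as.numeric(df[[sc$outcome]])

  first <- !duplicated(idx_i)
  arm_lab <- character(N); arm_lab[idx_i[first]] <- as.character(df[[sc$arm]])[first]
  base <- numeric(N); base[idx_i[first]] <- as.numeric(df[[sc$baseline]])[first]

  D <- NULL
  if (sc$offtrt %in% names(df)) {
    off <- matrix(NA_integer_, N, J)
    off[cbind(idx_i, visit)] <- as.integer(df[[sc$offtrt]])
    D <- apply(off, 1L, function(o) {
      on <- which(!is.na(o) & o == 0L)
      if (!length(on)) stop("patient with no on-treatment visit")
      k <- max(on)
      later_on <- which(!is.na(o) & o == 0L & seq_along(o) > k)
      if (length(later_on)) stop("on-treatment flag after an off-treatment visit")
      k
    })
  } else if (sc$deviation %in% names(df)) {
    D <- integer(N); D[idx_i[first]] <- as.integer(df[[sc$deviation]])[first]
  }
  trial_data(outcomes, arm_lab, base, deviation_visit = D,
             subject_id = ids, arm_labels = arm_labels)
}

#' Write trial data to long-format CSV
#'
#' Emits the same dialect the reader accepts: comma separated, header row,
#' empty string for missing outcomes, one row per (subject, visit) with a
#' per-visit off-treatment flag.
#'
#' @param data a [trial_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  J <- data$n_visits
  N <- n_patients(data)
  df <- data.frame(
    subject = rep(data$subject_id, each = J),
    arm = rep(data$arm_labels[data$arm + 1L], each = J),
    visit = rep(seq_len(J), N),
    outcome = as.vector(t(data$outcomes)),
    baseline = rep(data$baseline, each = J),
    offtrt = as.integer(rep(seq_len(J), N) > rep(data$deviation_visit, each = J)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
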