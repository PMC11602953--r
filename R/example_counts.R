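#' Published visit-wise counts of the antidepressant example datasets
#'
#' The per-visit on-treatment / observed off-treatment / missing
#' off-treatment frequencies of the two publicly available antidepressant
#' example datasets ("covered" and "perforated") distributed through the
#' DIA Scientific Working Group on Estimands and Missing Data (hosted on
#' the LSHTM missing-data page). Both share the on-treatment layout
#' (88 reference, 84 active patients, 4 post-baseline visits) and differ
#' only in how the off-treatment missingness is arranged; the perforated
#' layout has no observed off-treatment data for the active patients who
#' deviate after visit 1.
#'
#' @param dataset `"covered"` or `"perforated"`.
#' @return data frame with columns `arm`, `visit`, `on`, `off_obs`,
#'   `off_miss`, in the shape of `pattern_summary()$visit_counts`.
#' @export
example_visit_counts <- function(dataset = c("covered", "perforated")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", "antidepressant_visit_counts.csv",
                      package = "rdrcmi", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- df[df$dataset == dataset, c("arm", "visit", "on", "off_obs", "off_miss")]
  rownames(out) <- NULL
  out
}
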