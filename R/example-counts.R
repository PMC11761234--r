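#' Reference recognition counts
#'
#' Moderate-or-severe recognition counts from a 24-patient facial-asymmetry
#' cohort assessed with both methods (mirroring-and-overlapping under the
#' three deviation criteria, and the wireframe template under the AAI
#' criterion), shipped as package data. These counts are the canonical input
#' for the counts-replay consistency tables.
#'
#' @param level `"overall"` (per region) or `"dimension"` (per region and
#'   axis).
#' @param criterion Optional filter: 1, 2 or 3.
#' @return A tibble with columns `region` (, `axis`), `criterion`,
#'   `mirror_n`, `template_n`, `n`.
#' @export
reference_recognition_counts <- function(level = c("overall", "dimension"),
                                         criterion = NULL) {
  level <- match.arg(level)
  path <- system.file("extdata",
                      paste0("recognition_counts_", level, ".csv"),
                      package = "faceasym", mustWork = TRUE)
  counts <- read_table(path)
  if (!is.null(criterion)) {
    counts <- counts[counts$criterion %in% criterion, ]
  }
  counts
}
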