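#' Grading criterion
#'
#' A three-level severity criterion over a non-negative asymmetry statistic:
#' `[0, lower) = mild`, `[lower, upper) = moderate`, `[upper, Inf) = severe`.
#'
#' @param name Identifier (`rmse_criterion`, `mfm_wide`, `mfm_narrow`, `aai`,
#'   or a custom name).
#' @param statistic Which summary is thresholded: `"RMSE"`, `"MFM"` or
#'   `"AAI"`.
#' @param lower_cut Mild/moderate threshold.
#' @param upper_cut Moderate/severe threshold.
#' @param units `"mm"` or `"percent"`.
#' @return A list of class `grading_criterion`.
#' @export
grading_criterion <- function(name, statistic, lower_cut, upper_cut, units) {
  statistic <- match.arg(statistic, c("RMSE", "MFM", "AAI"))
  units <- match.arg(units, c("mm", "percent"))
  if (!(0 < lower_cut && lower_cut < upper_cut)) {
    abort("Thresholds must satisfy 0 < lower_cut < upper_cut.")
  }
  structure(list(name = name, statistic = statistic, lower_cut = lower_cut,
                 upper_cut = upper_cut, units = units),
            class = "grading_criterion")
}

#' @export
print.grading_criterion <- function(x, ...) {
  cat(sprintf("<grading_criterion %s: %s, mild < %g %s <= moderate < %g %s <= severe>\n",
              x$name, x$statistic, x$lower_cut, x$units, x$upper_cut, x$units))
  invisible(x)
}

#' Standard grading criteria
#'
#' The four criteria used to grade regional facial asymmetry:
#' \describe{
#'   \item{1 / `rmse_criterion`}{RMSE: mild < 0.5 mm, moderate < 1 mm,
#'     severe >= 1 mm.}
#'   \item{2 / `mfm_wide`}{MFM: mild < 3 mm, moderate < 6 mm,
#'     severe >= 6 mm.}
#'   \item{3 / `mfm_narrow`}{MFM: mild < 1 mm, moderate < 2 mm,
#'     severe >= 2 mm.}
#'   \item{`aai`}{Angle Asymmetry Index: mild < 1 percent, moderate < 3
#'     percent, severe >= 3 percent.}
#' }
#'
#' @param which A criterion name, or 1, 2, 3 for the deviation-based criteria.
#'   Omit to get the full named list.
#' @return A [grading_criterion()] (or named list of all four).
#' @export
grading_criteria <- function(which = NULL) {
  all <- list(
    rmse_criterion = grading_criterion("rmse_criterion", "RMSE", 0.5, 1, "mm"),
    mfm_wide = grading_criterion("mfm_wide", "MFM", 3, 6, "mm"),
    mfm_narrow = grading_criterion("mfm_narrow", "MFM", 1, 2, "mm"),
    aai = grading_criterion("aai", "AAI", 1, 3, "percent")
  )
  if (is.null(which)) return(all)
  if (is.numeric(which)) {
    which <- c("rmse_criterion", "mfm_wide", "mfm_narrow")[which]
  }
  if (is.na(which) || !which %in% names(all)) {
    abort("Unknown grading criterion.")
  }
  all[[which]]
}

#' Classify a statistic into a severity grade
#'
#' Half-open interval mapping: values below `lower_cut` are mild, values in
#' `[lower_cut, upper_cut)` moderate, and values at or above `upper_cut`
#' severe.
#'
#' @param value Non-negative statistic value(s).
#' @param criterion A [grading_criterion()].
#' @return A [severity_grade()] vector.
#' @export
classify_statistic <- function(value, criterion) {
  stopifnot(inherits(criterion, "grading_criterion"))
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("Statistic values must be finite and non-negative.")
  }
  out <- ifelse(value < criterion$lower_cut, "mild",
                ifelse(value < criterion$upper_cut, "moderate", "severe"))
  severity_grade(out)
}

#' Grade a mirror-overlap summary under a deviation criterion
#'
#' Attaches a per-(region, axis) severity grade to the summary of a
#' [mirror_overlap_analysis()], thresholding RMSE or MFM as the criterion
#' dictates, and appends a per-region aggregate row (`axis = "region"`) using
#' the all-mild rule of [aggregate_region()] over X, Y, Z.
#'
#' @param summary The `summary` tibble of a `mirror_analysis` (or the object
#'   itself).
#' @param criterion A deviation-based [grading_criterion()] (statistic RMSE
#'   or MFM).
#' @return A tibble with columns `region`, `axis`, `value`, `grade`.
#' @export
grade_deviation <- function(summary, criterion = grading_criteria("mfm_narrow")) {
  if (inherits(summary, "mirror_analysis")) summary <- summary$summary
  stopifnot(inherits(criterion, "grading_criterion"))
  stat_col <- if (criterion$statistic == "RMSE") "rmse" else "mfm"
  ax <- summary[summary$axis %in% AXES, c("region", "axis", stat_col)]
  names(ax)[3] <- "value"
  ax$grade <- classify_statistic(ax$value, criterion)
  agg <- ax |>
    group_by(.data$region) |>
    summarise(axis = "region", value = NA_real_,
              grade = aggregate_region(.data$grade), .groups = "drop")
  bind_rows(ax, agg[, c("region", "axis", "value", "grade")]) |>
    arrange(match(.data$region, REGIONS))
}
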