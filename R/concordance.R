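#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' all printed percentage tables; base `round()` rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Recognition rate
#'
#' The fraction of subjects graded moderate or severe. The exact counts are
#' kept alongside the rate so downstream consistency rates can be computed on
#' exact rationals.
#'
#' @param grades A vector of severity grades.
#' @return A one-row tibble with `numerator`, `denominator`, `rate`.
#' @export
recognition_rate <- function(grades) {
  grades <- severity_grade(grades)
  if (length(grades) == 0) abort("Recognition rate of an empty grade list.")
  num <- sum(grades %in% c("moderate", "severe"))
  tibble(numerator = num, denominator = length(grades),
         rate = num / length(grades))
}

#' Consistency rate between two recognition rates
#'
#' The smaller recognition rate divided by the larger, times 100. This single
#' expression covers both directions of the ratio (whichever method
#' recognises fewer subjects forms the numerator). Computed on exact
#' rationals; not rounded here.
#'
#' @param rate_a,rate_b Either one-row tibbles from [recognition_rate()] or
#'   plain proportions in `[0, 1]`.
#' @return Consistency in percent, in `(0, 100]`; `NA` (flagged undefined)
#'   when both rates are zero.
#' @export
consistency_rate <- function(rate_a, rate_b) {
  getr <- function(r) if (is.data.frame(r)) r$rate else as.numeric(r)
  a <- getr(rate_a)
  b <- getr(rate_b)
  if (any(a < 0 | a > 1 | b < 0 | b > 1)) {
    abort("Recognition rates must lie in [0, 1].")
  }
  out <- pmin(a, b) / pmax(a, b) * 100
  out[a == 0 & b == 0] <- NA_real_
  out
}

#' Grade matrix
#'
#' Long-format container for per-subject severity grades: one row per
#' (subject, region, axis), with `axis` one of `X`, `Y`, `Z` or `"region"`
#' for the per-region aggregate. Validates completeness and, when axis rows
#' are present, that each aggregate equals [aggregate_region()] of its three
#' axis grades.
#'
#' @param df Data frame with columns `subject`, `region`, `axis`, `grade`,
#'   and optionally `method`.
#' @param method_tag Optional method label stored in a `method` column.
#' @return A tibble of class `grade_matrix`.
#' @export
grade_matrix <- function(df, method_tag = NULL) {
  df <- as_tibble(df)
  stopifnot(all(c("subject", "region", "axis", "grade") %in% names(df)))
  df$grade <- severity_grade(df$grade)
  if (!all(df$region %in% REGIONS)) abort("Unknown region in grade matrix.")
  if (!all(df$axis %in% c(AXES, "region"))) {
    abort("`axis` must be X, Y, Z or 'region'.")
  }
  if (!is.null(method_tag)) df$method <- method_tag
  # completeness: every subject has the same (region, axis) cells
  cells <- table(df$subject, paste(df$region, df$axis))
  if (any(cells != 1)) {
    abort("Grade matrix is incomplete or has duplicate (subject, region, axis) cells.")
  }
  # aggregate consistency where both axis and aggregate rows exist
  has_axes <- any(df$axis %in% AXES)
  has_agg <- any(df$axis == "region")
  if (has_axes && has_agg) {
    chk <- df |>
      filter(.data$axis %in% AXES) |>
      group_by(.data$subject, .data$region) |>
      summarise(expected = aggregate_region(.data$grade), .groups = "drop")
    agg <- df[df$axis == "region", c("subject", "region", "grade")]
    m <- left_join(agg, chk, by = c("subject", "region"))
    if (any(as.character(m$grade) != as.character(m$expected))) {
      abort("Aggregate region grades disagree with their axis grades.")
    }
  }
  class(df) <- unique(c("grade_matrix", class(df)))
  df
}

check_same_subjects <- function(a, b) {
  if (!setequal(unique(a$subject), unique(b$subject))) {
    abort("The two grade matrices cover different subjects.")
  }
}

counts_by <- function(gm, by) {
  gm |>
    group_by(across(all_of(by))) |>
    summarise(numerator = sum(.data$grade %in% c("moderate", "severe")),
              denominator = n(), .groups = "drop")
}

#' Consistency table from recognition counts
#'
#' The counts-replay entry point: builds a per-group consistency table
#' directly from moderate-or-severe recognition counts of the two methods,
#' without meshes or landmarks. Rates are exact rationals; consistency is
#' rounded half-up to one decimal for display, with the unrounded value kept
#' in `consistency_exact`.
#'
#' @param counts A data frame with grouping columns (`region`, optionally
#'   `axis`), counts `mirror_n` and `template_n`, and a common denominator
#'   column `n` (or a single `n` value passed separately).
#' @param n Denominator (number of subjects) if not a column of `counts`.
#' @param average Append an `average` row with the mean of the exact
#'   per-group consistencies, rounded half-up (default `TRUE` for
#'   region-level tables).
#' @return A tibble with recognition rates and consistency per group.
#' @export
consistency_from_counts <- function(counts, n = NULL, average = "region" %in%
                                      names(counts) && !"axis" %in% names(counts)) {
  counts <- as_tibble(counts)
  if (!"n" %in% names(counts)) {
    if (is.null(n)) abort("Provide the denominator `n`.")
    counts$n <- n
  }
  stopifnot(all(c("mirror_n", "template_n") %in% names(counts)))
  out <- counts |>
    mutate(
      mirror_rate = .data$mirror_n / .data$n,
      template_rate = .data$template_n / .data$n,
      consistency_exact = consistency_rate(.data$mirror_rate,
                                           .data$template_rate),
      consistency = round_half_up(.data$consistency_exact, 1)
    )
  if (isTRUE(average)) {
    avg <- tibble(region = "average",
                  consistency_exact = mean(out$consistency_exact),
                  consistency = round_half_up(mean(out$consistency_exact), 1))
    out <- bind_rows(out, avg)
  }
  out
}

#' Overall consistency table (per region)
#'
#' Per-region moderate-or-severe recognition rates of the two methods and
#' their consistency rate, with an average row — the region-level agreement
#' table comparing mirroring-and-overlapping grades against wireframe
#' template grades.
#'
#' @param mirror_grades,template_grades `grade_matrix` objects with
#'   `axis = "region"` rows (aggregates are computed from axis rows if
#'   absent).
#' @return A consistency tibble (see [consistency_from_counts()]).
#' @export
build_overall_table <- function(mirror_grades, template_grades) {
  check_same_subjects(mirror_grades, template_grades)
  pick_region_rows <- function(gm) {
    if (any(gm$axis == "region")) {
      gm[gm$axis == "region", ]
    } else {
      gm |>
        group_by(.data$subject, .data$region) |>
        summarise(grade = aggregate_region(.data$grade), .groups = "drop")
    }
  }
  mc <- counts_by(pick_region_rows(mirror_grades), "region")
  tc <- counts_by(pick_region_rows(template_grades), "region")
  counts <- left_join(
    rename(mc, mirror_n = "numerator", n = "denominator"),
    rename(tc, template_n = "numerator", n2 = "denominator"),
    by = "region"
  )
  if (any(counts$n != counts$n2)) abort("Subject counts differ between methods.")
  counts <- counts[, c("region", "mirror_n", "template_n", "n")]
  counts <- counts[order(match(counts$region, REGIONS)), ]
  consistency_from_counts(counts, average = TRUE)
}

#' Per-dimension consistency table (region x axis)
#'
#' As [build_overall_table()] but at (region, axis) granularity: 15 rows, no
#' average row.
#'
#' @inheritParams build_overall_table
#' @return A consistency tibble with `region` and `axis` columns.
#' @export
build_dimension_table <- function(mirror_grades, template_grades) {
  check_same_subjects(mirror_grades, template_grades)
  ax <- function(gm) gm[gm$axis %in% AXES, ]
  mc <- counts_by(ax(mirror_grades), c("region", "axis"))
  tc <- counts_by(ax(template_grades), c("region", "axis"))
  counts <- left_join(
    rename(mc, mirror_n = "numerator", n = "denominator"),
    rename(tc, template_n = "numerator", n2 = "denominator"),
    by = c("region", "axis")
  )
  if (any(counts$n != counts$n2)) abort("Subject counts differ between methods.")
  counts <- counts[, c("region", "axis", "mirror_n", "template_n", "n")]
  counts <- counts[order(match(counts$region, REGIONS), counts$axis), ]
  consistency_from_counts(counts, average = FALSE)
}

#' Cohen's kappa
#'
#' Unweighted Cohen's kappa between two parallel label vectors,
#' `kappa = (p_o - p_e) / (1 - p_e)`, over the union of observed categories.
#' When chance agreement is 1 (both raters constant), kappa is defined as 1
#' if the labels agree everywhere and 0 otherwise.
#'
#' @param labels_a,labels_b Equal-length vectors (severity grades or any
#'   categorical labels).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.")
  }
  if (length(labels_a) < 2) abort("Kappa needs at least 2 paired labels.")
  lev <- sort(unique(c(labels_a, labels_b)))
  tab <- table(factor(labels_a, levels = lev), factor(labels_b, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(if (po >= 1 - 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Kappa table for repeated wireframe measurements
#'
#' Cohen's kappa per (region, axis) between two repeated gradings, the
#' repeatability analysis of the template method.
#'
#' @param grades_1,grades_2 `grade_matrix` objects of the two measurement
#'   sessions (axis rows).
#' @return A tibble with `region`, `axis`, `kappa`.
#' @export
kappa_table <- function(grades_1, grades_2) {
  check_same_subjects(grades_1, grades_2)
  a <- grades_1[grades_1$axis %in% AXES, ]
  b <- grades_2[grades_2$axis %in% AXES, ]
  key <- function(d) paste(d$subject, d$region, d$axis)
  b <- b[match(key(a), key(b)), ]
  a |>
    mutate(grade_b = b$grade) |>
    group_by(.data$region, .data$axis) |>
    summarise(kappa = cohen_kappa(.data$grade, .data$grade_b),
              .groups = "drop") |>
    arrange(match(.data$region, REGIONS), .data$axis)
}
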