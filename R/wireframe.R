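#' Angular parameter registry
#'
#' The 15 spatial-angle parameters of the wireframe template: one ordered
#' landmark triplet (A, B, C) per region and axis, the angle being measured
#' at vertex B. Two triplets serve double duty (`Tr-Zg-Go` for mandibular
#' angle Y and articular Y; `Me-Go-Mt` for mandibular angle X and chin Z):
#' they are computed once and referenced twice.
#'
#' @return A 15-row tibble with columns `region`, `axis`, `a`, `b`, `c` and
#'   `parameter` (the display label `"A-B-C"`).
#' @export
angular_parameters <- function() {
  p <- tibble::tribble(
    ~region,            ~axis, ~a,    ~b,   ~c,
    "labial",           "X",  "Sal", "Ch", "Stb",
    "labial",           "Y",  "Sal", "Go", "Ch",
    "labial",           "Z",  "Sal", "Ch", "As",
    "mandibular_angle", "X",  "Me",  "Go", "Mt",
    "mandibular_angle", "Y",  "Tr",  "Zg", "Go",
    "mandibular_angle", "Z",  "Zg",  "Tr", "Go",
    "cheek",            "X",  "Ex",  "Zg", "Sal",
    "cheek",            "Y",  "Zg",  "Tr", "He",
    "cheek",            "Z",  "Tr",  "Zg", "Ex",
    "chin",             "X",  "Gn",  "Mt", "Me",
    "chin",             "Y",  "Li",  "Mt", "Gn",
    "chin",             "Z",  "Me",  "Go", "Mt",
    "articular",        "X",  "Ex",  "Tr", "Go",
    "articular",        "Y",  "Tr",  "Zg", "Go",
    "articular",        "Z",  "Tr",  "Go", "Zg"
  )
  p$parameter <- paste(p$a, p$b, p$c, sep = "-")
  p
}

#' Spatial angle at a landmark triplet
#'
#' The full 3D angle at vertex B between segments B->A and B->C, in degrees.
#' Bilateral landmark names are resolved with the side suffix; midline names
#' resolve as-is, so e.g. the "left" chin-X angle Gn-Mt-Me uses `Gn`,
#' `Mt_L`, `Me`.
#'
#' @param landmarks A `landmark_set`.
#' @param triplet Character vector `c(A, B, C)` of base landmark names.
#' @param side `"left"` or `"right"`.
#' @param vocabulary Landmark registry used for side resolution.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
compute_angle <- function(landmarks, triplet, side = c("left", "right"),
                          vocabulary = landmark_vocabulary()) {
  side <- match.arg(side)
  stopifnot(length(triplet) == 3)
  ids <- vapply(triplet, resolve_landmark_id, "", side = side,
                vocabulary = vocabulary)
  a <- lm_xyz(landmarks, ids[1])
  b <- lm_xyz(landmarks, ids[2])
  c_ <- lm_xyz(landmarks, ids[3])
  u <- a - b
  v <- c_ - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    abort(paste0("Degenerate geometry: zero-length arm in angle ",
                 paste(ids, collapse = "-")))
  }
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Angle Asymmetry Index
#'
#' The relative right-left difference of a bilateral angle:
#' `AAI = |R - L| / L x 100` (percent). The denominator is the
#' anatomical-left angle by convention; set `denominator = "min"` for the
#' symmetric variant.
#'
#' @param left_deg,right_deg Angles in degrees; `left_deg` must be positive.
#' @param denominator `"left"` (default) or `"min"`.
#' @return AAI in percent (>= 0).
#' @export
compute_aai <- function(left_deg, right_deg, denominator = c("left", "min")) {
  denominator <- match.arg(denominator)
  if (any(left_deg <= 0)) abort("Left angle must be positive.")
  den <- switch(denominator, left = left_deg, min = pmin(left_deg, right_deg))
  abs(right_deg - left_deg) / den * 100
}

#' Classify an AAI value
#'
#' @param aai_percent Non-negative AAI value(s) in percent.
#' @param criterion A [grading_criterion()], default the AAI criterion
#'   (mild < 1, moderate < 3, severe >= 3).
#' @return A [severity_grade()] vector.
#' @export
classify_aai <- function(aai_percent, criterion = grading_criteria("aai")) {
  classify_statistic(aai_percent, criterion)
}

#' Aggregate three axis grades into a region grade
#'
#' A region is mild only when all three of its axis grades are mild;
#' otherwise the region takes the worst (maximum) of the three grades.
#'
#' @param grades Exactly three severity grades (X, Y, Z of one region).
#' @return A single [severity_grade()].
#' @export
aggregate_region <- function(grades) {
  grades <- severity_grade(grades)
  if (length(grades) != 3) {
    abort("aggregate_region() needs exactly three axis grades.")
  }
  severity_grade(GRADES[max(as.integer(grades))])
}

#' Wireframe template analysis
#'
#' Evaluates all 15 angular parameters of the template on a landmark set:
#' the left and right spatial angles of each (region, axis) triplet, the
#' Angle Asymmetry Index, and its severity grade. Duplicated triplets are
#' computed once and referenced by both rows.
#'
#' @param landmarks A `landmark_set` containing every landmark referenced by
#'   the template on both sides.
#' @param criterion AAI grading criterion, see [grading_criteria()].
#' @param denominator Passed to [compute_aai()].
#' @param vocabulary Landmark registry for side resolution.
#' @return A tibble of class `wireframe_result` with 15 rows: `region`,
#'   `axis`, `parameter`, `left_deg`, `right_deg`, `aai_percent`, `grade`.
#' @export
evaluate_template <- function(landmarks, criterion = grading_criteria("aai"),
                              denominator = c("left", "min"),
                              vocabulary = landmark_vocabulary()) {
  denominator <- match.arg(denominator)
  params <- angular_parameters()
  uniq <- params[!duplicated(params$parameter), ]
  ang <- lapply(seq_len(nrow(uniq)), function(i) {
    trip <- c(uniq$a[i], uniq$b[i], uniq$c[i])
    tibble(
      parameter = uniq$parameter[i],
      left_deg = compute_angle(landmarks, trip, "left", vocabulary),
      right_deg = compute_angle(landmarks, trip, "right", vocabulary)
    )
  })
  out <- left_join(params, bind_rows(ang), by = "parameter")
  out$aai_percent <- compute_aai(out$left_deg, out$right_deg,
                                 denominator = denominator)
  out$grade <- classify_statistic(out$aai_percent, criterion)
  out <- out[, c("region", "axis", "parameter", "left_deg", "right_deg",
                 "aai_percent", "grade")]
  class(out) <- c("wireframe_result", class(out))
  out
}

#' Per-region grades from a wireframe result
#'
#' Applies the all-mild aggregation rule over the X, Y, Z grades of each
#' region.
#'
#' @param result A `wireframe_result` from [evaluate_template()].
#' @return A 5-row tibble with `region` and `grade`.
#' @export
wireframe_region_grades <- function(result) {
  result |>
    group_by(.data$region) |>
    summarise(grade = aggregate_region(.data$grade), .groups = "drop") |>
    arrange(match(.data$region, REGIONS))
}

#' Wireframe edge list
#'
#' The union of the two arms (A-B and B-C) of every template triplet on both
#' sides, with shared edges deduplicated. Edges whose endpoints are absent
#' from the landmark set are dropped, so a partial (or empty) set yields a
#' partial (or empty) wireframe.
#'
#' @param landmarks A `landmark_set` (may be empty).
#' @param vocabulary Landmark registry for side resolution.
#' @return A tibble with columns `from`, `to` (full landmark identifiers,
#'   each edge stored once with `from` < `to`).
#' @export
build_wireframe <- function(landmarks, vocabulary = landmark_vocabulary()) {
  params <- angular_parameters()
  edges <- list()
  for (side in c("left", "right")) {
    for (i in seq_len(nrow(params))) {
      ids <- vapply(c(params$a[i], params$b[i], params$c[i]),
                    resolve_landmark_id, "", side = side,
                    vocabulary = vocabulary)
      edges[[length(edges) + 1]] <- tibble(from = ids[1], to = ids[2])
      edges[[length(edges) + 1]] <- tibble(from = ids[2], to = ids[3])
    }
  }
  e <- bind_rows(edges)
  swap <- e$from > e$to
  tmp <- e$from[swap]
  e$from[swap] <- e$to[swap]
  e$to[swap] <- tmp
  e <- unique(e)
  present <- if (is.null(landmarks) || nrow(landmarks) == 0) {
    character(0)
  } else {
    landmarks$name
  }
  e <- e[e$from %in% present & e$to %in% present, ]
  arrange(e, .data$from, .data$to)
}

#' Export wireframe edges as OBJ line elements
#'
#' @param landmarks A `landmark_set`.
#' @param path Output `.obj` path.
#' @param edges Optional precomputed edge tibble from [build_wireframe()].
#' @return `path`, invisibly.
#' @export
write_wireframe_obj <- function(landmarks, path, edges = NULL) {
  edges <- edges %||% build_wireframe(landmarks)
  nm <- landmarks$name
  v <- sprintf("v %.9g %.9g %.9g", landmarks$x, landmarks$y, landmarks$z)
  l <- sprintf("l %d %d", match(edges$from, nm), match(edges$to, nm))
  writeLines(c(v, l), path)
  invisible(path)
}

#' @export
print.wireframe_result <- function(x, ...) {
  cat("<wireframe_result: 15 angular parameters>\n")
  NextMethod()
}

#' Tidy a wireframe result
#'
#' @param x A `wireframe_result`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy wireframe_result
#' @export
tidy.wireframe_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wireframe_result")
  out
}

#' One-row summary of a wireframe result
#'
#' @param x A `wireframe_result`.
#' @param ... Unused.
#' @return A tibble with the maximum AAI, its parameter, and grade counts.
#' @method glance wireframe_result
#' @export
glance.wireframe_result <- function(x, ...) {
  tibble(
    max_aai = max(x$aai_percent),
    worst_parameter = x$parameter[which.max(x$aai_percent)],
    n_mild = sum(x$grade == "mild"),
    n_moderate = sum(x$grade == "moderate"),
    n_severe = sum(x$grade == "severe")
  )
}
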