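#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline geom_histogram
#'   geom_tile geom_text facet_wrap labs scale_fill_gradient2
#'   scale_fill_manual theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a wireframe template result
#'
#' Bar chart of the Angle Asymmetry Index per region and axis, with the
#' mild/moderate and moderate/severe thresholds as horizontal lines.
#'
#' @param object A `wireframe_result` from [evaluate_template()].
#' @param criterion AAI criterion whose thresholds are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wireframe_result
#' @export
autoplot.wireframe_result <- function(object,
                                      criterion = grading_criteria("aai"),
                                      ...) {
  df <- as_tibble(object)
  df$region <- factor(df$region, levels = REGIONS)
  ggplot(df, aes(x = .data$axis, y = .data$aai_percent, fill = .data$grade)) +
    geom_col() +
    geom_hline(yintercept = c(criterion$lower_cut, criterion$upper_cut),
               linetype = "dashed", colour = "grey40") +
    facet_wrap(~region, nrow = 1) +
    scale_fill_manual(values = c(mild = "#4DAF4A", moderate = "#FF7F00",
                                 severe = "#E41A1C"), drop = FALSE) +
    labs(x = "axis", y = "AAI (%)", fill = "grade",
         title = "Wireframe template: angle asymmetry by region and axis") +
    theme_minimal()
}

#' Plot a mirror-overlap analysis
#'
#' Histogram of the signed per-vertex deviations (mm) between the face and
#' its mirrored, best-fit-aligned copy.
#'
#' @param object A `mirror_analysis`.
#' @param bins Histogram bins (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirror_analysis
#' @export
autoplot.mirror_analysis <- function(object, bins = 60, ...) {
  ggplot(object$field, aes(x = .data$signed_distance)) +
    geom_histogram(bins = bins, fill = "#4393C3", colour = "grey30",
                   linewidth = 0.1) +
    labs(x = "signed deviation (mm)", y = "vertices",
         title = "Mirroring and overlapping: deviation distribution") +
    theme_minimal()
}

#' Plot a consistency table
#'
#' Tile map of consistency rates per region (and axis, when present), with
#' the printed value overlaid.
#'
#' @param table A consistency tibble from [build_overall_table()],
#'   [build_dimension_table()] or [consistency_from_counts()].
#' @param good_threshold Rate regarded as good agreement (default 85).
#' @return A ggplot object.
#' @export
plot_consistency <- function(table, good_threshold = 85) {
  df <- table[table$region %in% REGIONS, ]
  df$region <- factor(df$region, levels = REGIONS)
  if (!"axis" %in% names(df)) df$axis <- "overall"
  ggplot(df, aes(x = .data$axis, y = .data$region,
                 fill = .data$consistency)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = sprintf("%.1f", .data$consistency)), size = 3) +
    scale_fill_gradient2(low = "#B2182B", mid = "#FDDBC7", high = "#2166AC",
                         midpoint = good_threshold, limits = c(0, 100)) +
    labs(x = NULL, y = NULL, fill = "consistency (%)",
         title = "Inter-method consistency rates") +
    theme_minimal()
}
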