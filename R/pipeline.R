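#' Wireframe template workflow
#'
#' Pose-normalizes the landmarks, evaluates the 15-angle template, and grades
#' each region; optionally writes the per-parameter report (JSON), the region
#' grades (CSV) and the wireframe overlay (OBJ line elements).
#'
#' @param landmarks A `landmark_set` (raw frame is fine; pose is computed
#'   from the landmarks themselves).
#' @param criterion AAI grading criterion.
#' @param out_dir Optional output directory for report files.
#' @return A list with `angles` (the `wireframe_result`), `region_grades`,
#'   and `pose` (the rigid transform used).
#' @export
run_wireframe_analysis <- function(landmarks,
                                   criterion = grading_criteria("aai"),
                                   out_dir = NULL) {
  pose <- frankfort_pose(landmarks)
  posed <- apply_transform(pose, landmarks)
  angles <- evaluate_template(posed, criterion = criterion)
  region_grades <- wireframe_region_grades(angles)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(angles, file.path(out_dir, "wireframe_angles.json"))
    write_table(region_grades, file.path(out_dir, "wireframe_region_grades.csv"))
    write_wireframe_obj(posed, file.path(out_dir, "wireframe.obj"))
  }
  list(angles = angles, region_grades = region_grades, pose = pose)
}

#' Mirroring-and-overlapping workflow
#'
#' Pose-normalizes mesh and landmarks, optionally crops to the analysis
#' extent, runs the mirror / best-fit / deviation pipeline, and grades each
#' region under the chosen deviation criterion; optionally writes the
#' summary table and the deviation colormap (PLY).
#'
#' @param mesh A `face_mesh`.
#' @param landmarks The matching `landmark_set`.
#' @param criterion A deviation [grading_criterion()] (or 1, 2, 3).
#' @param crop_bounds Optional bounds list for [crop_extent()]; `NULL` skips
#'   cropping.
#' @param icp ICP settings, see [icp_settings()].
#' @param out_dir Optional output directory.
#' @return A list with `analysis` (the `mirror_analysis`), `grades`
#'   (region x axis grades plus aggregates) and `pose`.
#' @export
run_mirror_analysis <- function(mesh, landmarks,
                                criterion = grading_criteria("mfm_narrow"),
                                crop_bounds = NULL, icp = icp_settings(),
                                out_dir = NULL) {
  if (is.numeric(criterion)) criterion <- grading_criteria(criterion)
  pose <- frankfort_pose(landmarks)
  mesh <- apply_transform(pose, mesh, frame_tag = "normalized")
  landmarks <- apply_transform(pose, landmarks)
  if (!is.null(crop_bounds)) mesh <- crop_extent(mesh, crop_bounds)
  analysis <- mirror_overlap_analysis(mesh, landmarks, params = icp)
  grades <- grade_deviation(analysis$summary, criterion)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(analysis$summary, file.path(out_dir, "deviation_summary.csv"))
    write_table(grades, file.path(out_dir, "deviation_grades.csv"))
    export_colormap(analysis$field, mesh, file.path(out_dir, "colormap.ply"))
  }
  list(analysis = analysis, grades = grades, pose = pose)
}

#' Grade matrices for a synthetic cohort
#'
#' Runs both workflows over a list of synthetic cases and collects the
#' per-subject grades into two [grade_matrix()] objects.
#'
#' @param cases List of `synthetic_case` objects (see [generate_cohort()]).
#' @param criterion Deviation criterion for the mirroring grades (1, 2, 3 or
#'   a [grading_criterion()]).
#' @param icp ICP settings.
#' @return A list with `mirror` and `template` grade matrices (axis rows and
#'   `region` aggregate rows).
#' @export
cohort_grade_matrices <- function(cases, criterion = grading_criteria("mfm_narrow"),
                                  icp = icp_settings()) {
  if (is.numeric(criterion)) criterion <- grading_criteria(criterion)
  rows_m <- list()
  rows_t <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    wf <- run_wireframe_analysis(case$landmarks)
    tw <- bind_rows(
      wf$angles[, c("region", "axis", "grade")],
      mutate(wf$region_grades, axis = "region")[, c("region", "axis", "grade")]
    )
    tw$subject <- i
    rows_t[[i]] <- tw
    mr <- run_mirror_analysis(case$mesh, case$landmarks, criterion = criterion,
                              icp = icp)
    tm <- mr$grades[, c("region", "axis", "grade")]
    tm$subject <- i
    rows_m[[i]] <- tm
  }
  list(
    mirror = grade_matrix(bind_rows(rows_m), method_tag = "mirroring"),
    template = grade_matrix(bind_rows(rows_t), method_tag = "wireframe")
  )
}

#' Compare the two methods over a cohort
#'
#' Batch entry point: both workflows over a cohort, then the overall
#' (per-region) and per-dimension consistency tables.
#'
#' @inheritParams cohort_grade_matrices
#' @param out_dir Optional output directory for the two tables (CSV).
#' @return A list with `overall`, `dimension`, and the two grade matrices.
#' @export
compare_methods <- function(cases, criterion = grading_criteria("mfm_narrow"),
                            icp = icp_settings(), out_dir = NULL) {
  gm <- cohort_grade_matrices(cases, criterion = criterion, icp = icp)
  overall <- build_overall_table(gm$mirror, gm$template)
  dimension <- build_dimension_table(gm$mirror, gm$template)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(overall, file.path(out_dir, "consistency_overall.csv"))
    write_table(dimension, file.path(out_dir, "consistency_dimension.csv"))
  }
  list(overall = overall, dimension = dimension, mirror = gm$mirror,
       template = gm$template)
}

#' Read a YAML run configuration
#'
#' Parses the configuration consumed by the command-line interface: grading
#' criterion, ICP block (`icp:` with `max_iterations`, `tolerance_mm`,
#' `trim_fraction`, `subsample`), crop bounds, and ROI thresholds.
#'
#' @param path YAML file.
#' @return A list with `criterion`, `icp` ([icp_settings()]), `crop_bounds`,
#'   `roi` ([roi_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  icp <- do.call(icp_settings, cfg$icp %||% list())
  roi <- do.call(roi_config, cfg$roi %||% list())
  crit <- cfg$criterion %||% "mfm_narrow"
  if (is.numeric(crit)) crit <- c("rmse_criterion", "mfm_wide", "mfm_narrow")[crit]
  list(criterion = grading_criteria(crit), icp = icp,
       crop_bounds = cfg$crop_bounds, roi = roi)
}
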