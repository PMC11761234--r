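#' Region-of-interest thresholds
#'
#' The five facial regions are bounded in the source material by anatomy
#' (grooves, bone edges, the mandibular-angle "fan") that has no closed-form
#' location on a soft-tissue surface. Each curved boundary is operationalized
#' here as a landmark-level axis threshold or radius cut in the normalized
#' frame; every threshold is a named configuration value with a
#' landmark-derived default.
#'
#' @param earlobe_drop_mm Vertical drop from tragion level to the "lowest
#'   point of the earlobe" surrogate (default 12 mm).
#' @param fan_radius_mm Radius around gonion approximating the fan-shaped
#'   mandibular-angle area (default 25 mm).
#' @param nasofacial_offset_mm Lateral offset from the subalare level to the
#'   nasofacial-groove surrogate bounding the cheek medially (default 5 mm).
#' @param chin_drop_mm Depth of the chin slab below menton (default 12 mm).
#' @param chin_margin_mm Lateral margin beyond the mental-tubercle pair
#'   (default 5 mm).
#' @param posterior_offset_mm Offset added to the zygion Z level for the
#'   "posterior edge of the zygomatic bone" surrogate plane (default 0 mm).
#' @return A named list of thresholds.
#' @export
roi_config <- function(earlobe_drop_mm = 12, fan_radius_mm = 25,
                       nasofacial_offset_mm = 5, chin_drop_mm = 12,
                       chin_margin_mm = 5, posterior_offset_mm = 0) {
  list(earlobe_drop_mm = earlobe_drop_mm, fan_radius_mm = fan_radius_mm,
       nasofacial_offset_mm = nasofacial_offset_mm, chin_drop_mm = chin_drop_mm,
       chin_margin_mm = chin_margin_mm, posterior_offset_mm = posterior_offset_mm)
}

region_mask <- function(region, side, idx) {
  if (length(idx) == 0) {
    abort(paste0("Region '", region, "' (", side, ") selected no vertices."))
  }
  structure(list(region = region, side = side,
                 vertex_indices = as.integer(idx)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask: %s (%s), %d vertices>\n", x$region, x$side,
              length(x$vertex_indices)))
  invisible(x)
}

need_landmarks <- function(landmarks, names) {
  miss <- setdiff(names, landmarks$name)
  if (length(miss) > 0) {
    abort(paste0("Region definition needs landmark(s): ",
                 paste(miss, collapse = ", ")))
  }
}

pair_level <- function(landmarks, base, coord) {
  mean(c(lm_xyz(landmarks, paste0(base, "_L"))[coord],
         lm_xyz(landmarks, paste0(base, "_R"))[coord]))
}

# mean |x| of a bilateral pair: the lateral level of the pair
pair_halfwidth <- function(landmarks, base) {
  mean(c(abs(lm_xyz(landmarks, paste0(base, "_L"))[1]),
         abs(lm_xyz(landmarks, paste0(base, "_R"))[1])))
}

side_sel <- function(x, side) {
  switch(side, left = x > 0, right = x < 0, bilateral = rep(TRUE, length(x)))
}

#' Define the labial region
#'
#' Rectangular slab between the nose floor (subalare level) above and the
#' mentolabial groove below, laterally bounded by the labiofacial-groove
#' surrogates at the mouth corners (cheilion).
#'
#' @param mesh A posed `face_mesh`.
#' @param landmarks Matching posed `landmark_set`.
#' @param config See [roi_config()].
#' @return A `region_mask`.
#' @export
define_labial <- function(mesh, landmarks, config = roi_config()) {
  need_landmarks(landmarks, c("Sal_L", "Sal_R", "Ch_L", "Ch_R", "Li", "Gn"))
  V <- mesh$vertices
  y_top <- pair_level(landmarks, "Sal", 2)
  y_groove <- (lm_xyz(landmarks, "Li")[2] + lm_xyz(landmarks, "Gn")[2]) / 2
  x_l <- lm_xyz(landmarks, "Ch_L")[1]
  x_r <- lm_xyz(landmarks, "Ch_R")[1]
  sel <- V[, 2] >= y_groove & V[, 2] < y_top & V[, 1] > x_r & V[, 1] < x_l
  region_mask("labial", "bilateral", which(sel))
}

#' Define a mandibular-angle region
#'
#' Fan-shaped area around gonion: below the earlobe level, at or behind the
#' zygion Z level (posterior-edge surrogate), within a fixed radius of the
#' gonion of the requested side.
#'
#' @inheritParams define_labial
#' @param side `"left"` or `"right"`.
#' @return A `region_mask`.
#' @export
define_mandibular_angle <- function(mesh, landmarks, side = c("left", "right"),
                                    config = roi_config()) {
  side <- match.arg(side)
  sfx <- if (side == "left") "_L" else "_R"
  need_landmarks(landmarks, c(paste0(c("Go", "Zg", "Tr"), sfx)))
  V <- mesh$vertices
  go <- lm_xyz(landmarks, paste0("Go", sfx))
  zg <- lm_xyz(landmarks, paste0("Zg", sfx))
  tr <- lm_xyz(landmarks, paste0("Tr", sfx))
  y_ear <- tr[2] - config$earlobe_drop_mm
  d <- sqrt((V[, 1] - go[1])^2 + (V[, 2] - go[2])^2 + (V[, 3] - go[3])^2)
  sel <- V[, 2] < y_ear &
    V[, 3] <= zg[3] + config$posterior_offset_mm &
    d < config$fan_radius_mm &
    side_sel(V[, 1], side)
  region_mask("mandibular_angle", side, which(sel))
}

#' Define a cheek region
#'
#' Between the lower edge of the zygomatic level above and the mandibular
#' lower edge (gonion level) below, lateral to the nasofacial-groove
#' surrogate, on one side.
#'
#' @inheritParams define_mandibular_angle
#' @return A `region_mask`.
#' @export
define_cheek <- function(mesh, landmarks, side = c("left", "right"),
                         config = roi_config()) {
  side <- match.arg(side)
  need_landmarks(landmarks, c("Zg_L", "Zg_R", "Go_L", "Go_R", "Sal_L", "Sal_R"))
  V <- mesh$vertices
  y_top <- pair_level(landmarks, "Zg", 2)
  y_bot <- pair_level(landmarks, "Go", 2)
  x_groove <- pair_halfwidth(landmarks, "Sal") + config$nasofacial_offset_mm
  sel <- V[, 2] >= y_bot & V[, 2] < y_top &
    abs(V[, 1]) > x_groove &
    side_sel(V[, 1], side)
  region_mask("cheek", side, which(sel))
}

#' Define the chin region
#'
#' Slab below the mentolabial groove containing menton, gnathion and the
#' mental tubercles, laterally bounded just beyond the tubercle pair.
#'
#' @inheritParams define_labial
#' @return A `region_mask`.
#' @export
define_chin <- function(mesh, landmarks, config = roi_config()) {
  need_landmarks(landmarks, c("Li", "Gn", "Me", "Mt_L", "Mt_R"))
  V <- mesh$vertices
  y_groove <- (lm_xyz(landmarks, "Li")[2] + lm_xyz(landmarks, "Gn")[2]) / 2
  y_bot <- lm_xyz(landmarks, "Me")[2] - config$chin_drop_mm
  x_lim <- pair_halfwidth(landmarks, "Mt") + config$chin_margin_mm
  sel <- V[, 2] >= y_bot & V[, 2] < y_groove & abs(V[, 1]) < x_lim
  region_mask("chin", "bilateral", which(sel))
}

#' Define an articular region
#'
#' Band between the top of the helix and the earlobe level, with Z between
#' the tragus plane and the zygomatic posterior-edge surrogate, on one side.
#'
#' @inheritParams define_mandibular_angle
#' @return A `region_mask`.
#' @export
define_articular <- function(mesh, landmarks, side = c("left", "right"),
                             config = roi_config()) {
  side <- match.arg(side)
  sfx <- if (side == "left") "_L" else "_R"
  need_landmarks(landmarks, paste0(c("He", "Tr", "Zg"), sfx))
  V <- mesh$vertices
  he <- lm_xyz(landmarks, paste0("He", sfx))
  tr <- lm_xyz(landmarks, paste0("Tr", sfx))
  zg <- lm_xyz(landmarks, paste0("Zg", sfx))
  y_ear <- tr[2] - config$earlobe_drop_mm
  sel <- V[, 2] >= y_ear & V[, 2] < he[2] &
    V[, 3] >= tr[3] & V[, 3] < zg[3] + config$posterior_offset_mm &
    side_sel(V[, 1], side)
  region_mask("articular", side, which(sel))
}

#' All five region masks
#'
#' Convenience wrapper returning one combined (left + right where bilateral)
#' vertex-index set per region, the granularity at which asymmetry is graded.
#'
#' @inheritParams define_labial
#' @return Named list of integer vertex-index vectors, one per region.
#' @export
region_masks <- function(mesh, landmarks, config = roi_config()) {
  list(
    labial = define_labial(mesh, landmarks, config)$vertex_indices,
    mandibular_angle = sort(union(
      define_mandibular_angle(mesh, landmarks, "left", config)$vertex_indices,
      define_mandibular_angle(mesh, landmarks, "right", config)$vertex_indices
    )),
    cheek = sort(union(
      define_cheek(mesh, landmarks, "left", config)$vertex_indices,
      define_cheek(mesh, landmarks, "right", config)$vertex_indices
    )),
    chin = define_chin(mesh, landmarks, config)$vertex_indices,
    articular = sort(union(
      define_articular(mesh, landmarks, "left", config)$vertex_indices,
      define_articular(mesh, landmarks, "right", config)$vertex_indices
    ))
  )
}

#' Export region masks for inspection
#'
#' Writes the masks as a JSON object of vertex-index lists (1-based).
#'
#' @param masks Named list from [region_masks()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_region_masks <- function(masks, path) {
  jsonlite::write_json(masks, path)
  invisible(path)
}
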