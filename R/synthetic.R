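#' Asymmetry specification
#'
#' Describes one planted deformation of a synthetic face: the target region,
#' the displacement axis, the magnitude in mm, and the mode —
#' `surface_bump` (a compact-support radial bump on the right-side surface),
#' `landmark_shift` (displacement of the region's template landmark on the
#' right side), or `combined` (both).
#'
#' @param region One of the five region identifiers.
#' @param axis `"X"`, `"Y"` or `"Z"` (normalized-frame axes).
#' @param magnitude Displacement in mm (>= 0). For `landmark_shift` and
#'   `combined` this is the landmark displacement; the surface bump height
#'   can be set separately via `bump_mm`.
#' @param mode Deformation mode.
#' @param bump_mm Bump height in mm for `combined` mode (defaults to
#'   `magnitude`).
#' @return A list of class `asymmetry_spec`.
#' @export
asymmetry_spec <- function(region, axis, magnitude,
                           mode = c("surface_bump", "landmark_shift",
                                    "combined"),
                           bump_mm = magnitude) {
  region <- match.arg(region, REGIONS)
  axis <- match.arg(axis, AXES)
  mode <- match.arg(mode)
  stopifnot(is.finite(magnitude), magnitude >= 0, is.finite(bump_mm),
            bump_mm >= 0)
  structure(list(region = region, axis = axis, magnitude = magnitude,
                 mode = mode, bump_mm = bump_mm),
            class = "asymmetry_spec")
}

# analytic height-field: smooth symmetric face-like front surface (mm)
face_height_fun <- function(p) {
  force(p)
  function(x, y) {
    p$face_h * exp(-((x / p$face_a)^2 + ((y - p$face_yc) / p$face_b)^2)) +
      p$nose_h * exp(-((x / p$nose_w)^2 + ((y - p$nose_y) / p$nose_l)^2)) +
      p$chin_h * exp(-((x / p$chin_w)^2 + ((y - p$chin_y) / p$chin_w)^2)) +
      p$lip_h * exp(-((x / p$lip_wx)^2 + ((y - p$lip_y) / p$lip_wy)^2))
  }
}

default_face_params <- function() {
  list(face_h = 70, face_a = 70, face_b = 95, face_yc = -20,
       nose_h = 18, nose_w = 12, nose_l = 28, nose_y = -12,
       chin_h = 8, chin_w = 18, chin_y = -80,
       lip_h = 4, lip_wx = 25, lip_wy = 10, lip_y = -50)
}

# landmark template: (x, y) positions in the generator frame; z from the
# height field. Exocanthion x is solved at generation time so that the
# exocanthion midpoint sits at the tragion z level (pose comes out axis
# aligned for the base face).
landmark_template <- function() {
  tibble::tribble(
    ~base, ~x,  ~y,
    "Tr",  75,   0,
    "He",  72,  30,
    "Zg",  58,   5,
    "Go",  55, -60,
    "Ch",  24, -48,
    "Sal", 12, -32,
    "Stb", 14, -56,
    "As",  20, -26,
    "Mt",  16, -78,
    "Li",   0, -56,
    "Gn",   0, -76,
    "Me",   0, -88
  )
}

# per-region bump centres (right side, generator frame) and support radii
bump_geometry <- function() {
  list(
    labial = list(center = c(-15, -48), radius = 10),
    mandibular_angle = list(center = c(-55, -60), radius = 12),
    cheek = list(center = c(-40, -28), radius = 12),
    chin = list(center = c(-12, -80), radius = 10),
    articular = list(center = c(-67, 10), radius = 12)
  )
}

# the template landmark displaced by landmark_shift for each region; every
# one of them appears in all three of its region's angular parameters
region_shift_landmark <- c(labial = "Ch", mandibular_angle = "Go",
                           cheek = "Zg", chin = "Mt", articular = "Tr")

#' Generate a symmetric synthetic base face
#'
#' Builds an analytic face-like front surface (blended Gaussian domes for
#' the facial mass, nose ridge, lips and chin) that is exactly bilaterally
#' symmetric about X = 0, with all template landmarks planted at analytic
#' surface positions (bilateral pairs exact mirror images). A small seeded,
#' symmetric variation of the dome parameters gives distinct but equally
#' symmetric subjects. The returned case is posed in the normalized frame.
#'
#' @param resolution Grid vertices per axis (default 48; minimum 24).
#' @param seed Integer seed for the symmetric shape variation.
#' @return A list of class `synthetic_case` with `mesh`, `landmarks`,
#'   `truth` (empty tibble), `seed`, `resolution` and the internal surface
#'   parameters.
#' @export
generate_base_face <- function(resolution = 48, seed = 1) {
  if (resolution < 24) {
    abort("`resolution` below 24 cannot host the five regions.")
  }
  p <- default_face_params()
  rng <- local({
    set.seed(as.integer(seed))
    stats::runif(5, 0.96, 1.04)
  })
  p$face_h <- p$face_h * rng[1]
  p$face_a <- p$face_a * rng[2]
  p$face_b <- p$face_b * rng[3]
  p$nose_h <- p$nose_h * rng[4]
  p$chin_h <- p$chin_h * rng[5]
  f <- face_height_fun(p)

  # exactly symmetric grid
  xs <- seq(-85, 85, length.out = resolution)
  xs <- (xs - rev(xs)) / 2
  ys <- seq(-105, 45, length.out = resolution)
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, f(g$x, g$y))

  # regular grid triangulation
  idx <- function(i, j) (j - 1L) * resolution + i
  i <- rep(seq_len(resolution - 1L), resolution - 1L)
  j <- rep(seq_len(resolution - 1L), each = resolution - 1L)
  F <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  mesh <- face_mesh(V, F, frame_tag = "raw")

  # solve exocanthion x so the Ex midpoint sits at tragion z level
  z_tr <- f(75, 0)
  x_ex <- stats::uniroot(function(x) f(x, 22) - z_tr, c(40, 84),
                         tol = 1e-10)$root
  tmpl <- bind_rows(landmark_template(), tibble(base = "Ex", x = x_ex, y = 22))
  voc <- landmark_vocabulary()
  bil <- tmpl$base %in% voc$base[voc$bilateral]
  lm <- bind_rows(
    tibble(name = paste0(tmpl$base[bil], "_L"), x = tmpl$x[bil],
           y = tmpl$y[bil]),
    tibble(name = paste0(tmpl$base[bil], "_R"), x = -tmpl$x[bil],
           y = tmpl$y[bil]),
    tibble(name = tmpl$base[!bil], x = tmpl$x[!bil], y = tmpl$y[!bil])
  )
  lm$z <- f(lm$x, lm$y)
  landmarks <- landmark_set(lm)

  # pose into the standard frame (identity rotation by construction; the
  # tragion midpoint moves to the origin)
  tf <- frankfort_pose(landmarks)
  mesh <- apply_transform(tf, mesh, frame_tag = "normalized")
  landmarks <- apply_transform(tf, landmarks)

  structure(list(mesh = mesh, landmarks = landmarks,
                 truth = tibble(region = character(), axis = character(),
                                magnitude = numeric(), mode = character(),
                                bump_mm = numeric()),
                 seed = as.integer(seed), resolution = as.integer(resolution),
                 params = p),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case: seed %d, %d vertices, %d planted deformation(s)>\n",
              x$seed, nrow(x$mesh$vertices), nrow(x$truth)))
  invisible(x)
}

# cosine bump weights: C1, compact support
bump_weights <- function(xy, center, radius) {
  r <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
  w <- numeric(length(r))
  inside <- r < radius
  w[inside] <- 0.5 * (1 + cos(pi * r[inside] / radius))
  w
}

axis_direction <- function(axis, center_x) {
  switch(axis,
         X = c(sign(center_x), 0, 0),
         Y = c(0, 1, 0),
         Z = c(0, 0, 1))
}

#' Plant an asymmetric deformation
#'
#' Applies an [asymmetry_spec()] to a synthetic case. Deformations act on
#' the right side only (the left side stays pristine, keeping the AAI
#' denominator analytic): `surface_bump` adds a C1 compact-support radial
#' cosine bump of height `bump_mm` to the mesh; `landmark_shift` displaces
#' the region's template landmark (`Ch`, `Go`, `Zg`, `Mt` or `Tr`, right
#' side) by `magnitude` along the spec axis. A region can only be deformed
#' once per case.
#'
#' @param case A `synthetic_case`.
#' @param spec An [asymmetry_spec()].
#' @return The deformed `synthetic_case` with the spec appended to `truth`.
#' @export
apply_asymmetry <- function(case, spec) {
  stopifnot(inherits(case, "synthetic_case"), inherits(spec, "asymmetry_spec"))
  if (spec$region %in% case$truth$region) {
    abort(paste0("Region '", spec$region, "' already carries a deformation."))
  }
  geom <- bump_geometry()[[spec$region]]
  if (spec$mode %in% c("surface_bump", "combined") && spec$bump_mm > 0) {
    V <- case$mesh$vertices
    w <- bump_weights(V[, 1:2, drop = FALSE], geom$center, geom$radius)
    # displace along the local outward normal so the bump height equals the
    # planted point-to-surface deviation (an axis-aligned push would be
    # foreshortened on the inclined facial surface)
    vn <- vertex_normals(case$mesh)
    flip <- sign(vn[, 3])
    flip[flip == 0] <- 1
    V <- V + spec$bump_mm * w * flip * vn
    case$mesh <- face_mesh(V, case$mesh$faces, frame_tag = case$mesh$frame_tag)
  }
  if (spec$mode %in% c("landmark_shift", "combined") && spec$magnitude > 0) {
    id <- paste0(region_shift_landmark[[spec$region]], "_R")
    i <- match(id, case$landmarks$name)
    dirv <- axis_direction(spec$axis, -1)
    case$landmarks$x[i] <- case$landmarks$x[i] + spec$magnitude * dirv[1]
    case$landmarks$y[i] <- case$landmarks$y[i] + spec$magnitude * dirv[2]
    case$landmarks$z[i] <- case$landmarks$z[i] + spec$magnitude * dirv[3]
  }
  case$truth <- bind_rows(case$truth,
                          tibble(region = spec$region, axis = spec$axis,
                                 magnitude = spec$magnitude, mode = spec$mode,
                                 bump_mm = spec$bump_mm))
  case
}

#' Calibrate a landmark shift to a target AAI
#'
#' Finds the right-side landmark displacement (mm, along `axis`) that makes
#' the worst Angle Asymmetry Index among the region's three angular
#' parameters equal `target_aai` percent on the given case, by root finding
#' on the analytic template response.
#'
#' @param case A `synthetic_case`.
#' @param region,axis Deformation site and displacement axis.
#' @param target_aai Target AAI in percent.
#' @return Displacement in mm.
#' @export
calibrate_shift <- function(case, region, axis, target_aai) {
  region <- match.arg(region, REGIONS)
  axis <- match.arg(axis, AXES)
  g <- function(m) {
    c2 <- case
    c2$truth <- c2$truth[0, ]
    c2 <- apply_asymmetry(c2, asymmetry_spec(region, axis, m,
                                             mode = "landmark_shift"))
    res <- evaluate_template(c2$landmarks)
    max(res$aai_percent[res$region == region]) - target_aai
  }
  # cross-region leakage through shared landmarks can put the region at the
  # target already; no further shift is needed then
  if (g(0) >= 0) return(0)
  upper <- 10
  while (g(upper) < 0 && upper < 160) upper <- upper * 2
  if (g(upper) < 0) abort("Target AAI unreachable by landmark displacement.")
  stats::uniroot(g, c(0, upper), tol = 1e-6)$root
}

#' Generate a synthetic cohort
#'
#' Builds `n` synthetic subjects with planted asymmetry. Each subject draws
#' a severity target from `grade_mix`; every region of that subject then
#' receives a deformation calibrated to the target band — landmark shifts
#' sized by [calibrate_shift()] so the AAI criterion reproduces the target
#' grade, plus a surface bump sized so the narrow MFM criterion agrees
#' (mild: none; moderate: AAI in \[1.5, 2.5\]\%, bump in \[1.3, 1.8\] mm;
#' severe: AAI in \[4, 8\]\%, bump in \[3, 5\] mm). All randomness flows from
#' `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param grade_mix Named proportions over `mild`, `moderate`, `severe`
#'   summing to 1.
#' @param seed Integer master seed.
#' @param resolution Mesh resolution per subject.
#' @return A list of `synthetic_case` objects; each carries its truth table
#'   and the per-subject target grade as attribute `target_grade`.
#' @export
generate_cohort <- function(n = 24,
                            grade_mix = c(mild = 0, moderate = 0, severe = 1),
                            seed = 1, resolution = 48) {
  stopifnot(n >= 1)
  grade_mix <- grade_mix[GRADES]
  grade_mix[is.na(grade_mix)] <- 0
  if (abs(sum(grade_mix) - 1) > 1e-9) abort("`grade_mix` must sum to 1.")
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  targets <- sample(GRADES, n, replace = TRUE, prob = grade_mix)
  lapply(seq_len(n), function(i) {
    case <- generate_base_face(resolution = resolution,
                               seed = subject_seeds[i])
    set.seed(subject_seeds[i] %% 1000000L + 7L)
    if (targets[i] != "mild") {
      for (region in REGIONS) {
        axis <- sample(AXES, 1)
        if (targets[i] == "moderate") {
          aai_target <- stats::runif(1, 1.5, 2.5)
          bump <- stats::runif(1, 1.3, 1.8)
        } else {
          aai_target <- stats::runif(1, 4, 8)
          bump <- stats::runif(1, 3, 5)
        }
        shift <- calibrate_shift(case, region, axis, aai_target)
        case <- apply_asymmetry(case, asymmetry_spec(region, axis, shift,
                                                     mode = "combined",
                                                     bump_mm = bump))
      }
    }
    attr(case, "target_grade") <- targets[i]
    case
  })
}

#' Write a synthetic case to disk
#'
#' Emits the mesh (OBJ), landmarks (JSON) and truth table (CSV) of one case.
#'
#' @param case A `synthetic_case`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default `"case"`.
#' @return The directory, invisibly.
#' @export
write_synthetic_case <- function(case, dir, stem = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obj(case$mesh, file.path(dir, paste0(stem, ".obj")))
  write_landmarks(case$landmarks, file.path(dir, paste0(stem, "_landmarks.json")))
  truth <- case$truth
  if (nrow(truth) == 0) {
    truth <- tibble(region = "none", axis = NA_character_, magnitude = 0,
                    mode = "none", bump_mm = 0)
  }
  write_table(truth, file.path(dir, paste0(stem, "_truth.csv")))
  invisible(dir)
}
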