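#' Rigid transform
#'
#' A proper rigid-body transform `p -> R p + t` (no scaling or shear).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort("`rotation` must be a proper rotation (orthonormal, det = +1).")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform: rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Rotation angle of a rotation matrix, degrees.
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_))) * 180 / pi
}

#' Apply a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @param x A `face_mesh`, `landmark_set`, or n-by-3 coordinate matrix.
#' @param frame_tag Optional frame label for transformed meshes.
#' @return `x` with transformed coordinates.
#' @export
apply_transform <- function(transform, x, frame_tag = NULL) {
  stopifnot(inherits(transform, "rigid_transform"))
  tf <- function(m) {
    sweep(m %*% t(transform$rotation), 2, -transform$translation)
  }
  if (inherits(x, "face_mesh")) {
    face_mesh(tf(x$vertices), x$faces, frame_tag = frame_tag %||% x$frame_tag)
  } else if (inherits(x, "landmark_set")) {
    lm_set_matrix(x, tf(lm_matrix(x)))
  } else {
    tf(as.matrix(x))
  }
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Pose normalization from landmarks
#'
#' Computes the rigid transform that places a face in the package's standard
#' frame, a soft-tissue surrogate for Frankfort-plane orientation:
#' the transverse axis (X) runs along the tragion pair `Tr_R -> Tr_L`, the
#' vertical axis (Y) is the direction from the tragion midpoint towards the
#' exocanthion midpoint after removal of its transverse component, and Z
#' (anterior) completes the right-handed frame. The tragion midpoint maps to
#' the origin, so the midsagittal plane is X = 0.
#'
#' @param landmarks A `landmark_set` containing `Tr_L`, `Tr_R`, `Ex_L`, `Ex_R`.
#' @return A [rigid_transform()] mapping raw coordinates into the standard
#'   frame.
#' @export
frankfort_pose <- function(landmarks) {
  need <- c("Tr_L", "Tr_R", "Ex_L", "Ex_R")
  miss <- setdiff(need, landmarks$name)
  if (length(miss) > 0) {
    abort(paste0("Pose normalization needs landmark(s): ",
                 paste(miss, collapse = ", ")))
  }
  trl <- lm_xyz(landmarks, "Tr_L")
  trr <- lm_xyz(landmarks, "Tr_R")
  exm <- (lm_xyz(landmarks, "Ex_L") + lm_xyz(landmarks, "Ex_R")) / 2
  trm <- (trl + trr) / 2

  xax <- trl - trr
  nx <- sqrt(sum(xax^2))
  if (nx < 1e-9) abort("Degenerate geometry: Tr_L and Tr_R coincide.")
  xax <- xax / nx

  up <- exm - trm
  up <- up - sum(up * xax) * xax
  nu <- sqrt(sum(up^2))
  if (nu < 1e-9) {
    abort("Degenerate geometry: exocanthion midpoint is collinear with the tragion axis.")
  }
  yax <- up / nu
  zax <- c(xax[2] * yax[3] - xax[3] * yax[2],
           xax[3] * yax[1] - xax[1] * yax[3],
           xax[1] * yax[2] - xax[2] * yax[1])

  R <- rbind(xax, yax, zax)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% trm))
}

#' Estimate the midsagittal offset from bilateral landmark pairs
#'
#' After pose normalization the midsagittal plane should sit at X = 0. This
#' returns the least-squares X offset of the midpoints of all bilateral
#' landmark pairs, useful as a diagnostic (it is ~0 for a well-posed face).
#'
#' @param landmarks A posed `landmark_set`.
#' @return The mean X coordinate of bilateral pair midpoints (mm).
#' @export
midsagittal_offset <- function(landmarks) {
  bil <- landmarks[landmarks$side != "midline", ]
  if (nrow(bil) == 0) return(0)
  mid <- tapply(bil$x, bil$base, mean)
  mean(mid)
}

#' Crop a mesh to an axis-aligned extent
#'
#' Keeps faces whose three vertices all fall inside the given bounds, then
#' compacts the vertex array and remaps face indices. Used to trim a raw scan
#' to the analysis extent (hairline to neck, ear to ear).
#'
#' @param mesh A `face_mesh`.
#' @param bounds Named list with any of `xmin`, `xmax`, `ymin`, `ymax`,
#'   `zmin`, `zmax`; omitted limits are infinite.
#' @return A cropped `face_mesh`.
#' @export
crop_extent <- function(mesh, bounds = list()) {
  b <- modifyList(list(xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf,
                       zmin = -Inf, zmax = Inf), bounds)
  V <- mesh$vertices
  inside <- V[, 1] >= b$xmin & V[, 1] <= b$xmax &
    V[, 2] >= b$ymin & V[, 2] <= b$ymax &
    V[, 3] >= b$zmin & V[, 3] <= b$zmax
  keepf <- inside[mesh$faces[, 1]] & inside[mesh$faces[, 2]] &
    inside[mesh$faces[, 3]]
  if (!any(keepf)) abort("Crop removed the whole mesh.")
  F2 <- mesh$faces[keepf, , drop = FALSE]
  used <- sort(unique(as.vector(F2)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  face_mesh(V[used, , drop = FALSE],
            matrix(remap[F2], ncol = 3),
            frame_tag = mesh$frame_tag)
}
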