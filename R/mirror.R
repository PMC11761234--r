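#' Mirror a mesh across the midsagittal plane
#'
#' Reflects every vertex `(x, y, z)` to `(-x, y, z)` and reverses face winding
#' so that outward orientation is preserved. The mesh is assumed to be in the
#' normalized frame, where the midsagittal plane is X = 0.
#'
#' @param mesh A `face_mesh`.
#' @return The mirrored `face_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  V <- mesh$vertices
  V[, 1] <- -V[, 1]
  face_mesh(V, mesh$faces[, c(1, 3, 2), drop = FALSE],
            frame_tag = mesh$frame_tag)
}

#' Default ICP settings
#'
#' @param max_iterations Iteration cap (default 100).
#' @param tolerance_mm Convergence threshold on the change in trimmed RMS
#'   distance between iterations (mm, default 1e-6).
#' @param trim_fraction Fraction of worst correspondences discarded each
#'   iteration (default 0.10); robustifies against locally asymmetric patches.
#' @param subsample Deterministic stride for source points (1 = use all).
#' @return A list of ICP settings.
#' @export
icp_settings <- function(max_iterations = 100, tolerance_mm = 1e-6,
                         trim_fraction = 0.10, subsample = 1L) {
  stopifnot(max_iterations >= 1, tolerance_mm > 0,
            trim_fraction >= 0, trim_fraction < 1, subsample >= 1)
  list(max_iterations = as.integer(max_iterations),
       tolerance_mm = tolerance_mm,
       trim_fraction = trim_fraction,
       subsample = as.integer(subsample))
}

# Kabsch: least-squares rotation + translation mapping P onto Q (both n x 3).
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

#' Rigid best-fit alignment (trimmed ICP)
#'
#' Iteratively aligns `source` onto `target` with a rigid (no-scale)
#' transform: exact nearest-vertex correspondences, optional trimming of the
#' worst matches, and a closed-form least-squares update each iteration. The
#' procedure is fully deterministic.
#'
#' @param source,target `face_mesh` objects (or n-by-3 point matrices).
#' @param params See [icp_settings()].
#' @param init Optional initial [rigid_transform()].
#' @return A [rigid_transform()] with attributes `final_rms` (mm, on the
#'   trimmed set), `iterations`, and `converged`.
#' @export
best_fit_align <- function(source, target, params = icp_settings(),
                           init = NULL) {
  P0 <- if (inherits(source, "face_mesh")) source$vertices else as.matrix(source)
  Q <- if (inherits(target, "face_mesh")) target$vertices else as.matrix(target)
  if (nrow(P0) < 3 || nrow(Q) < 3) {
    abort("Alignment needs at least 3 points in each mesh.")
  }
  if (params$subsample > 1L) {
    P0 <- P0[seq(1, nrow(P0), by = params$subsample), , drop = FALSE]
  }
  tf <- init %||% rigid_transform()
  P <- apply_transform(tf, P0)
  nkeep <- max(3L, floor(nrow(P) * (1 - params$trim_fraction)))
  prev_rms <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    nn <- .nn_bruteforce(P, Q)
    keep <- order(nn$distance)[seq_len(nkeep)]
    step <- kabsch(P[keep, , drop = FALSE], Q[nn$index[keep], , drop = FALSE])
    tf <- compose_transform(step, tf)
    P <- apply_transform(tf, P0)
    nn2 <- .nn_bruteforce(P[keep, , drop = FALSE], Q)
    rms <- sqrt(mean(nn2$distance^2))
    if (abs(prev_rms - rms) < params$tolerance_mm) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    if (it >= params$max_iterations) break
  }
  if (!converged) {
    warn(sprintf("ICP did not converge in %d iterations (final RMS %.4g mm).",
                 it, rms))
  }
  attr(tf, "final_rms") <- rms
  attr(tf, "iterations") <- it
  attr(tf, "converged") <- converged
  tf
}

#' Per-vertex deviation to a reference surface
#'
#' For every vertex of `original`, finds the closest point on the surface of
#' `mirrored_aligned` (point-to-triangle, not point-to-vertex) and records the
#' displacement vector, its Euclidean norm, and a signed distance whose sign
#' is the sign of the dot product between the displacement and the vertex
#' normal of `original` (positive = reference surface lies outside).
#'
#' @param original A `face_mesh` whose vertices are sampled.
#' @param mirrored_aligned The reference `face_mesh` (typically the mirrored,
#'   best-fit-aligned copy).
#' @return A tibble of class `deviation_field` with one row per vertex:
#'   `vertex`, `closest_distance`, `signed_distance`, `dx`, `dy`, `dz`.
#' @export
compute_deviation <- function(original, mirrored_aligned) {
  stopifnot(inherits(original, "face_mesh"),
            inherits(mirrored_aligned, "face_mesh"))
  res <- .closest_on_surface(original$vertices,
                             mirrored_aligned$vertices,
                             mirrored_aligned$faces)
  disp <- res$closest - original$vertices
  vn <- vertex_normals(original)
  sgn <- sign(rowSums(disp * vn))
  sgn[sgn == 0] <- 1
  out <- tibble(
    vertex = seq_len(nrow(original$vertices)),
    closest_distance = res$distance,
    signed_distance = sgn * res$distance,
    dx = disp[, 1], dy = disp[, 2], dz = disp[, 3]
  )
  class(out) <- c("deviation_field", class(out))
  out
}

#' Regional deviation summary (RMSE and MFM)
#'
#' Summarises a deviation field over a vertex subset: the root-mean-squared
#' deviation (RMSE) and the maximum absolute deviation (maximum facial
#' misalignment, MFM), overall and per axis. Per-axis values are computed on
#' the corresponding displacement component.
#'
#' @param field A `deviation_field` from [compute_deviation()].
#' @param region_vertices Integer vertex indices of the region.
#' @param region Optional region label carried into the output.
#' @return A one-row-per-axis tibble with columns `region`, `axis` (one of
#'   `overall`, `X`, `Y`, `Z`), `rmse`, `mfm`, `n_vertices`.
#' @export
summarize_region <- function(field, region_vertices, region = NA_character_) {
  region_vertices <- as.integer(region_vertices)
  if (length(region_vertices) == 0) abort("Empty region.")
  if (any(region_vertices < 1L) || any(region_vertices > nrow(field))) {
    abort("Region vertex indices out of range.")
  }
  f <- field[match(region_vertices, field$vertex), ]
  comp <- list(overall = f$closest_distance, X = abs(f$dx), Y = abs(f$dy),
               Z = abs(f$dz))
  tibble(
    region = region,
    axis = names(comp),
    rmse = vapply(comp, function(v) sqrt(mean(v^2)), 0),
    mfm = vapply(comp, max, 0),
    n_vertices = length(region_vertices)
  )
}

#' Export a deviation colormap as PLY
#'
#' Writes the mesh with per-vertex RGB from a symmetric diverging scale
#' (blue, negative, through green at zero to red, positive) applied to the
#' signed distance. Scale limits default to the maximum absolute signed
#' deviation so the extremes of asymmetry saturate the colour ends.
#'
#' @param field A `deviation_field` matching `mesh`.
#' @param mesh The `face_mesh` the field was computed on.
#' @param path Output `.ply` path.
#' @param limit Colour-scale half-range in mm; default `max(abs(signed))`.
#' @param format `"ascii"` (default) or `"binary_little_endian"`.
#' @return `path` invisibly, with attribute `limit` (the half-range used).
#' @export
export_colormap <- function(field, mesh, path, limit = NULL,
                            format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  if (nrow(field) != nrow(mesh$vertices)) {
    abort("Deviation field and mesh have different vertex counts.")
  }
  s <- field$signed_distance
  limit <- limit %||% max(abs(s), 0)
  # symmetric diverging ramp centred on zero
  u <- if (limit > 0) pmax(-1, pmin(1, s / limit)) else rep(0, length(s))
  ramp <- grDevices::colorRamp(c("#2166AC", "#4393C3", "#7FBC41", "#D6604D",
                                 "#B2182B"))
  rgb <- round(ramp((u + 1) / 2))

  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    "comment faceasym deviation colormap",
    paste("element vertex", nv),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (format == "ascii") {
    vl <- sprintf("%.6f %.6f %.6f %d %d %d",
                  mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                  rgb[, 1], rgb[, 2], rgb[, 3])
    fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
    writeLines(c(header, vl, fl), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writLines <- paste0(paste(header, collapse = "\n"), "\n")
    writeBin(charToRaw(writLines), con)
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(rgb[i, ]), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  }
  out <- invisible(path)
  attr(out, "limit") <- limit
  out
}

#' Full mirroring-and-overlapping analysis
#'
#' The reference pipeline for facial asymmetry: mirror the posed face across
#' the midsagittal plane, rigidly best-fit the mirrored copy back onto the
#' original (trimmed ICP), compute per-vertex point-to-surface deviations, and
#' summarise RMSE / MFM per region of interest and axis.
#'
#' @param mesh A `face_mesh` in the normalized frame.
#' @param landmarks The matching posed `landmark_set` (used to build region
#'   masks).
#' @param params ICP settings, see [icp_settings()].
#' @param regions Optional precomputed list of region masks (from
#'   [region_masks()]); computed from the landmarks when `NULL`.
#' @return A list of class `mirror_analysis` with elements `field`
#'   (deviation field), `summary` (tibble region x axis with rmse/mfm),
#'   `alignment` (the ICP transform), and `mirrored` (the aligned mirror
#'   mesh).
#' @export
mirror_overlap_analysis <- function(mesh, landmarks, params = icp_settings(),
                                    regions = NULL) {
  mir <- mirror_mesh(mesh)
  tf <- best_fit_align(mir, mesh, params = params)
  mir_aligned <- apply_transform(tf, mir)
  field <- compute_deviation(mesh, mir_aligned)
  regions <- regions %||% region_masks(mesh, landmarks)
  summary <- bind_rows(lapply(names(regions), function(r) {
    summarize_region(field, regions[[r]], region = r)
  }))
  structure(list(field = field, summary = summary, alignment = tf,
                 mirrored = mir_aligned),
            class = "mirror_analysis")
}

#' @export
print.mirror_analysis <- function(x, ...) {
  cat("<mirror_analysis>\n")
  ov <- x$summary[x$summary$axis == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-17s RMSE %6.3f mm  MFM %6.3f mm  (%d vertices)\n",
                ov$region[i], ov$rmse[i], ov$mfm[i], ov$n_vertices[i]))
  }
  invisible(x)
}

#' Tidy a mirror-overlap analysis
#'
#' @param x A `mirror_analysis`.
#' @param ... Unused.
#' @return The region x axis summary tibble (rmse, mfm, n_vertices).
#' @method tidy mirror_analysis
#' @export
tidy.mirror_analysis <- function(x, ...) x$summary

#' One-row summary of a mirror-overlap analysis
#'
#' @param x A `mirror_analysis`.
#' @param ... Unused.
#' @return A tibble with whole-face RMS / MFM and ICP diagnostics.
#' @method glance mirror_analysis
#' @export
glance.mirror_analysis <- function(x, ...) {
  tibble(
    n_vertices = nrow(x$field),
    rms_overall = sqrt(mean(x$field$closest_distance^2)),
    mfm_overall = max(x$field$closest_distance),
    icp_rms = attr(x$alignment, "final_rms"),
    icp_iterations = attr(x$alignment, "iterations"),
    icp_converged = attr(x$alignment, "converged")
  )
}
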