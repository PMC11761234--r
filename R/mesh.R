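#' Triangulated facial surface
#'
#' Constructs a `face_mesh`: a triangulated 3D surface in millimetres. This is
#' the container every surface-based operation in the package consumes and
#' returns.
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z) in mm.
#' @param faces Integer matrix with 3 columns of 1-based vertex indices.
#' @param frame_tag Label for the coordinate frame, `"raw"` or `"normalized"`.
#' @return An object of class `face_mesh` with elements `vertices`, `faces`
#'   and `frame_tag`.
#' @export
face_mesh <- function(vertices, faces, frame_tag = "raw") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) abort("`vertices` must have 3 columns.")
  if (ncol(faces) != 3) abort("`faces` must have 3 columns.")
  if (nrow(vertices) < 4 || nrow(faces) < 1) {
    abort("A face_mesh needs at least 4 vertices and 1 face.")
  }
  if (!all(is.finite(vertices))) abort("All vertex coordinates must be finite.")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    abort("Face indices must reference existing vertices (1-based).")
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen)) {
    abort(paste0("Degenerate face(s) with repeated vertices at rows: ",
                 paste(head(which(degen), 5), collapse = ", ")))
  }
  frame_tag <- match.arg(frame_tag, c("raw", "normalized"))
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, frame_tag = frame_tag),
            class = "face_mesh")
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("<face_mesh: %d vertices, %d faces, frame=%s>\n",
              nrow(x$vertices), nrow(x$faces), x$frame_tag))
  invisible(x)
}

#' @export
format.face_mesh <- function(x, ...) {
  sprintf("<face_mesh: %d vertices, %d faces>", nrow(x$vertices), nrow(x$faces))
}

#' Read a Wavefront OBJ surface
#'
#' Parses `v` and `f` records; polygonal faces are fan-triangulated from the
#' first vertex. Texture (`vt`), normal (`vn`) and other records are ignored.
#' OBJ 1-based indices (including negative, relative indices) are resolved to
#' the package's internal 1-based convention.
#'
#' @param path Path to an OBJ file.
#' @param frame_tag Frame label to attach, default `"raw"`.
#' @return A [face_mesh()].
#' @export
read_obj <- function(path, frame_tag = "raw") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(toks, function(t) if (length(t)) t[[1]] else "", "")

  vlines <- which(keys == "v")
  verts <- matrix(NA_real_, length(vlines), 3)
  for (i in seq_along(vlines)) {
    t <- toks[[vlines[i]]]
    if (length(t) < 4) {
      abort(paste0("Malformed vertex record at line ", vlines[i]))
    }
    xyz <- suppressWarnings(as.numeric(t[2:4]))
    if (any(is.na(xyz))) {
      abort(paste0("Malformed vertex record at line ", vlines[i]))
    }
    verts[i, ] <- xyz
  }

  flines <- which(keys == "f")
  faces_list <- vector("list", length(flines))
  for (i in seq_along(flines)) {
    t <- toks[[flines[i]]][-1]
    # strip vt/vn suffixes ("7/1/3" -> "7")
    idx <- suppressWarnings(as.integer(sub("/.*$", "", t)))
    if (length(idx) < 3 || any(is.na(idx)) || any(idx == 0L)) {
      abort(paste0("Malformed face record at line ", flines[i]))
    }
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    if (any(idx < 1L) || any(idx > nrow(verts))) {
      abort(paste0("Face index out of range at line ", flines[i]))
    }
    # fan triangulation of polygons
    k <- length(idx)
    faces_list[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }
  faces <- do.call(rbind, faces_list)
  if (length(vlines) == 0 || is.null(faces)) {
    abort(paste0("Empty mesh (no vertices or faces): ", path))
  }
  face_mesh(verts, faces, frame_tag = frame_tag)
}

#' Write a Wavefront OBJ surface
#'
#' @param mesh A [face_mesh()].
#' @param path Output path.
#' @param digits Significant digits for coordinates (default 9, round-trips
#'   within 1e-6 mm for facial-scale coordinates).
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, digits = 9) {
  stopifnot(inherits(mesh, "face_mesh"))
  v <- sprintf(paste0("v %.", digits, "g %.", digits, "g %.", digits, "g"),
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

# Area-weighted per-vertex normals, rows unit length.
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], F[, k], sum)
      vn[as.integer(names(acc)), c] <- vn[as.integer(names(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

# Bounding box helper: rows min/max, cols x/y/z.
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}
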