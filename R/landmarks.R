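#' Soft-tissue landmark vocabulary
#'
#' The registry of named craniofacial soft-tissue landmarks recognised by the
#' package. Bilateral landmarks occur once per side with identifier suffixes
#' `_L` / `_R` (anatomical left / right); midline landmarks carry no suffix.
#' The registry is extensible: supply `extra` rows for landmarks beyond the
#' core template vocabulary.
#'
#' @param extra Optional tibble with columns `base` (character) and
#'   `bilateral` (logical) to append.
#' @return A tibble with columns `base` and `bilateral`.
#' @export
landmark_vocabulary <- function(extra = NULL) {
  core <- tibble(
    base = c("Sal", "Ch", "Stb", "Go", "As", "Mt", "Tr", "Zg", "Ex", "He",
             "Me", "Gn", "Li"),
    bilateral = c(rep(TRUE, 10), FALSE, FALSE, FALSE)
  )
  if (!is.null(extra)) {
    extra <- as_tibble(extra)
    stopifnot(all(c("base", "bilateral") %in% names(extra)))
    core <- bind_rows(core, extra[, c("base", "bilateral")])
    if (anyDuplicated(core$base)) abort("Duplicate landmark base names.")
  }
  core
}

# Split "Go_L" -> list(base = "Go", side = "left"); "Me" -> midline.
split_landmark_id <- function(id) {
  side <- rep("midline", length(id))
  base <- id
  isl <- grepl("_L$", id)
  isr <- grepl("_R$", id)
  side[isl] <- "left"
  side[isr] <- "right"
  base[isl | isr] <- sub("_[LR]$", "", id[isl | isr])
  tibble(name = id, base = base, side = side)
}

#' Build a landmark set
#'
#' Validates identifiers against the landmark vocabulary and checks that every
#' bilateral landmark present on one side is present on the other.
#'
#' @param x Either a named list / named numeric matrix of 3D points (names are
#'   landmark identifiers such as `"Go_L"`, `"Me"`), or a data frame with
#'   columns `name`, `x`, `y`, `z`.
#' @param permissive If `TRUE`, identifiers outside the vocabulary are kept
#'   (with side inferred from the `_L`/`_R` suffix) instead of rejected.
#' @param vocabulary Landmark registry, see [landmark_vocabulary()].
#' @return A tibble of class `landmark_set` with columns `name`, `base`,
#'   `side`, `x`, `y`, `z`.
#' @export
landmark_set <- function(x, permissive = FALSE,
                         vocabulary = landmark_vocabulary()) {
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "x", "y", "z") %in% names(x)))
    df <- as_tibble(x[, c("name", "x", "y", "z")])
  } else {
    if (is.matrix(x)) x <- split(x, row(x, as.factor = TRUE)) # nocov
    pts <- lapply(x, as.numeric)
    if (is.null(names(pts)) || any(names(pts) == "")) {
      abort("Landmark points must be named.")
    }
    if (!all(lengths(pts) == 3)) abort("Each landmark needs 3 coordinates.")
    m <- do.call(rbind, pts)
    df <- tibble(name = names(pts), x = m[, 1], y = m[, 2], z = m[, 3])
  }
  if (anyDuplicated(df$name)) {
    abort(paste0("Duplicate landmark identifiers: ",
                 paste(unique(df$name[duplicated(df$name)]), collapse = ", ")))
  }
  if (!all(is.finite(c(df$x, df$y, df$z)))) {
    abort("Landmark coordinates must be finite.")
  }
  parts <- split_landmark_id(df$name)
  df$base <- parts$base
  df$side <- parts$side

  known <- df$base %in% vocabulary$base
  if (!permissive && any(!known)) {
    abort(paste0("Unknown landmark name(s): ",
                 paste(unique(df$name[!known]), collapse = ", "),
                 ". Set permissive = TRUE to keep them."))
  }
  # vocabulary landmarks must respect their laterality
  voc <- setNames(vocabulary$bilateral, vocabulary$base)
  mism <- known & ((df$side == "midline") == voc[df$base])
  if (any(mism)) {
    abort(paste0("Laterality mismatch for: ",
                 paste(df$name[mism], collapse = ", "),
                 " (bilateral landmarks need _L/_R, midline ones none)."))
  }
  # bilateral pairing check
  bil <- df[df$side != "midline", ]
  if (nrow(bil) > 0) {
    have <- split(bil$side, bil$base)
    missing <- unlist(lapply(names(have), function(b) {
      s <- have[[b]]
      c(if (!"left" %in% s) paste0(b, "_L"), if (!"right" %in% s) paste0(b, "_R"))
    }))
    if (length(missing) > 0) {
      abort(paste0("Bilateral landmark(s) missing a side: ",
                   paste(missing, collapse = ", ")))
    }
  }
  out <- df[, c("name", "base", "side", "x", "y", "z")]
  class(out) <- c("landmark_set", class(out))
  out
}

#' Read landmarks from file
#'
#' Two dialects are supported: JSON (`{"Go_L": [x, y, z], ...}`) and MeshLab
#' picked-points XML (`<point name="Go_L" x="..." y="..." z="..."/>`). Both
#' yield identical landmark sets for the same points.
#'
#' @param path Input file.
#' @param dialect `"json"` or `"picked_points"`; default guessed from the file
#'   extension (`.pp` is picked points).
#' @inheritParams landmark_set
#' @return A `landmark_set` tibble.
#' @export
read_landmarks <- function(path, dialect = NULL, permissive = FALSE,
                           vocabulary = landmark_vocabulary()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.pp$", path, ignore.case = TRUE)) {
      "picked_points"
    } else {
      "json"
    }
  }
  dialect <- match.arg(dialect, c("json", "picked_points"))
  pts <- switch(dialect,
    json = {
      raw <- jsonlite::read_json(path, simplifyVector = TRUE)
      lapply(raw, as.numeric)
    },
    picked_points = {
      doc <- xml2::read_xml(path)
      nodes <- xml2::xml_find_all(doc, ".//point")
      nm <- xml2::xml_attr(nodes, "name")
      setNames(lapply(seq_along(nodes), function(i) {
        as.numeric(c(xml2::xml_attr(nodes[i], "x"),
                     xml2::xml_attr(nodes[i], "y"),
                     xml2::xml_attr(nodes[i], "z")))
      }), nm)
    }
  )
  landmark_set(pts, permissive = permissive, vocabulary = vocabulary)
}

#' Write landmarks to file
#'
#' @param landmarks A `landmark_set`.
#' @param path Output file.
#' @param dialect `"json"` or `"picked_points"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, dialect = c("json", "picked_points")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    lst <- setNames(
      lapply(seq_len(nrow(landmarks)), function(i) {
        unname(c(landmarks$x[i], landmarks$y[i], landmarks$z[i]))
      }),
      landmarks$name
    )
    jsonlite::write_json(lst, path, digits = NA, auto_unbox = FALSE)
  } else {
    doc <- xml2::xml_new_root("PickedPoints")
    for (i in seq_len(nrow(landmarks))) {
      xml2::xml_add_child(doc, "point",
                          name = landmarks$name[i],
                          x = format(landmarks$x[i], digits = 17),
                          y = format(landmarks$y[i], digits = 17),
                          z = format(landmarks$z[i], digits = 17))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

# Side-resolved identifier: bilateral base + side -> "Go_L"; midline as-is.
resolve_landmark_id <- function(base, side, vocabulary = landmark_vocabulary()) {
  i <- match(base, vocabulary$base)
  if (is.na(i)) return(base) # unknown names pass through (permissive sets)
  if (!vocabulary$bilateral[i]) return(base)
  paste0(base, if (side == "left") "_L" else "_R")
}

# Coordinates of one landmark by full identifier; errors if absent.
lm_xyz <- function(landmarks, name) {
  i <- match(name, landmarks$name)
  if (is.na(i)) abort(paste0("Landmark not found: ", name))
  c(landmarks$x[i], landmarks$y[i], landmarks$z[i])
}

# Coordinate matrix (n x 3) in row order of the set.
lm_matrix <- function(landmarks) {
  m <- cbind(landmarks$x, landmarks$y, landmarks$z)
  rownames(m) <- landmarks$name
  m
}

# Replace coordinates wholesale, keeping names/sides.
lm_set_matrix <- function(landmarks, m) {
  landmarks$x <- m[, 1]
  landmarks$y <- m[, 2]
  landmarks$z <- m[, 3]
  landmarks
}
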