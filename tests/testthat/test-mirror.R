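test_that("mirroring negates X, preserves orientation, and is an involution", {
  m <- BASE_CASE$mesh
  mm <- mirror_mesh(m)
  expect_equal(mm$vertices[, 1], -m$vertices[, 1])
  expect_equal(mm$vertices[, 2:3], m$vertices[, 2:3])
  # winding is flipped so outward normals stay outward
  vn <- faceasym:::vertex_normals(mm)
  expect_true(all(vn[, 3] > 0))
  expect_equal(mirror_mesh(mm)$vertices, m$vertices)
  expect_equal(mirror_mesh(mm)$faces, m$faces)
})

test_that("best-fit alignment recovers a planted rigid motion", {
  set.seed(3)
  # an irregular subsample: a regular lattice is self-similar under
  # one-cell shifts and lets trimmed ICP lock into an aliased minimum
  pts <- BASE_CASE$mesh$vertices[sample(2304, 400), ]
  tf <- random_rigid(max_deg = 8, max_t = 4)
  moved <- apply_transform(tf, pts)
  rec <- best_fit_align(moved, pts)
  resid <- compose_transform(rec, tf)
  expect_lt(faceasym:::rotation_angle_deg(resid$rotation), 0.01)
  expect_lt(max(abs(resid$translation)), 0.01)
  expect_true(attr(rec, "converged"))
  expect_lt(attr(rec, "final_rms"), 0.01)
})

test_that("deviation to an identical surface is zero with positive sign", {
  m <- BASE_CASE$mesh
  f <- compute_deviation(m, m)
  expect_lt(max(f$closest_distance), 1e-9)
  expect_true(all(f$signed_distance >= 0))
})

test_that("deviation sign follows the outward normal", {
  m <- BASE_CASE$mesh
  vn <- faceasym:::vertex_normals(m)
  # inflate the reference surface outward: it then lies outside the
  # original everywhere, so signed distances must be positive
  out <- face_mesh(m$vertices + 0.5 * vn, m$faces)
  f <- compute_deviation(m, out)
  expect_true(all(f$signed_distance > 0))
  # and a deflated reference lies inside: negative signs
  inn <- face_mesh(m$vertices - 0.5 * vn, m$faces)
  f2 <- compute_deviation(m, inn)
  expect_true(all(f2$signed_distance < 0))
})

test_that("regional summaries satisfy the RMSE/MFM invariants", {
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("cheek", "X", 0,
                                       mode = "surface_bump", bump_mm = 2))
  an <- mirror_overlap_analysis(c2$mesh, c2$landmarks)
  s <- an$summary
  expect_true(all(s$mfm >= s$rmse - 1e-12))
  expect_true(all(s$rmse >= 0))
  for (r in unique(s$region)) {
    ov <- s$mfm[s$region == r & s$axis == "overall"]
    expect_true(all(s$mfm[s$region == r] <= ov + 1e-9))
  }
})

test_that("a planted surface bump is measured at its planted height", {
  # spec'd contract of the generator + mirror pipeline: a 2 mm cheek bump
  # yields a cheek MFM within [1.7, 2.3] mm
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("cheek", "X", 0,
                                       mode = "surface_bump", bump_mm = 2))
  res <- run_mirror_analysis(c2$mesh, c2$landmarks)
  s <- res$analysis$summary
  mfm <- s$mfm[s$region == "cheek" & s$axis == "overall"]
  expect_gte(mfm, 1.7)
  expect_lte(mfm, 2.3)
})

test_that("colormap export writes a well-formed PLY", {
  m <- BASE_CASE$mesh
  f <- compute_deviation(m, m)
  path <- withr::local_tempfile(fileext = ".ply")
  export_colormap(f, m, path, format = "ascii")
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  expect_true(any(grepl(paste0("element vertex ", nrow(m$vertices)), lines)))
  expect_true(any(grepl(paste0("element face ", nrow(m$faces)), lines)))
  expect_true(any(lines == "end_header"))
})
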