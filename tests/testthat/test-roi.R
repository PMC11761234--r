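test_that("all five regions select vertices on a posed face", {
  masks <- region_masks(BASE_MESH_POSED, BASE_LM_POSED)
  expect_named(masks, c("labial", "mandibular_angle", "cheek", "chin",
                        "articular"))
  expect_true(all(lengths(masks) > 0))
})

test_that("bilateral region masks are left-right symmetric in size", {
  for (f in list(define_mandibular_angle, define_cheek, define_articular)) {
    l <- f(BASE_MESH_POSED, BASE_LM_POSED, "left")
    r <- f(BASE_MESH_POSED, BASE_LM_POSED, "right")
    expect_equal(length(l$vertex_indices), length(r$vertex_indices))
  }
})

test_that("sided masks stay on their side of the midsagittal plane", {
  V <- BASE_MESH_POSED$vertices
  l <- define_cheek(BASE_MESH_POSED, BASE_LM_POSED, "left")
  r <- define_cheek(BASE_MESH_POSED, BASE_LM_POSED, "right")
  expect_true(all(V[l$vertex_indices, 1] > 0))
  expect_true(all(V[r$vertex_indices, 1] < 0))
})

test_that("lateral extents use the half-width of bilateral pairs", {
  # regression: averaging the signed X of an exactly mirrored pair gives 0
  # and collapses the chin slab to its margin width
  V <- BASE_MESH_POSED$vertices
  chin <- define_chin(BASE_MESH_POSED, BASE_LM_POSED)$vertex_indices
  mt_x <- abs(BASE_LM_POSED$x[BASE_LM_POSED$name == "Mt_L"])
  expect_gt(max(abs(V[chin, 1])), mt_x / 2)
  expect_lt(max(abs(V[chin, 1])), mt_x + 5)
})

test_that("every planted bump centre falls inside its own region mask", {
  masks <- region_masks(BASE_MESH_POSED, BASE_LM_POSED)
  V <- BASE_MESH_POSED$vertices
  geo <- faceasym:::bump_geometry()
  for (r in names(geo)) {
    ctr <- geo[[r]]$center
    nearest <- which.min((V[, 1] - ctr[1])^2 + (V[, 2] - ctr[2])^2)
    expect_true(nearest %in% masks[[r]],
                label = sprintf("bump centre of '%s' inside its mask", r))
  }
})

test_that("region definitions report missing landmarks and empty selections", {
  lm <- BASE_LM_POSED[!(BASE_LM_POSED$name %in% c("Mt_L", "Mt_R")), ]
  class(lm) <- c("landmark_set", class(lm))
  expect_error(define_chin(BASE_MESH_POSED, lm), "Mt")
  cfg <- roi_config(fan_radius_mm = 1e-6)
  expect_error(define_mandibular_angle(BASE_MESH_POSED, BASE_LM_POSED,
                                       "left", cfg),
               "no vertices")
})

test_that("region masks export as JSON and read back identically", {
  masks <- region_masks(BASE_MESH_POSED, BASE_LM_POSED)
  path <- withr::local_tempfile(fileext = ".json")
  write_region_masks(masks, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(lapply(back, as.integer), lapply(masks, as.integer))
})
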