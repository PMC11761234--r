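test_that("base faces are deterministic and exactly symmetric", {
  a <- generate_base_face(seed = 5)
  b <- generate_base_face(seed = 5)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$landmarks$x, b$landmarks$x)
  c <- generate_base_face(seed = 6)
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
  # the vertex set is closed under x -> -x
  V <- a$mesh$vertices
  key <- function(M) paste(sprintf("%.9f", M[, 1]), sprintf("%.9f", M[, 2]),
                           sprintf("%.9f", M[, 3]))
  expect_setequal(key(V), key(cbind(-V[, 1], V[, 2:3])))
  # bilateral landmark pairs are exact mirror images
  lm <- a$landmarks
  for (b_ in unique(lm$base[lm$side != "midline"])) {
    l <- lm[lm$name == paste0(b_, "_L"), ]
    r <- lm[lm$name == paste0(b_, "_R"), ]
    expect_equal(l$x, -r$x, ignore_attr = TRUE)
    expect_equal(l$y, r$y, ignore_attr = TRUE)
    expect_equal(l$z, r$z, ignore_attr = TRUE)
  }
  expect_error(generate_base_face(resolution = 8), "resolution")
})

test_that("zero-magnitude deformation is the identity", {
  c0 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("cheek", "X", 0,
                                       mode = "landmark_shift"))
  expect_equal(c0$mesh$vertices, BASE_CASE$mesh$vertices)
  expect_equal(c0$landmarks$x, BASE_CASE$landmarks$x)
  expect_equal(nrow(c0$truth), 1L)
})

test_that("deformations are local to the region's support", {
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("cheek", "X", 0,
                                       mode = "surface_bump", bump_mm = 2))
  moved <- rowSums((c2$mesh$vertices - BASE_CASE$mesh$vertices)^2) > 1e-18
  geo <- faceasym:::bump_geometry()$cheek
  V <- BASE_CASE$mesh$vertices
  inside <- sqrt((V[, 1] - geo$center[1])^2 +
                   (V[, 2] - geo$center[2])^2) < geo$radius
  expect_true(all(!moved | inside))
  expect_true(any(moved))
})

test_that("landmark shifts touch only the region's right-side landmark", {
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("chin", "Y", 1.5,
                                       mode = "landmark_shift"))
  d <- abs(cbind(c2$landmarks$x - BASE_CASE$landmarks$x,
                 c2$landmarks$y - BASE_CASE$landmarks$y,
                 c2$landmarks$z - BASE_CASE$landmarks$z))
  changed <- which(rowSums(d) > 0)
  expect_equal(c2$landmarks$name[changed], "Mt_R")
  expect_equal(d[changed, 2], 1.5, ignore_attr = TRUE)
  expect_equal(c2$mesh$vertices, BASE_CASE$mesh$vertices)
})

test_that("a region cannot be deformed twice", {
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("chin", "X", 1,
                                       mode = "landmark_shift"))
  expect_error(
    apply_asymmetry(c2, asymmetry_spec("chin", "Z", 1,
                                       mode = "landmark_shift")),
    "already"
  )
})

test_that("calibrated shifts hit their target asymmetry index", {
  shift <- calibrate_shift(BASE_CASE, "chin", "X", 5)
  expect_gt(shift, 0)
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("chin", "X", shift,
                                       mode = "landmark_shift"))
  res <- evaluate_template(c2$landmarks)
  expect_equal(max(res$aai_percent[res$region == "chin"]), 5,
               tolerance = 1e-3)
})

test_that("cohorts are reproducible and carry their target grades", {
  a <- generate_cohort(n = 3, seed = 7,
                       grade_mix = c(mild = 1, moderate = 0, severe = 0))
  b <- generate_cohort(n = 3, seed = 7,
                       grade_mix = c(mild = 1, moderate = 0, severe = 0))
  expect_equal(length(a), 3L)
  for (i in 1:3) {
    expect_identical(a[[i]]$mesh$vertices, b[[i]]$mesh$vertices)
    expect_equal(attr(a[[i]], "target_grade"), "mild")
    expect_equal(nrow(a[[i]]$truth), 0L)
  }
  expect_error(generate_cohort(n = 2, grade_mix = c(mild = 0.5)), "sum to 1")
})

test_that("synthetic cases round trip through their on-disk form", {
  dir <- withr::local_tempdir()
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("labial", "X", 1,
                                       mode = "landmark_shift"))
  write_synthetic_case(c2, dir, stem = "subj")
  m <- read_obj(file.path(dir, "subj.obj"))
  lm <- read_landmarks(file.path(dir, "subj_landmarks.json"))
  truth <- read_table(file.path(dir, "subj_truth.csv"))
  expect_equal(m$vertices, c2$mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(lm$name, c2$landmarks$name)
  expect_equal(truth$region, "labial")
})
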