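test_that("the angular-parameter registry has 15 rows with two shared triplets", {
  p <- angular_parameters()
  expect_equal(nrow(p), 15L)
  expect_equal(sum(duplicated(p$parameter)), 2L)
  expect_equal(sort(p$parameter[duplicated(p$parameter)]),
               c("Me-Go-Mt", "Tr-Zg-Go"))
  expect_equal(unname(table(p$region)[c("labial", "mandibular_angle", "cheek",
                                        "chin", "articular")]),
               rep(3L, 5), ignore_attr = TRUE)
  expect_true(all(p$axis %in% c("X", "Y", "Z")))
})

test_that("spatial angles match planar geometry on known configurations", {
  lm <- landmark_set(list(
    Go_L = c(1, 0, 0), Go_R = c(-1, 0, 0),
    Mt_L = c(0, 0, 0), Mt_R = c(0, 0, 0),
    Me = c(0, 1, 0)
  ), permissive = TRUE)
  # right angle at Mt between Go_L and Me
  expect_equal(compute_angle(lm, c("Go", "Mt", "Me"), "left"), 90)
  # straight angle through collinear points
  expect_equal(compute_angle(lm, c("Go", "Mt", "Go"), "left"), 0)
  lm2 <- landmark_set(list(Go_L = c(1, 0, 0), Go_R = c(-1, 0, 0),
                           Me = c(0, 0, 0), Gn = c(0, 1, 1)))
  expect_equal(compute_angle(lm2, c("Go", "Me", "Gn"), "left"),
               90, tolerance = 1e-9)
  # degenerate zero-length arm
  lm3 <- landmark_set(list(Go_L = c(0, 0, 0), Go_R = c(0, 0, 0),
                           Me = c(0, 0, 0), Gn = c(0, 1, 1)))
  expect_error(compute_angle(lm3, c("Go", "Me", "Gn"), "left"), "Degenerate")
})

test_that("the asymmetry index is the relative right-left difference", {
  expect_equal(compute_aai(100, 102), 2)
  expect_equal(compute_aai(100, 98), 2)
  expect_equal(compute_aai(50, 50), 0)
  # the left angle is the denominator, so the index is not symmetric
  expect_equal(compute_aai(80, 100), 25)
  expect_equal(compute_aai(100, 80), 20)
  expect_equal(compute_aai(100, 80, denominator = "min"), 25)
  expect_error(compute_aai(0, 10), "positive")
})

test_that("a symmetric face scores zero asymmetry on every parameter", {
  res <- evaluate_template(BASE_LM_POSED)
  expect_equal(nrow(res), 15L)
  expect_true(all(res$aai_percent < 1e-9))
  expect_true(all(res$grade == "mild"))
})

test_that("shared triplets carry identical angles in both their rows", {
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("chin", "X", 2,
                                       mode = "landmark_shift"))
  res <- evaluate_template(c2$landmarks)
  for (pp in c("Tr-Zg-Go", "Me-Go-Mt")) {
    rows <- res[res$parameter == pp, ]
    expect_equal(nrow(rows), 2L)
    expect_equal(rows$left_deg[1], rows$left_deg[2])
    expect_equal(rows$right_deg[1], rows$right_deg[2])
    expect_equal(rows$aai_percent[1], rows$aai_percent[2])
  }
})

test_that("region grades follow the all-mild aggregation of their axes", {
  c2 <- apply_asymmetry(BASE_CASE,
                        asymmetry_spec("cheek", "Z", 3,
                                       mode = "landmark_shift"))
  res <- evaluate_template(c2$landmarks)
  rg <- wireframe_region_grades(res)
  expect_equal(nrow(rg), 5L)
  for (r in rg$region) {
    ax <- res$grade[res$region == r]
    expect_equal(as.character(rg$grade[rg$region == r]),
                 as.character(aggregate_region(ax)))
  }
})

test_that("the wireframe edge list shrinks gracefully with missing landmarks", {
  full <- build_wireframe(BASE_CASE$landmarks)
  expect_true(nrow(full) > 0)
  expect_true(all(full$from < full$to))
  expect_equal(anyDuplicated(paste(full$from, full$to)), 0L)
  partial_lm <- BASE_CASE$landmarks[BASE_CASE$landmarks$base %in%
                                      c("Tr", "Zg", "Go"), ]
  class(partial_lm) <- c("landmark_set", class(partial_lm))
  partial <- build_wireframe(partial_lm)
  expect_true(nrow(partial) < nrow(full))
  expect_true(all(paste(partial$from, partial$to) %in%
                    paste(full$from, full$to)))
  empty <- build_wireframe(BASE_CASE$landmarks[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("wireframe OBJ export writes one line element per edge", {
  path <- withr::local_tempfile(fileext = ".obj")
  edges <- build_wireframe(BASE_CASE$landmarks)
  write_wireframe_obj(BASE_CASE$landmarks, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), nrow(BASE_CASE$landmarks))
  expect_equal(sum(startsWith(lines, "l ")), nrow(edges))
})

test_that("wireframe results expose tidy and glance views", {
  res <- evaluate_template(BASE_LM_POSED)
  td <- generics::tidy(res)
  expect_false(inherits(td, "wireframe_result"))
  expect_equal(nrow(td), 15L)
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_mild, 15L)
})
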