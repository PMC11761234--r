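test_that("grading bands are half-open on the left-closed side", {
  aai <- grading_criteria("aai")
  expect_equal(as.character(classify_statistic(c(0, 0.999, 1, 2.999, 3, 10),
                                               aai)),
               c("mild", "mild", "moderate", "moderate", "severe", "severe"))
  c1 <- grading_criteria(1)
  expect_equal(c1$statistic, "RMSE")
  expect_equal(as.character(classify_statistic(c(0.499, 0.5, 0.999, 1), c1)),
               c("mild", "moderate", "moderate", "severe"))
  c2 <- grading_criteria(2)
  expect_equal(c2$statistic, "MFM")
  expect_equal(as.character(classify_statistic(c(2.999, 3, 5.999, 6), c2)),
               c("mild", "moderate", "moderate", "severe"))
  c3 <- grading_criteria(3)
  expect_equal(c3$statistic, "MFM")
  expect_equal(as.character(classify_statistic(c(0.999, 1, 1.999, 2), c3)),
               c("mild", "moderate", "moderate", "severe"))
  expect_error(classify_statistic(-1, aai), "non-negative")
  expect_error(classify_statistic(NaN, aai), "finite")
})

test_that("a region is mild only when all three axes are mild", {
  expect_equal(as.character(aggregate_region(c("mild", "mild", "mild"))),
               "mild")
  expect_equal(as.character(aggregate_region(c("mild", "moderate", "mild"))),
               "moderate")
  expect_equal(as.character(aggregate_region(c("severe", "mild", "moderate"))),
               "severe")
  expect_error(aggregate_region(c("mild", "mild")), "three")
})

test_that("deviation grading appends aggregate rows consistent with the axes", {
  s <- tibble::tibble(
    region = rep(c("labial", "chin"), each = 4),
    axis = rep(c("overall", "X", "Y", "Z"), 2),
    rmse = c(0.4, 0.2, 0.2, 0.3, 1.5, 0.9, 1.2, 0.4),
    mfm = c(1.2, 0.5, 0.8, 1.1, 4.0, 2.5, 3.5, 1.0),
    n_vertices = 10L
  )
  g <- grade_deviation(s, grading_criteria(2))
  expect_setequal(unique(g$axis), c("X", "Y", "Z", "region"))
  for (r in c("labial", "chin")) {
    ax <- g$grade[g$region == r & g$axis %in% c("X", "Y", "Z")]
    agg <- g$grade[g$region == r & g$axis == "region"]
    expect_equal(as.character(agg), as.character(aggregate_region(ax)))
  }
  # criterion 2 thresholds on MFM: chin Y (3.5) is moderate, labial all mild
  expect_equal(as.character(g$grade[g$region == "labial" & g$axis == "region"]),
               "mild")
  expect_equal(as.character(g$grade[g$region == "chin" & g$axis == "region"]),
               "moderate")
})

test_that("severity grades form an ordered scale", {
  g <- severity_grade(c("severe", "mild", "moderate"))
  expect_true(is.ordered(g))
  expect_true(g[1] > g[3] && g[3] > g[2])
  expect_error(severity_grade("extreme"), "Unknown severity")
})
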