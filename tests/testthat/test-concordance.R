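test_that("half-up rounding sends ties away from zero", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(0.15, 1), 0.2)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(87.5, 0), 88)
  # base round() ties-to-even would give 0.1 here; half-up must give 0.2
  expect_equal(round_half_up(0.25, 1), 0.3)
})

test_that("recognition counts moderate-or-severe subjects", {
  rr <- recognition_rate(c("mild", "moderate", "severe", "mild"))
  expect_equal(rr$numerator, 2L)
  expect_equal(rr$denominator, 4L)
  expect_equal(rr$rate, 0.5)
  expect_error(recognition_rate(character(0)), "empty")
})

test_that("the consistency rate is the min/max ratio of recognition rates", {
  expect_equal(consistency_rate(0.5, 1), 50)
  expect_equal(consistency_rate(1, 0.5), 50)
  expect_equal(consistency_rate(0.75, 0.75), 100)
  expect_true(is.na(consistency_rate(0, 0)))
  expect_equal(consistency_rate(0, 0.5), 0)
  expect_error(consistency_rate(1.2, 0.5), "0, 1")
})

test_that("grade matrices enforce completeness and aggregate consistency", {
  df <- expand.grid(subject = 1:2, region = c("labial", "chin"),
                    axis = c("X", "Y", "Z"), stringsAsFactors = FALSE)
  df$grade <- "mild"
  gm <- grade_matrix(df, method_tag = "wireframe")
  expect_s3_class(gm, "grade_matrix")
  expect_true(all(gm$method == "wireframe"))
  expect_error(grade_matrix(df[-1, ]), "incomplete")
  expect_error(grade_matrix(transform(df, region = "nose")), "Unknown region")
  # aggregate rows must agree with aggregate_region of the axis rows
  agg <- unique(df[, c("subject", "region")])
  agg$axis <- "region"
  agg$grade <- "severe"
  expect_error(grade_matrix(rbind(df, agg)), "disagree")
  agg$grade <- "mild"
  expect_s3_class(grade_matrix(rbind(df, agg)), "grade_matrix")
})

test_that("counts replay reproduces hand-computed consistency tables", {
  counts <- tibble::tibble(region = c("labial", "chin"),
                           mirror_n = c(12, 0), template_n = c(24, 0))
  out <- consistency_from_counts(counts, n = 24)
  expect_equal(out$consistency[out$region == "labial"], 50)
  expect_true(is.na(out$consistency[out$region == "chin"]))
  # the average row averages the exact values, then rounds
  counts2 <- tibble::tibble(region = c("labial", "chin"),
                            mirror_n = c(16, 17), template_n = c(24, 24))
  out2 <- consistency_from_counts(counts2, n = 24)
  avg <- out2$consistency[out2$region == "average"]
  expect_equal(avg, round_half_up(mean(c(16, 17) / 24 * 100), 1))
})

test_that("overall and per-dimension tables agree with direct counting", {
  set.seed(5)
  grid <- expand.grid(subject = 1:6,
                      region = c("labial", "mandibular_angle", "cheek",
                                 "chin", "articular"),
                      axis = c("X", "Y", "Z"), stringsAsFactors = FALSE)
  mk <- function() {
    g <- grid
    g$grade <- sample(c("mild", "moderate", "severe"), nrow(g),
                      replace = TRUE)
    grade_matrix(g)
  }
  a <- mk()
  b <- mk()
  ov <- build_overall_table(a, b)
  expect_equal(nrow(ov), 6L)
  dm <- build_dimension_table(a, b)
  expect_equal(nrow(dm), 15L)
  # spot check one cell against direct counting
  cnt <- function(gm, r, ax) {
    sum(gm$grade[gm$region == r & gm$axis == ax] %in% c("moderate", "severe"))
  }
  i <- dm$region == "cheek" & dm$axis == "Y"
  expect_equal(dm$mirror_n[i], cnt(a, "cheek", "Y"))
  expect_equal(dm$template_n[i], cnt(b, "cheek", "Y"))
})

test_that("Cohen's kappa matches its definition on known tables", {
  expect_equal(cohen_kappa(c("a", "b", "a", "b"), c("a", "b", "a", "b")), 1)
  # both raters constant but different: chance agreement 1, no agreement
  expect_equal(cohen_kappa(rep("a", 5), rep("b", 5)), 0)
  expect_error(cohen_kappa("a", c("a", "b")), "equal length")
})

test_that("Cohen's kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  for (i in 1:20) {
    a <- sample(c("mild", "moderate", "severe"), 30, replace = TRUE)
    b <- sample(c("mild", "moderate", "severe"), 30, replace = TRUE)
    tab <- table(factor(a, levels = c("mild", "moderate", "severe")),
                 factor(b, levels = c("mild", "moderate", "severe")))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa tables cover every region-axis cell", {
  grid <- expand.grid(subject = 1:4,
                      region = c("labial", "chin"),
                      axis = c("X", "Y", "Z"), stringsAsFactors = FALSE)
  g1 <- grid; g1$grade <- rep(c("mild", "moderate"), length.out = nrow(grid))
  g2 <- g1
  kt <- kappa_table(grade_matrix(g1), grade_matrix(g2))
  expect_equal(nrow(kt), 6L)
  expect_true(all(kt$kappa == 1))
})
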