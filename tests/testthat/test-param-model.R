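default_B1 <- c(23L, 47L, 113L)
default_B2 <- c(37L, 79L, 167L)

# the ten formula classes of the two generated fixed-size codes
formula_classes <- list(
  "b1+b2"   = c(0, 1, 1, 0, 0),
  "2*b1+b2" = c(0, 2, 1, 0, 0),
  "b1*b2"   = c(1, 0, 0, 0, 0),
  "b1-1"    = c(0, 1, 0, 0, -1),
  "b1"      = c(0, 1, 0, 0, 0),
  "b1-2"    = c(0, 1, 0, 0, -2),
  "b3"      = c(0, 0, 0, 1, 0),
  "b3-1"    = c(0, 0, 0, 1, -1),
  "b2-1"    = c(0, 0, 1, 0, -1),
  "b2"      = c(0, 0, 1, 0, 0))

as_coeffs <- function(a) list(a0 = a[1], a1 = a[2], a2 = a[3], a3 = a[4], a4 = a[5])

test_that("the worked factor pair (93, 153) solves to 2*b1 + b2", {
  fm <- fit_factor_model(93, 153)
  expect_identical(c(fm$a0, fm$a1, fm$a2, fm$a3, fm$a4), c(0L, 2L, 1L, 0L, 0L))
  expect_identical(fm$formula, "2*b1+b2")
  expect_identical(predict_factor(fm, default_B1), 93L)
  expect_identical(predict_factor(fm, default_B2), 153L)
})

test_that("observed factor pairs recover their generating expressions", {
  # bilinear term: 1081 = 23*47, 2923 = 37*79
  fm <- fit_factor_model(1081, 2923)
  expect_identical(c(fm$a0, fm$a1, fm$a2, fm$a3, fm$a4), c(1L, 0L, 0L, 0L, 0L))
  # linear term with constant: 22 = 23 - 1, 36 = 37 - 1
  fm <- fit_factor_model(22, 36)
  expect_identical(c(fm$a1, fm$a4), c(1L, -1L))
  # constant factor
  fm <- fit_factor_model(12, 12)
  expect_identical(c(fm$a0, fm$a1, fm$a2, fm$a3, fm$a4), c(0L, 0L, 0L, 0L, 12L))
  expect_identical(predict_factor(fm, c(5, 6, 7)), 12L)
})

test_that("all ten formula classes round-trip exactly with sparse support", {
  for (nm in names(formula_classes)) {
    a <- formula_classes[[nm]]
    y1 <- predict_factor(as_coeffs(a), default_B1)
    y2 <- predict_factor(as_coeffs(a), default_B2)
    fm <- fit_factor_model(y1, y2)
    expect_identical(c(fm$a0, fm$a1, fm$a2, fm$a3, fm$a4), as.integer(a))
    expect_identical(fm$formula, nm)
    expect_lte(sum(c(fm$a0, fm$a1, fm$a2, fm$a3, fm$a4) != 0), 2L)
    expect_identical(predict_factor(fm, default_B1), y1)   # round trip
    expect_identical(predict_factor(fm, default_B2), y2)
  }
})

test_that("support search is deterministic about failure modes", {
  expect_error(fit_factor_model(1, 1e6), "unmodellable")
  # (400, 624): both 16*b1 + 32 and 7*b2 + 71 fit at the same rank
  expect_error(fit_factor_model(400, 624), "ambiguous.*16\\*b1\\+32.*7\\*b2\\+71")
  expect_error(fit_factor_model(1, 2, B1 = c(2, 3, 4), B2 = c(2, 3, 4)), "differ")
  expect_error(fit_factor_model(1.5, 2), "integer")
})

test_that("code-level fitting tabulates positions and collects failures", {
  tab <- fit_code_model(data.frame(position = c("L6", "L10", "bad"),
                                   y1 = c(93, 70, 1), y2 = c(153, 116, 1e6)))
  expect_identical(tab$formula[1:2], c("2*b1+b2", "b1+b2"))
  expect_true(is.na(tab$formula[3]) && grepl("unmodellable", tab$error[3]))
  expect_identical(nrow(fit_code_model(data.frame(y1 = numeric(), y2 = numeric()))), 0L)
})

test_that("the predicted factor is the model value at any tile size", {
  expect_identical(predict_factor(as_coeffs(c(0, 0, 0, 0, 0)), c(9, 9, 9)), 0L)
  expect_identical(predict_factor(as_coeffs(c(1, 2, 3, 4, 5)), c(2, 3, 5)),
                   as.integer(1 * 6 + 2 * 2 + 3 * 3 + 4 * 5 + 5))
  # fit/predict round trip on random sparse models
  for (sd in 1:20) {
    a <- numeric(5)
    pick <- with_seed(sd, sample(5, sample(0:2, 1)))
    a[pick] <- with_seed(sd + 50, sample(c(-3:-1, 1:9), length(pick), replace = TRUE))
    y1 <- predict_factor(as_coeffs(a), default_B1)
    y2 <- predict_factor(as_coeffs(a), default_B2)
    fm <- tryCatch(fit_factor_model(y1, y2), error = function(e) NULL)
    if (!is.null(fm)) {   # ambiguous pairs legitimately error
      expect_identical(predict_factor(fm, default_B1), y1)
      expect_identical(predict_factor(fm, default_B2), y2)
      expect_lte(sum(c(fm$a0, fm$a1, fm$a2, fm$a3, fm$a4) != 0), 2L)
    }
  }
})
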