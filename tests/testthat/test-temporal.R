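test_that("trend fitting matches the closed form and an independent lm fit", {
  # exact line: slope recovered exactly, overwhelming significance
  tr <- fit_trend(marker_series("p1", "platelets", 0:9, 2 + 3 * (0:9)))
  expect_equal(tr$beta1, 3, tolerance = 1e-12)
  expect_equal(tr$beta0, 2, tolerance = 1e-12)
  expect_lt(tr$p_value, 1e-12)
  expect_identical(tr$direction, "increasing")
  # constant series: zero slope, no direction
  tr0 <- fit_trend(marker_series("p1", "urea", 0:5, rep(30, 6)))
  expect_equal(tr0$beta1, 0)
  expect_identical(tr0$direction, "none")
  # noisy series against lm() as the independent oracle
  set.seed(11)
  t <- seq(0, 345, by = 15)
  y <- 250 - 0.8 * t + rnorm(length(t), 0, 1)
  tr2 <- fit_trend(t, y)
  fit <- lm(y ~ t)
  expect_equal(tr2$beta1, unname(coef(fit)[2]), tolerance = 1e-9)
  expect_equal(tr2$beta0, unname(coef(fit)[1]), tolerance = 1e-9)
  expect_equal(tr2$p_value, summary(fit)$coefficients[2, 4], tolerance = 1e-9)
  expect_equal(tr2$sigma2, summary(fit)$sigma^2, tolerance = 1e-9)
  expect_true(abs(tr2$beta1 - (-0.8)) < 0.25)
  expect_identical(tr2$direction, "decreasing")
  expect_error(fit_trend(c(0, 1), c(1, 2)), class = "depdst_error_series")
  expect_error(marker_series("p", "m", c(0, 0, 1), c(1, 2, 3)),
               class = "depdst_error_series")
})

test_that("trend classification applies the significance threshold and slope sign", {
  mk <- function(p, b1) structure(list(beta0 = 0, beta1 = b1, sigma2 = 1,
                                       p_value = p, direction = "none", n = 10),
                                  class = "trend_result")
  expect_identical(classify_trend(mk(0.04, 2), 0.05), "increasing")
  expect_identical(classify_trend(mk(0.06, 2), 0.05), "none")
  expect_identical(classify_trend(mk(0.04, -2), 0.05), "decreasing")
  expect_error(classify_trend(mk(0.04, 2), 1.5), class = "depdst_error_alpha")
})

test_that("the temporality basis applies the overlap and knowledge-map rules", {
  trends <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3"),
    marker = c("platelets", "glucose", "platelets", "platelets"),
    direction = c("decreasing", "none", "decreasing", "decreasing"),
    mid_date = as.Date(c("2019-03-01", "2019-03-01", "2019-09-01", "2019-03-01")),
    stringsAsFactors = FALSE)
  exposures <- data.frame(
    patient_id = c("p1", "p2", "p3"), drug = "Morphine",
    start_date = as.Date("2019-01-15"), end_date = as.Date("2019-05-15"),
    stringsAsFactors = FALSE)
  map <- data.frame(marker = "platelets", direction = "decreasing",
                    symptom = "bleeding", stringsAsFactors = FALSE)
  basis <- build_temporality_basis(trends, exposures, map)
  # p1: significant decreasing platelets inside the Morphine window -> in basis
  # p2: trend midpoint months after the window (+30-day lag) -> excluded
  # p1 glucose: not significant -> excluded
  expect_equal(nrow(basis), 2)
  expect_setequal(basis$patient_id, c("p1", "p3"))
  expect_true(all(basis$drug == "Morphine" & basis$symptom == "bleeding"))
  expect_equal(dep_temporal(c("p1", "p2"), "Morphine", "bleeding", basis),
               c(1L, 0L))
  # empty basis maps every record to 0
  empty <- build_temporality_basis(trends[trends$direction == "none", , drop = FALSE],
                                   exposures, map)
  expect_equal(dep_temporal(c("p1", "p2"), "Morphine", "bleeding", empty),
               c(0L, 0L))
  bad <- exposures
  bad$end_date <- bad$start_date - 1
  expect_error(build_temporality_basis(trends, bad, map),
               class = "depdst_error_exposure")
})

test_that("basis membership is invariant to construction order", {
  trends <- data.frame(
    patient_id = c("p2", "p1"), marker = "platelets", direction = "decreasing",
    mid_date = as.Date("2019-03-01"), stringsAsFactors = FALSE)
  exposures <- data.frame(patient_id = c("p1", "p2"), drug = "Morphine",
                          start_date = as.Date("2019-02-01"),
                          end_date = as.Date("2019-04-01"),
                          stringsAsFactors = FALSE)
  map <- data.frame(marker = "platelets", direction = "decreasing",
                    symptom = "bleeding", stringsAsFactors = FALSE)
  b1 <- build_temporality_basis(trends, exposures, map)
  b2 <- build_temporality_basis(trends[2:1, ], exposures[2:1, ], map)
  q <- c("p1", "p2", "p9")
  expect_equal(dep_temporal(q, "Morphine", "bleeding", b1),
               dep_temporal(q, "Morphine", "bleeding", b2))
})

test_that("per-series trend table handles short series without error", {
  labs <- data.frame(
    patient_id = c(rep("p1", 12), "p2", "p2"),
    marker = "urea",
    date = c(as.Date("2019-01-01") + 30 * (0:11), as.Date("2019-01-01") + 0:1),
    value = c(30 + 0.08 * 30 * (0:11), 30, 31))
  tt <- fit_marker_trends(labs)
  expect_equal(nrow(tt), 2)
  expect_identical(tt$direction[tt$patient_id == "p1"], "increasing")
  expect_identical(tt$direction[tt$patient_id == "p2"], "none")
  expect_true(is.na(tt$p_value[tt$patient_id == "p2"]))
})
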