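test_that("chi-square correlation component matches the closed form", {
  expect_identical(dep_correlation(matrix(c(10, 10, 10, 10), 2)), 0)
  # closed form: stat = n (ad - bc)^2 / (r1 r2 c1 c2), df = 1
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  stat <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  p_oracle <- pchisq(stat, df = 1, lower.tail = FALSE)
  expect_equal(dep_correlation(tab), 1 - p_oracle, tolerance = 1e-12)
  expect_equal(dep_correlation(tab), 0.990, tolerance = 5e-4)
  expect_equal(dep_correlation(tab, direction = "p"),
               1 - dep_correlation(tab), tolerance = 1e-12)
  expect_error(dep_correlation(matrix(c(1, 2, 0, 0), 2)),
               class = "depdst_error_degenerate_margin")
  expect_error(dep_correlation(matrix(c(1.5, 2, 3, 4), 2)),
               class = "depdst_error_contingency")
})

test_that("chi-square component keeps its nominal type-I behaviour", {
  set.seed(123)
  n_sim <- 2000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    # two independent binary draws, n = 200
    a <- rbinom(1, 100, 0.5); b <- rbinom(1, 100, 0.5)
    tab <- matrix(c(a, 100 - a, b, 100 - b), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (dep_correlation(tab) > 0.95) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.035)
  expect_lte(hits / n_sim, 0.065)
})

test_that("effect size is the reciprocal concurrent-drug count", {
  expect_equal(dep_effect_size(1), 1)
  expect_equal(dep_effect_size(4), 0.25)
  expect_equal(dep_effect_size(c(2, 5)), c(0.5, 0.2))
  expect_error(dep_effect_size(0), class = "depdst_error_no_exposure")
})

test_that("PCA integration finds the dominant direction and normalizes to [0,1]", {
  # only one column varies: loadings collapse onto it
  set.seed(21)
  X <- cbind(a = runif(40), b = 0.5, c = 0.5, d = 0.5)
  ci <- pca_integrate(X)
  expect_equal(unname(ci$loadings), c(1, 0, 0, 0), tolerance = 1e-9)
  expect_equal(ci$normalized, normalize_index(X[, "a"]), tolerance = 1e-12)
  # scaled i.i.d. columns: the inflated column dominates
  Z <- sapply(c(2, 1, 1, 1), function(s) rnorm(300, 0, s))
  colnames(Z) <- letters[1:4]
  ci2 <- pca_integrate(Z)
  expect_true(all(abs(ci2$loadings["a"]) > abs(ci2$loadings[c("b", "c", "d")])))
  # power-iteration oracle for the top eigenvector
  S <- cov(Z)
  v <- rep(1, 4)
  for (i in 1:500) { v <- S %*% v; v <- v / sqrt(sum(v^2)) }
  v <- as.numeric(v) * sign(sum(v))
  expect_equal(unname(abs(ci2$loadings)), abs(v), tolerance = 1e-6)
  expect_equal(min(ci2$normalized), 0)
  expect_equal(max(ci2$normalized), 1)
  expect_error(pca_integrate(X[1, , drop = FALSE]), class = "depdst_error_pca_n")
  expect_error(pca_integrate(matrix(1, 5, 4)),
               class = "depdst_error_degenerate_covariance")
})

test_that("the index direction maximizes explained variance (property)", {
  set.seed(31)
  X <- cbind(rbeta(200, 2, 2), rbinom(200, 1, 0.4), runif(200), rnorm(200, 0.5, 0.2))
  colnames(X) <- c("dep_causal_strength", "dep_temporal", "dep_correlation",
                   "dep_effect_size")
  ci <- pca_integrate(X)
  v_star <- var(as.numeric(X %*% ci$loadings))
  for (i in 1:200) {
    u <- rnorm(4); u <- u / sqrt(sum(u^2))
    expect_gte(v_star + 1e-12, var(as.numeric(X %*% u)))
  }
})

test_that("with non-negative loadings the index is monotone in each component", {
  set.seed(32)
  # positively correlated components so the oriented loadings are positive
  base <- runif(100)
  X <- cbind(a = base + rnorm(100, 0, 0.1), b = base + rnorm(100, 0, 0.1),
             c = base + rnorm(100, 0, 0.1), d = base + rnorm(100, 0, 0.1))
  ci <- pca_integrate(X)
  expect_true(all(ci$loadings >= 0))
  eps <- 1e-4
  for (j in 1:4) {
    X2 <- X
    X2[7, j] <- X2[7, j] + eps
    expect_gte(predict(ci, X2)[7], predict(ci, X)[7])
  }
})

test_that("normalization and the quartile cutoff behave as affine/quantile maps", {
  x <- c(2, 4, 6)
  expect_equal(normalize_index(x), c(0, 0.5, 1))
  expect_error(normalize_index(rep(1, 5)), class = "depdst_error_constant_index")
  expect_equal(low_credibility_cutoff(seq(0, 1, length.out = 101)), 0.25)
  expect_error(low_credibility_cutoff(c(0.1, 0.2, 0.3)),
               class = "depdst_error_cutoff_n")
  # sort-and-interpolate oracle on a seeded Beta sample
  set.seed(33)
  v <- rbeta(1000, 2, 5)
  s <- sort(v)
  h <- (length(v) - 1) * 0.25
  oracle <- s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2] - s[floor(h) + 1])
  expect_equal(low_credibility_cutoff(v), oracle, tolerance = 1e-12)
})

test_that("component assembly composes the four operations per record", {
  expect_equal(nrow(assemble_components(
    data.frame(record_id = character(0), patient_id = character(0),
               disease = character(0), drug = character(0),
               symptom = character(0), n_drugs = integer(0)),
    NULL, list(), structure(data.frame(), class = c("temporality_basis", "data.frame")))),
    0)
  e1 <- matrix(c("DrugA", "Sym1"), 1, 2, dimnames = list(NULL, c("from", "to")))
  st <- arc_strength(c(rep(list(e1), 54), rep(list(e1[0, , drop = FALSE]), 46)),
                     nodes = c("DrugA", "Sym1"))
  conting <- list("Dis1::Sym1" = matrix(c(20, 10, 10, 20), 2))
  basis <- build_temporality_basis(
    data.frame(patient_id = "p1", marker = "platelets",
               direction = "decreasing", mid_date = as.Date("2019-03-01")),
    data.frame(patient_id = "p1", drug = "DrugA",
               start_date = as.Date("2019-02-01"),
               end_date = as.Date("2019-04-01")),
    data.frame(marker = "platelets", direction = "decreasing", symptom = "Sym1"))
  rec <- data.frame(record_id = "r1", patient_id = "p1", disease = "Dis1",
                    drug = "DrugA", symptom = "Sym1", n_drugs = 2)
  comp <- assemble_components(rec, st, conting, basis)
  expect_equal(comp$dep_causal_strength, 0.54)
  expect_equal(comp$dep_correlation, dep_correlation(conting[[1]]))
  expect_equal(comp$dep_effect_size, 0.5)
  expect_equal(comp$dep_temporal, 1L)
  # errors carry the record id
  bad <- rec; bad$disease <- "Dis9"
  expect_error(assemble_components(bad, st, conting, basis), "record r1")
})

test_that("assembled components on generated data are in range with no NaN", {
  sim <- tiny_sim(seed = 501, n_patients = 100)
  cc <- depdst:::compute_all_components(sim, seed = 501, mcmc_iter = 400,
                                        mcmc_burn = 100)
  comp <- cc$components
  expect_gt(nrow(comp), 50)
  expect_false(anyNA(comp))
  expect_true(all(comp$dep_causal_strength >= 0 & comp$dep_causal_strength <= 1))
  expect_true(all(comp$dep_correlation >= 0 & comp$dep_correlation <= 1))
  expect_true(all(comp$dep_effect_size > 0 & comp$dep_effect_size <= 1))
  expect_true(all(comp$dep_temporal %in% c(0L, 1L)))
})

test_that("credibility-index JSON persistence reproduces held-out scoring", {
  set.seed(34)
  X <- matrix(runif(200), 50, 4,
              dimnames = list(NULL, c("dep_causal_strength", "dep_correlation",
                                      "dep_effect_size", "dep_temporal")))
  ci <- pca_integrate(X)
  back <- ci_from_json(ci_to_json(ci))
  Xnew <- matrix(runif(40), 10, 4, dimnames = dimnames(X)[c(1, 2)])
  colnames(Xnew) <- colnames(X)
  expect_equal(predict(back, Xnew), predict(ci, Xnew), tolerance = 1e-12)
})
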