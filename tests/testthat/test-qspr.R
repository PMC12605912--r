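idx_tab <- expected_indices()
prop_tab <- drug_properties()

test_that("noiseless linear data is fitted exactly", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  f <- suppressWarnings(fit_polynomial(x, 2 * x + 1, degree = 1))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(f$r, 1, tolerance = 1e-10)
  expect_lt(f$se, 1e-8)
})

test_that("degree-1 fits reproduce the textbook closed forms on every fixture pair", {
  for (ix in c("FRZI1", "FRZI2", "SRZI", "RHM", "RF")) {
    for (pr in c("MV", "P", "MR", "PSA", "ST")) {
      x <- idx_tab[[ix]]; y <- prop_tab[[pr]]
      f <- fit_polynomial(x, y, 1)
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
      expect_equal(unname(f$coefficients["a1"]), sxy / sxx, tolerance = 1e-12)
      expect_equal(unname(f$coefficients["intercept"]),
                   mean(y) - sxy / sxx * mean(x), tolerance = 1e-12)
      expect_equal(f$r, abs(sxy) / sqrt(sxx * syy), tolerance = 1e-12)
      # F reconstructed from R^2 with (degree, n - degree - 1) df
      n <- length(x)
      expect_equal(f$f, (f$r2 / 1) / ((1 - f$r2) / (n - 2)),
                   tolerance = 1e-10)
    }
  }
})

test_that("R^2 is non-decreasing in polynomial degree on the same data", {
  for (pr in c("MV", "P", "ST")) {
    r2 <- vapply(1:3, function(d)
      fit_polynomial(idx_tab$FRZI2, prop_tab[[pr]], d)$r2, numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("the molar-volume linear model matches the published statistics", {
  f <- fit_polynomial(idx_tab$FRZI2, prop_tab$MV, 1)
  expect_equal(unname(f$coefficients["intercept"]), 61.071, tolerance = 2e-5)
  expect_equal(unname(f$coefficients["a1"]), 0.925, tolerance = 6e-4)
  expect_equal(f$r, 0.896, tolerance = 6e-4)
  expect_equal(f$f, 32.680, tolerance = 2e-5)
  expect_equal(f$se, 35.743, tolerance = 2e-5)
  expect_lt(f$p_overall, 0.001)
})

test_that("MLR fits report coefficients, tests and VIF as published", {
  m <- fit_mlr(idx_tab$FRZI2, idx_tab$RHM, prop_tab$P, c("FRZI2", "RHM"))
  expect_equal(unname(m$coefficients), c(6.2646, 0.2428, -0.0116),
               tolerance = 5e-4)
  expect_equal(m$r, 0.968, tolerance = 6e-4)
  expect_equal(m$se, 3.1067, tolerance = 2e-5)
  expect_equal(m$f, 51.3009, tolerance = 1e-5)
  # published to 4 decimals; agree within one unit in the last place
  expect_true(all(abs(unname(m$coef_p[c("FRZI2", "RHM")]) -
                        c(0.0002, 0.0082)) <= 1e-4))
  # exact-fit degenerate case
  y <- idx_tab$FRZI2
  m2 <- suppressWarnings(fit_mlr(idx_tab$FRZI2, idx_tab$RHM, y))
  expect_equal(m2$r, 1, tolerance = 1e-10)
})

test_that("vif_pair implements 1 / (1 - r12^2)", {
  # orthogonal predictors
  x1 <- c(-1, 1, -1, 1); x2 <- c(-1, -1, 1, 1)
  expect_equal(vif_pair(x1, x2), 1)
  expect_equal(fit_mlr(x1, x2, c(1, 2, 3, 5))$vif,
               c(X1 = 1, X2 = 1))
  # construct a pair with r12^2 = 0.8 exactly
  u <- scale(1:8)[, 1L]
  set.seed(42)
  e <- scale(resid(lm(rnorm(8) ~ u)))[, 1L]
  x2 <- sqrt(0.8) * u + sqrt(0.2) * e
  expect_equal(vif_pair(u, x2), 5, tolerance = 1e-8)
  # the index columns used as MLR predictors fall in the published VIF band
  v <- vif_pair(idx_tab$FRZI1, idx_tab$FRZI2)
  expect_gte(v, 4.8); expect_lte(v, 5.6)
  expect_error(vif_pair(1:5, (1:5) * 2), "collinear")
  expect_error(vif_pair(rep(1, 5), 1:5), "non-constant")
})

test_that("vif_pair agrees with the standard regression diagnostic", {
  skip_if_not_installed("car")
  d <- data.frame(y = prop_tab$P, x1 = idx_tab$FRZI2, x2 = idx_tab$RHM)
  v_car <- unname(car::vif(lm(y ~ x1 + x2, data = d)))
  expect_equal(rep(vif_pair(d$x1, d$x2), 2L), v_car, tolerance = 1e-10)
})

test_that("correlation matrices collect per-pair R and flag column maxima", {
  cm <- correlation_matrix(idx_tab, prop_tab, "linear")
  expect_equal(cm["FRZI2", "MV"], 0.896, tolerance = 6e-4)
  expect_true(attr(cm, "best")["FRZI2", "MV"])
  cm3 <- correlation_matrix(idx_tab, prop_tab, "cubic")
  expect_equal(cm3["FRZI1", "MV"], 0.947, tolerance = 6e-4)
  # a property regressed on itself scores R = 1 in every model
  fake_idx <- data.frame(drug = idx_tab$drug, FRZI1 = prop_tab$MV)
  for (m in c("linear", "quadratic", "cubic")) {
    r <- suppressWarnings(correlation_matrix(fake_idx, prop_tab, m))
    expect_equal(unname(r[1L, "MV"]), 1, tolerance = 1e-9)
  }
  expect_error(
    correlation_matrix(idx_tab[-1L, ], prop_tab, "linear"),
    "alignment error.*Toremifene")
})

test_that("best_fit_report emits the published best models and flags degenerate input", {
  rpt <- best_fit_report(idx_tab, prop_tab)
  mv_lin <- rpt$MV$linear
  expect_equal(mv_lin$index, "FRZI2")
  expect_equal(mv_lin$equation, "MV = 61.071 + 0.925[FRZI2]")
  expect_equal(mv_lin$F, 32.680, tolerance = 2e-5)
  st_quad <- rpt$ST$quadratic
  expect_equal(st_quad$index, "FRZI2")
  expect_equal(st_quad$R, 0.870, tolerance = 6e-4)
  expect_equal(st_quad$F, 10.871, tolerance = 2e-5)
  expect_equal(rpt$MV$mlr$F, 14.838, tolerance = 5e-4)
  expect_equal(rpt$MV$mlr$index, c("FRZI1", "FRZI2"))

  flat <- prop_tab
  flat$ST <- 50  # zero-variance property
  rpt2 <- best_fit_report(idx_tab, flat)
  expect_true(rpt2$ST$degenerate)
  expect_null(rpt2$ST$linear)
})

test_that("reports round-trip to CSV and JSON", {
  rpt <- best_fit_report(idx_tab, prop_tab)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  flat <- write_qspr_report(rpt, csv = csv, json = js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 20L)  # 5 properties x 4 models
  expect_equal(back$R, flat$R, tolerance = 1e-12)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$P$mlr$F, 51.3009, tolerance = 1e-4)
  expect_equal(parsed$P$mlr$VIF$FRZI2, 5.604, tolerance = 1e-3)
})

test_that("degenerate regression inputs raise argument errors", {
  expect_error(fit_polynomial(1:3, 1:3, 2), "at least 4")
  expect_error(fit_polynomial(rep(2, 8), rnorm(8), 1), "constant")
  expect_error(fit_mlr(1:3, 3:1, c(1, 2, 3)), "at least 4")
})
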