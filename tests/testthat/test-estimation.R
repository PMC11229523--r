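test_that("fit_model recovers generating coefficients exactly on noiseless data", {
  x <- seq(7, 15, length.out = 24)
  dat <- data.frame(CPA = x, M = 0.280 + 0.940 * x + 0.071 * x^2)
  m <- fit_model(dat, "M", "CPA", "quadratic")
  expect_equal(unname(m$k), c(0.280, 0.940, 0.071), tolerance = 1e-9)
  expect_equal(m$metrics$r2, 1, tolerance = 1e-12)

  set.seed(4)
  d3 <- data.frame(PA1 = runif(20, 6, 14), PA2 = runif(20, 6, 14),
                   PA3 = runif(20, 8, 19))
  d3$V <- -8.467 + 0.657 * d3$PA1 + 1.294 * d3$PA2 + 0.628 * d3$PA3
  m3 <- fit_model(d3, "V", c("PA1", "PA2", "PA3"), "multi3")
  expect_equal(unname(m3$k), c(-8.467, 0.657, 1.294, 0.628), tolerance = 1e-9)

  d2 <- data.frame(a = runif(15, 15, 26), b = runif(15, 11, 18))
  d2$M <- -31.970 + 1.829 * d2$a + 0.941 * d2$b
  m2 <- fit_model(d2, "M", c("a", "b"), "multi2")
  expect_equal(unname(m2$k), c(-31.970, 1.829, 0.941), tolerance = 1e-9)
})

test_that("exponential and power forms are fit by nonlinear least squares", {
  x <- seq(0.5, 5, length.out = 30)
  dat <- data.frame(x = x, M = 2 * exp(0.5 * x))
  me <- fit_model(dat, "M", "x", "exponential")
  expect_equal(unname(me$k), c(2, 0.5), tolerance = 1e-7)
  expect_equal(me$metrics$rmse, 0, tolerance = 1e-7)
  # a power fit of the same curve cannot reach zero residual
  mp <- fit_model(dat, "M", "x", "power")
  expect_gt(mp$metrics$rmse, 1e-3)

  datp <- data.frame(a = seq(15, 26, length.out = 25))
  datp$M <- 0.012 * datp$a^2.446
  mpw <- fit_model(datp, "M", "a", "power")
  expect_equal(unname(mpw$k), c(0.012, 2.446), tolerance = 1e-6)

  expect_error(fit_model(data.frame(x = 1:5, M = c(-1, 2, 3, 4, 5)),
                         "M", "x", "exponential"), class = "domain_error")
})

test_that("quadratic fits nest the linear fit when the data are linear", {
  set.seed(9)
  dat <- data.frame(CPA = runif(30, 7, 15))
  dat$M <- -8.109 + 2.519 * dat$CPA
  lin <- fit_model(dat, "M", "CPA", "linear")
  quad <- fit_model(dat, "M", "CPA", "quadratic")
  expect_equal(unname(quad$k[3]), 0, tolerance = 1e-9)
  expect_equal(unname(quad$k[1:2]), unname(lin$k), tolerance = 1e-7)
})

test_that("fit_model rejects degenerate designs", {
  dat <- data.frame(a = rep(5, 10), b = 1:10)
  dat$M <- 2 + dat$b
  expect_error(fit_model(dat, "M", c("a", "b"), "multi2"), class = "singular_fit")
  expect_error(fit_model(data.frame(a = 1, M = 2), "M", "a", "linear"),
               class = "singular_fit")
})

test_that("predict evaluates model formulas exactly", {
  m16 <- reference_model("M", "quadratic", "CPA")
  expect_equal(predict(m16, list(CPA = 0)), 0.280)
  m14 <- reference_model("M", "multi2", c("a", "b"))
  expect_equal(predict(m14, list(a = 0, b = 0)), -31.970)
  m18 <- reference_model("M", "quadratic", "Vellip")
  expect_equal(predict(m18, list(Vellip = 10)), 3.159 + 5.15 + 0.3)
  m17 <- reference_model("V", "multi3", c("PA1", "PA2", "PA3"))
  expect_equal(predict(m17, list(PA1 = 10, PA2 = 10, PA3 = 10)),
               -8.467 + 6.57 + 12.94 + 6.28)
  expect_error(predict(m16, list(PA3 = 5)), class = "domain_error")
})

test_that("fit_metrics implements R2, chi-square, RMSE and the accuracy identity", {
  y <- c(12, 15, 20, 24)
  m <- fit_metrics(y, y)
  expect_equal(m$r2, 1); expect_equal(m$rmse, 0)
  expect_equal(m$chi2, 0); expect_equal(m$phi, 100)

  m0 <- fit_metrics(y, rep(mean(y), 4))
  expect_equal(m0$r2, 0)

  # RMSE of exactly 0.73 gives the accuracy 99.27%
  yh <- rep(10, 4); yo <- yh + 0.73 * c(1, -1, 1, -1)
  m73 <- fit_metrics(yo, yh)
  expect_equal(m73$rmse, 0.73)
  expect_equal(m73$phi, 99.27)

  # chi-square is the Pearson-style sum
  yh2 <- c(10, 12, 18, 25)
  expect_equal(fit_metrics(y, yh2)$chi2, sum((y - yh2)^2 / yh2))

  expect_error(fit_metrics(rep(3, 5), rep(3, 5)), class = "domain_error")
  expect_warning(fit_metrics(y, c(-1, 15, 20, 24)), "chi2")
})

test_that("with Gaussian noise the fitted RMSE approaches the noise sd", {
  set.seed(21)
  n <- 10000
  x <- runif(n, 7, 15)
  y <- 0.280 + 0.940 * x + 0.071 * x^2 + rnorm(n, 0, 2)
  m <- fit_model(data.frame(CPA = x, M = y), "M", "CPA", "quadratic")
  expect_equal(m$metrics$rmse, 2, tolerance = 0.05)
})

test_that("rank_models sorts by R2, then chi-square, then RMSE, stably", {
  mk <- function(r2, chi2, rmse, tag) {
    m <- reference_model("M", "linear", "a")
    m$metrics$r2 <- r2; m$metrics$chi2 <- chi2; m$metrics$rmse <- rmse
    m$tag <- tag
    m
  }
  ms <- list(mk(0.978, 2.17, 0.79, "B"), mk(0.981, 1.82, 0.73, "A"),
             mk(0.965, 3.24, 1.01, "C"))
  expect_equal(vapply(rank_models(ms), `[[`, "", "tag"), c("A", "B", "C"))
  # ties keep input order
  tied <- list(mk(0.9, 1, 1, "first"), mk(0.9, 1, 1, "second"))
  expect_equal(vapply(rank_models(tied), `[[`, "", "tag"), c("first", "second"))
  # chi-square breaks R2 ties
  ms2 <- list(mk(0.9, 5, 1, "hi-chi"), mk(0.9, 2, 9, "lo-chi"))
  expect_equal(vapply(rank_models(ms2), `[[`, "", "tag"), c("lo-chi", "hi-chi"))
  # phi strictly decreases in RMSE
  rmses <- c(0.5, 1, 2, 5)
  phis <- vapply(rmses, function(r) {
    yh <- rep(10, 4); fit_metrics(yh + r * c(1, -1, 1, -1), yh)$phi
  }, numeric(1))
  expect_true(all(diff(phis) < 0))
})

test_that("the reference registry is complete and self-consistent", {
  tab <- reference_models()
  expect_equal(nrow(tab), 65)
  expect_equal(sum(tab$response == "M"), 8 + 17 + 12)
  expect_equal(sum(tab$response == "V"), 9 + 17 + 2)
  # no duplicated keys
  expect_false(any(duplicated(tab[, c("response", "form", "predictors")])))

  m <- reference_model("M", "quadratic", "CPA")
  expect_equal(unname(m$k), c(0.280, 0.940, 0.071))
  expect_equal(m$metrics$r2, 0.981)
  expect_equal(m$metrics$chi2, 1.82)
  expect_equal(m$metrics$rmse, 0.73)

  v3 <- reference_model("V", "multi3", c("PA1", "PA2", "PA3"))
  expect_equal(unname(v3$k), c(-8.467, 0.657, 1.294, 0.628))
  expect_equal(v3$metrics$r2, 0.898)

  la <- reference_model("M", "linear", "a")
  expect_equal(unname(la$k), c(-27.485, 2.307))
  expect_equal(la$metrics$r2, 0.929)

  expect_error(reference_model("M", "exponential", "a"), class = "lookup_error")
  expect_error(reference_model("M", "cubic", "a"), class = "lookup_error")
})

test_that("every registry model predicts its hand-evaluated formula", {
  tab <- reference_models()
  grid <- c(0.8, 1.7, 5, 9.3, 14.2)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    preds <- strsplit(row$predictors, "\\+")[[1]]
    m <- reference_model(row$response, row$form, preds)
    newdata <- stats::setNames(as.list(rep(grid, length.out = length(preds) * 5))[
      seq_along(preds)], preds)
    for (g in grid) {
      nd <- lapply(newdata, function(z) g)
      got <- predict(m, nd)
      want <- switch(row$form,
        linear      = row$k1 + row$k2 * g,
        quadratic   = row$k1 + row$k2 * g + row$k3 * g^2,
        exponential = row$k1 * exp(row$k2 * g),
        power       = row$k1 * g^row$k2,
        multi2      = row$k1 + row$k2 * g + row$k3 * g,
        multi3      = row$k1 + row$k2 * g + row$k3 * g + row$k4 * g,
        identity    = g)
      expect_equal(got, want, tolerance = 1e-9,
                   info = paste(row$response, row$form, row$predictors))
    }
  }
})

test_that("correlation matrix reflects the generator's shared-axis structure", {
  # perfectly collinear columns
  base <- generate_population(population_spec(n = 10, seed = 3,
                                              noise_area_side = 0, noise_area_top = 0, noise_volume = 0,
                                              noise_mass = 0))
  lin <- base
  lin$pa1_cm2 <- 2 * lin$pa2_cm2    # force exact collinearity
  cm <- correlation_matrix(lin)
  expect_equal(unname(cm["PA1", "PA2"]), 1)
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 8))

  # independent noise columns decorrelate as ~ 3/sqrt(n)
  set.seed(14)
  n <- 4000
  ind <- data.frame(a = rnorm(n) + 10, b = rnorm(n) + 10, PA1 = rnorm(n) + 10,
                    PA2 = rnorm(n) + 10, PA3 = rnorm(n) + 10, CPA = rnorm(n) + 10,
                    M = rnorm(n) + 10, V = rnorm(n) + 10)
  cmi <- correlation_matrix(ind)
  expect_lt(max(abs(cmi[upper.tri(cmi)])), 3 / sqrt(n) * 2)

  # population emulating the reference summaries: corr(PA1, PA2) is the
  # largest off-diagonal entry (the two side views share both axes)
  pop <- generate_population(population_spec(n = 500, seed = 6))
  cmp <- correlation_matrix(pop)
  off <- cmp; diag(off) <- 0
  expect_equal(max(off), unname(cmp["PA1", "PA2"]))

  cc <- base; cc$a_mm <- 5
  expect_error(correlation_matrix(cc), class = "domain_error")
})

test_that("grading assigns reference-category masses to their classes", {
  expect_equal(grade_fruit(24.88), "Large")   # Large-category mean
  expect_equal(grade_fruit(13.15), "Small")   # Small-category mean
  expect_equal(grade_fruit(15.99), "Medium")  # Medium-category mean
  expect_error(grade_fruit(5), class = "ungradable")
  expect_error(grade_fruit(40), class = "ungradable")

  custom <- size_classes(c("S", "L"), c(0, 10, 20))
  expect_equal(grade_fruit(9.99, custom), "S")
  expect_equal(grade_fruit(20, custom), "L")   # top class closed above
  expect_error(size_classes(c("S", "L"), c(0, 10)), class = "invalid_config")
})

test_that("models round-trip through JSON at full precision", {
  set.seed(31)
  dat <- data.frame(CPA = runif(20, 7, 15))
  dat$M <- 0.3 + 0.9 * dat$CPA + 0.07 * dat$CPA^2 + rnorm(20, 0, 0.5)
  m <- fit_model(dat, "M", "CPA", "quadratic")
  tf <- tempfile(fileext = ".json")
  write_model_json(m, tf)
  back <- read_model_json(tf)
  expect_identical(unname(back$k), unname(m$k))
  expect_identical(back$metrics$r2, m$metrics$r2)
  expect_identical(predict(back, list(CPA = 11.3)), predict(m, list(CPA = 11.3)))
})

test_that("fit_report mirrors the dimension-based table layout", {
  pop <- generate_population(population_spec(n = 40, seed = 12))
  rep_m <- fit_report(pop, "M")
  expect_equal(nrow(rep_m), 9)   # 4 forms x {a, b} + the two-dimension model
  expect_true(all(c("k1", "k2", "k3", "k4", "r2", "chi2", "rmse") %in% names(rep_m)))
  expect_true(all(is.na(rep_m$k4)))
  expect_true(all(rep_m$r2 <= 1))
})
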