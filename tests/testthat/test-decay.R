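test_that("loading-control normalization follows the hand computations", {
  tt <- c(0, 5, 10)
  s1 <- normalize_decay(tt, band = c(4, 4, 4), control = c(4, 4, 4))
  expect_equal(s1$percent_remaining, c(100, 100, 100))
  s2 <- normalize_decay(c(0, 5), band = c(8, 4), control = c(2, 2))
  expect_equal(s2$percent_remaining, c(100, 50))
  # control drift x2 with constant band is corrected to [100, 50]
  s3 <- normalize_decay(c(0, 5), band = c(6, 6), control = c(3, 6))
  expect_equal(s3$percent_remaining, c(100, 50))
})

test_that("normalization validates its inputs", {
  expect_error(normalize_decay(c(0, 5), c(1, 0), c(1, 1)), "positive")
  expect_error(normalize_decay(c(0, 5), c(1, 1), c(1, -2)), "positive")
  expect_error(normalize_decay(c(5, 10), c(1, 1), c(1, 1)), "must be 0")
  expect_error(normalize_decay(c(0, 5, 5), c(1, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(normalize_decay(c(0, 5), c(1, 1, 1), c(1, 1)), "equal length")
})

test_that("exact log-linear decay recovers t1/2 = 10 min to machine precision", {
  tt <- c(0, 5, 10, 15, 30)
  s <- data.table(time = tt, percent_remaining = 100 * 2^(-tt / 10))
  f <- fit_halflife(s, model = "auto")
  expect_equal(f$model, "monophasic")
  expect_equal(f$slope, -log10(2) / 10, tolerance = 1e-12)
  expect_lt(abs(f$t_half - 10), 1e-9)
  expect_false(f$censored)
})

test_that("flat and slowly-decaying series are censored at t_max", {
  s <- data.table(time = c(0, 5, 10, 15, 20, 30), percent_remaining = rep(100, 6))
  f <- fit_halflife(s, model = "auto", t_max = 30)
  expect_true(f$censored)
  expect_true(is.na(f$t_half))
  expect_match(capture.output(print(f)), "> 30 min", all = FALSE)
  # censoring monotonicity: any slope flatter than the t_max bound censors
  for (th_true in c(45, 80, 300, 1e4)) {
    tt <- c(0, 5, 10, 15, 20, 30)
    s2 <- data.table(time = tt, percent_remaining = 100 * 2^(-tt / th_true))
    f2 <- fit_halflife(s2, model = "mono", t_max = 30)
    expect_true(f2$censored)
  }
})

test_that("biphasic series are detected and the initial slope is reported", {
  tt <- c(0, 2, 4, 6, 8, 10, 15, 20, 25, 30)
  pm <- ifelse(tt <= 10, 100 * 2^(-tt / 5),
               100 * 2^(-10 / 5) * 2^(-(tt - 10) / 10))
  f <- fit_halflife(data.table(time = tt, percent_remaining = pm), "auto")
  expect_equal(f$model, "biphasic")
  expect_equal(f$breakpoint, 10)
  expect_lt(abs(f$t_half - 5), 1e-6)
  expect_error(fit_halflife(data.table(time = c(0, 5, 10),
                                       percent_remaining = c(100, 50, 25)),
                            "biphasic"), ">= 6 points")
})

test_that("multiplying all intensities by a constant changes nothing", {
  tt <- seq(0, 30, 5)
  set.seed(1)
  band <- 100 * 2^(-tt / 8) * exp(rnorm(7, 0, 0.05))
  ctrl <- rep(50, 7)
  f1 <- fit_halflife(normalize_decay(tt, band, ctrl))
  f2 <- fit_halflife(normalize_decay(tt, band * 137.5, ctrl * 0.004))
  expect_equal(f1$t_half, f2$t_half)
  expect_equal(f1$slope, f2$slope)
})

test_that("replicates are averaged on the percent scale before fitting", {
  tt <- c(0, 10, 20)
  s1 <- data.table(time = tt, percent_remaining = c(100, 60, 30))
  s2 <- data.table(time = tt, percent_remaining = c(100, 40, 20))
  av <- average_decay(list(s1, s2))
  expect_equal(av$percent_remaining, c(100, 50, 25))
  expect_error(average_decay(list(s1, data.table(time = c(0, 5, 20),
                                                 percent_remaining = c(100, 50, 25)))),
               "share time points")
})

test_that("ladder size estimation matches the log-linear standard curve", {
  lad2 <- ladder_curve(distance = c(1, 2), size_nt = c(1000, 100))
  expect_equal(estimate_size(lad2, 1), 1000, tolerance = 1e-9)
  expect_equal(estimate_size(lad2, 1.5), 10^2.5, tolerance = 1e-9)
  # 6-point realistic ladder vs an independent least-squares oracle
  set.seed(4)
  d <- c(1.0, 1.8, 2.9, 3.7, 4.6, 5.2)
  sz <- c(622, 404, 242, 160, 110, 90)
  lad <- ladder_curve(d, sz)
  ora <- stats::lm.fit(cbind(1, d), log10(sz))$coefficients
  q <- c(1.3, 2.5, 4.9)
  expect_equal(estimate_size(lad, q), 10^(ora[1] + ora[2] * q),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(estimate_size(lad, 9), "interpolation")
})

test_that("absolute quantification inverse-regresses intensities to fmol", {
  std <- quant_standards(fmol = c(2, 4, 8), intensity = c(20, 40, 80))
  expect_equal(quantify_by_standards(std, 40), 4, tolerance = 1e-9)
  expect_equal(quantify_by_standards(std, 50), 5, tolerance = 1e-9)
  # noisy standards against the regression oracle
  set.seed(8)
  fm <- c(1, 2, 5, 10, 20)
  inten <- 12 * fm + rnorm(5, 0, 2)
  std2 <- quant_standards(fm, inten)
  cf <- stats::lm.fit(cbind(1, fm), inten)$coefficients
  expect_equal(quantify_by_standards(std2, 60), (60 - cf[1]) / cf[2],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(quantify_by_standards(std, 500), "outside")
})
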