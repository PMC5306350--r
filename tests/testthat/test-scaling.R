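test_that("power-law fits are exact on noiseless data and unbiased under noise", {
  x <- c(16, 32, 64, 128)
  f <- fit_power_law(x, 0.3 * x^1.5)
  expect_equal(f$exponent, 1.5, tolerance = 1e-12)
  expect_equal(f$stderr, 0, tolerance = 1e-10)
  expect_equal(f$prefactor, 0.3, tolerance = 1e-10)
  expect_equal(fit_power_law(x, 7 / x)$exponent, -1, tolerance = 1e-12)
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_power_law(c(1, 2, 3), c(-1, 2, 3)), "positive")

  set.seed(3)
  hits <- 0L
  for (i in 1:20) {
    x <- exp(seq(log(2), log(200), length.out = 20))
    y <- x^0.75 * exp(rnorm(20, 0, 0.1))
    f <- fit_power_law(x, y)
    if (abs(f$exponent - 0.75) < 3 * f$stderr) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # ~99.7% coverage expected per fit
})

test_that("scaling_fit behaves like a fitted-model object", {
  x <- c(16, 32, 64)
  f <- estimate_2nu(x, 0.18 * x^1.5)
  expect_s3_class(f, "scaling_fit")
  expect_equal(unname(coef(f)["exponent"]), 1.5, tolerance = 1e-10)
  expect_equal(predict(f, 100), 0.18 * 100^1.5, tolerance = 1e-8)
  ci <- confint(f)
  expect_true(ci[1] <= 1.5 && 1.5 <= ci[2])
  expect_output(print(f), "2nu")
})

test_that("concentration exponent reference reproduces the blob prediction", {
  expect_equal(concentration_exponent_reference(3 / 4, 2), -1)
  expect_equal(concentration_exponent_reference(1 / 2, 3), 0)
  expect_equal(concentration_exponent_reference(3 / 5, 3), -0.25)
  phi <- c(0.2, 0.4, 0.6, 0.8, 1)
  f <- estimate_concentration_exponent(phi, 5 / phi)
  expect_equal(f$exponent, -1, tolerance = 1e-12)
})

test_that("structure-factor slope estimation on synthetic curves", {
  q <- exp(seq(log(0.05), log(2), length.out = 40))
  curve <- data.frame(q = q, S = 3 * q^(-4 / 3))
  expect_equal(sq_slope(curve)$exponent, -4 / 3, tolerance = 1e-12)
  f <- sq_slope(curve, window = c(0.1, 1))
  expect_equal(f$exponent, -4 / 3, tolerance = 1e-12)
})

test_that("crossover detection finds a constructed breakpoint and no false ones", {
  q <- exp(seq(log(0.05), log(2), length.out = 48))
  s_break <- ifelse(q < 0.5, q^-2 * 0.5^(2 - 4 / 3), q^(-4 / 3))
  cr <- detect_crossover(data.frame(q = q, S = s_break))
  expect_true(cr$crossover)
  expect_equal(cr$q_star, 0.5, tolerance = 0.15)
  expect_equal(cr$xi, 2 * pi / cr$q_star)
  expect_equal(cr$slope_low, -2, tolerance = 0.05)
  expect_equal(cr$slope_high, -4 / 3, tolerance = 0.05)

  pure <- detect_crossover(data.frame(q = q, S = 2 * q^-1.5))
  expect_false(pure$crossover)
  expect_true(is.na(pure$q_star))
})

test_that("ideal-walk ensembles recover the ideal exponent", {
  Ns <- c(16, 32, 64, 128)
  rg2 <- vapply(seq_along(Ns), function(i)
    mean(sample_ideal_walks(Ns[i], 3000, seed = 100 + i)$rg2), numeric(1))
  f <- estimate_2nu(Ns, rg2)
  expect_lt(abs(f$exponent - 1), 2 * max(f$stderr, 0.02))
})
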