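test_that("fit_linear reproduces an exact line", {
  x <- c(1, 2, 4, 6, 8)
  s <- series_from(x, 5 * x - 2)
  f <- fit_linear(s, "charge")
  expect_equal(f$slope1, 5, tolerance = 1e-10)
  expect_equal(f$intercept1, -2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  # two points: r2 = 1 by construction, flagged low-n
  f2 <- fit_linear(series_from(c(2, 3), c(0.5, 1)), "charge")
  expect_equal(f2$r_squared, 1)
  expect_true("low_n" %in% f2$flags)
  expect_error(fit_linear(series_from(2, 0.5), "charge"), "2 suprathreshold")
})

test_that("noisy linear growth slopes recover within 15% in >= 90%", {
  x <- seq(2, 9, length.out = 8)
  set.seed(11)
  ok <- 0
  for (r in 1:100) {
    y <- pmax(0.12, 2 * (x - 1.5) + rnorm(8, sd = 0.05))
    f <- fit_linear(series_from(x, y), "charge")
    if (abs(f$slope1 / 2 - 1) < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 90)
})

test_that("broken-stick refits its own noiseless model within 1e-4", {
  x <- seq(3, 18, length.out = 10)
  cases <- list(c(a1 = -2, s1 = 5, s2 = -0.5, k = 10),
                c(a1 = 1, s1 = 0.8, s2 = -0.1, k = 7),
                c(a1 = -5, s1 = 12, s2 = -1.5, k = 14))
  for (p in cases) {
    y <- ifelse(x <= p["k"], p["a1"] + p["s1"] * x,
                p["a1"] + p["s1"] * p["k"] + p["s2"] * (x - p["k"]))
    f <- fit_broken_stick(series_from(x, y), "charge")
    got <- c(f$intercept1, f$slope1, f$slope2, f$knee)
    expect_lt(max(abs(got / p - 1)), 1e-4)
    expect_lte(f$slope2, 0)           # saturation bound
  }
  expect_error(fit_broken_stick(series_from(c(3, 5, 7), c(1, 2, 3))),
               "4 suprathreshold")
})

test_that("slope2 never exceeds zero, even on rising data", {
  set.seed(5)
  x <- seq(3, 18, length.out = 9)
  for (r in 1:20) {
    y <- pmax(0.12, 1.5 * x - 2 + rnorm(9, sd = 0.3))
    f <- fit_broken_stick(series_from(x, y), "charge")
    expect_lte(f$slope2, 0)
  }
})

test_that("current-basis fits rescale the bounds by the charge factor", {
  x <- seq(3, 18, length.out = 10)                 # charge, nC
  y <- ifelse(x <= 10, -2 + 5 * x, 48 - 0.5 * (x - 10))
  s <- series_from(x, y)                           # current = 40x uA
  f <- fit_broken_stick(s, "current")
  fac <- 25 / 1000                                 # nC per uA (REC, 25 us)
  expect_equal(f$knee, 10 / fac, tolerance = 1e-3)
  expect_equal(f$slope1, 5 * fac, tolerance = 1e-3)
})

test_that("select_model applies the F-test rule and honors overrides", {
  x <- seq(2, 16, length.out = 10)
  set.seed(21)
  # saturating data -> broken-stick
  ysat <- pmax(0.12, ifelse(x <= 9, 3 * (x - 1), 24) + rnorm(10, sd = 0.05))
  s_sat <- series_from(x, ysat)
  sel <- select_model(fit_linear(s_sat), fit_broken_stick(s_sat), s_sat)
  expect_equal(sel$model, "broken_stick")
  # linear data -> linear
  ylin <- pmax(0.12, 2 * x - 1 + rnorm(10, sd = 0.05))
  s_lin <- series_from(x, ylin)
  sel2 <- select_model(fit_linear(s_lin), fit_broken_stick(s_lin), s_lin)
  expect_equal(sel2$model, "linear")
  # manual override wins
  sel3 <- select_model(fit_linear(s_lin), fit_broken_stick(s_lin), s_lin,
                       override = "broken_stick")
  expect_equal(sel3$model, "broken_stick")
})

test_that("select_model keeps the type-I rate at or below 10%", {
  x <- seq(2, 16, length.out = 10)
  set.seed(42)
  n_bs <- 0
  for (r in 1:200) {
    y <- pmax(0.12, 2 * x - 1 + rnorm(10, sd = 0.05))
    s <- series_from(x, y)
    sel <- select_model(fit_linear(s), fit_broken_stick(s), s)
    if (sel$model == "broken_stick") n_bs <- n_bs + 1
  }
  expect_lte(n_bs / 200, 0.10)
})

test_that("strength-duration slopes follow the charge/current identities", {
  d <- c(25, 50, 75)
  # constant charge thresholds: 0 dB re 1 nC / doubling
  f_q <- strength_duration_fit(d, c(3, 3, 3), basis = "dB re 1 nC")
  expect_equal(f_q$slope, 0, tolerance = 1e-12)
  # constant current thresholds: charge slope +6.0206, current slope 0
  cur <- c(120, 120, 120)
  q <- d * cur / 1000
  expect_equal(strength_duration_fit(d, q)$slope, 20 * log10(2),
               tolerance = 1e-9)
  expect_equal(strength_duration_fit(d, cur)$slope, 0, tolerance = 1e-12)
  # identity holds for ANY shared threshold set, to 1e-9
  set.seed(3)
  for (r in 1:20) {
    cur <- exp(rnorm(3, log(100), 0.5))
    q <- d * cur / 1000               # same identity with the ramp /2
    diff <- strength_duration_fit(d, q)$slope -
      strength_duration_fit(d, cur)$slope
    expect_lt(abs(diff - 20 * log10(2)), 1e-9)
  }
  # NA thresholds dropped; < 2 remaining errors
  f <- strength_duration_fit(c(25, 50, 75), c(2, NA, 4))
  expect_equal(f$n, 2)
  expect_error(strength_duration_fit(c(25, 50, 75), c(2, NA, NA)), ">= 2")
})
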