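test_that("model 1 is a constant baseline", {
  expect_equal(r2eff_model1(25, 15.23), 15.23)
  expect_equal(r2eff_model1(2000, 15.23), 15.23)
  expect_equal(r2eff_model1(c(10, 100, 1000), 1.0), rep(1.0, 3))
})

test_that("fast-limit model matches its closed form and limits", {
  # hand-evaluated: tanh(kex/4nu) ~ 1 at nu = 25, bracket = 1 - 100/kex
  expect_rel_equal(r2eff_model2(25, 15.23, 3750.3, 47457.4),
                   27.54687347, 1e-8)
  # large-nu plateau at r20
  expect_equal(r2eff_model2(1e6, 15.23, 3750.3, 47457.4), 15.23,
               tolerance = 1e-3)
  # zero exchange amplitude
  expect_equal(r2eff_model2(100, 12.5, 2000, 0), 12.5)
  # nu -> 0+ approaches r20 + phi/kex
  expect_equal(r2eff_model2(1e-4, 15.23, 3750.3, 47457.4),
               15.23 + 47457.4 / 3750.3, tolerance = 1e-6)
  expect_error(r2eff_model2(-5, 15, 1000, 1e4), "nu_cpmg")
})

test_that("Carver-Richards model collapses analytically without exchange", {
  nu <- c(25, 100, 500, 2000)
  expect_equal(r2eff_model3(nu, 15.23, 306.2, 0.072, 0), rep(15.23, 4))
  # vanishing minor population
  expect_equal(r2eff_model3(100, 15.23, 306.2, 1e-12, 1875.5), 15.23,
               tolerance = 1e-6)
  # plateau at r20 for large nu
  expect_equal(r2eff_model3(1e6, 15.23, 306.2, 0.072, 1875.5), 15.23,
               tolerance = 1e-3)
  expect_error(r2eff_model3(0, 15, 300, 0.1, 1000), "nu_cpmg")
})

test_that("Carver-Richards agrees with the independent oracle", {
  # frozen oracle value for the slow-exchange generators at nu = 50
  expect_rel_equal(r2eff_model3(50, 15.23, 306.2, 0.072, 1875.5),
                   36.5178701008878, 1e-10)
  set.seed(101)
  for (i in 1:100) {
    r20 <- runif(1, 5, 40)
    kex <- 10^runif(1, 1.5, 4)
    pb <- runif(1, 0.005, 0.45)
    dw <- 10^runif(1, 2, 4)
    nu <- 10^runif(5, 1, 3.5)
    expect_rel_equal(r2eff_model3(nu, r20, kex, pb, dw),
                     oracle_carver_richards(nu, r20, kex, pb, dw),
                     1e-10)
  }
})

test_that("dispersion curves decay with nu_cpmg", {
  # the fast-limit curve is strictly non-increasing; the Carver-Richards
  # expression additionally carries small low-nu ripples in slow exchange
  # (kex < dw), so model 3 is tested as non-increasing up to ripples that
  # are small against the dispersion amplitude
  nu <- sort(10^seq(1, 4, length.out = 60))
  set.seed(77)
  for (i in 1:25) {
    r20 <- runif(1, 5, 40)
    kex <- 10^runif(1, 2, 4)
    pb <- runif(1, 0.01, 0.4)
    dw <- 10^runif(1, 2, 3.8)
    phi <- (1 - pb) * pb * dw^2
    c2 <- r2eff_model2(nu, r20, kex, phi)
    c3 <- r2eff_model3(nu, r20, kex, pb, dw)
    expect_true(all(diff(c2) <= 1e-8))
    amplitude <- max(c3) - min(c3)
    expect_true(all(diff(c3) <= 0.05 * amplitude + 1e-8))
    # and the overall trend is downward: plateau below the low-nu end
    expect_lt(c3[length(c3)], c3[1])
  }
})

test_that("exchange contribution Rex follows the limit formulas", {
  expect_rel_equal(rex_contribution(2, list(kex = 3750.3, phi = 47457.4)),
                   12.65429432, 1e-8)
  expect_rel_equal(rex_contribution(3, list(kex = 306.2, pb = 0.072,
                                            dw = 1875.5)),
                   19.92788444, 1e-8)
  expect_equal(rex_contribution(2, list(kex = 1000, phi = 0)), 0)
  expect_equal(rex_contribution(1, list(r20 = 10)), 0)
})

test_that("delta-omega scales linearly with the static field", {
  f600 <- field_context(600, ref_frequency_mhz = 800)
  expect_equal(scale_dw(1875.5, f600), 1406.625)
  expect_equal(scale_dw(1875.5, field_context(800, 800)), 1875.5)
  expect_equal(scale_dw(0, f600), 0)
})
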