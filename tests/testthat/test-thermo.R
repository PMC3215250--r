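test_that("free energy between states follows -RT ln(pb/pa)", {
  expect_rel_equal(delta_g(0.072, 298), 6333.932287, 1e-8)
  expect_equal(delta_g(0.5, 310), 0)
  expect_equal(delta_g(0.928, 298), -delta_g(0.072, 298))
  expect_error(delta_g(1, 298), "strictly")
  # round trip with the logistic inverse
  for (pb in c(0.008, 0.072, 0.3, 0.9)) {
    expect_equal(pb_from_delta_g(delta_g(pb, 298), 298), pb,
                 tolerance = 1e-12)
  }
})

test_that("populations from known shift differences invert phi", {
  phi <- 0.928 * 0.072 * 1875.5^2
  expect_equal(pb_from_dw(phi, 1875.5), 0.072, tolerance = 1e-10)
  expect_equal(pb_from_dw(0.25 * 1000^2, 1000), 0.5)
  expect_error(pb_from_dw(0.3 * 1000^2, 1000), "no physical")
})

test_that("kex splits into forward and backward rates by detailed balance", {
  k <- rates_from_kex(1000, 0.1)
  expect_equal(k$k_ab, 100)
  expect_equal(k$k_ba, 900)
  k2 <- rates_from_kex(306.2, 0.072)
  expect_rel_equal(k2$k_ab, 22.0464, 1e-4)
  expect_rel_equal(k2$k_ba, 284.1536, 1e-4)
  expect_equal(k2$k_ab + k2$k_ba, 306.2)
  expect_equal(k2$k_ab / k2$k_ba, 0.072 / 0.928)
  ks <- rates_from_kex(500, 0.5)
  expect_equal(ks$k_ab, ks$k_ba)
})

test_that("Eyring barriers behave like transition state theory", {
  expect_rel_equal(eyring_dg_activation(1000, 298), 55870.66264, 1e-6)
  kbt_h <- 1.380649e-23 * 298 / 6.62607015e-34
  expect_equal(eyring_dg_activation(kbt_h, 298), 0, tolerance = 1e-6)
  expect_gt(eyring_dg_activation(10, 298), eyring_dg_activation(1000, 298))
})

test_that("energy landscape is internally consistent", {
  el <- energy_landscape(306.2, 0.072, 298)
  expect_equal(el$dG_act_fwd - el$dG_act_bwd, el$dG, tolerance = 1e-8)
  expect_gt(el$dG, 0)  # minor state uphill
})

test_that("linear van't Hoff recovers generating dH and dS exactly", {
  dH <- 50e3; dS <- 100
  temps <- seq(278, 318, 10)
  K <- exp(-dH / (8.314462618 * temps) + dS / 8.314462618)
  vh <- vant_hoff(temps, K = K, mode = "linear", eval_t = 298)
  expect_rel_equal(vh$dH, dH, 1e-6)
  expect_rel_equal(vh$dS, dS, 1e-6)
  # dG = dH - T dS identity at the evaluation temperature
  expect_equal(vh$dG, dH - 298 * dS, tolerance = 1e-6)
  expect_error(vant_hoff(c(298, 298), K = c(1, 1)), "distinct")
})

test_that("nonlinear van't Hoff recovers a heat-capacity change", {
  dH0 <- 50e3; dS0 <- 100; dCp <- -2e3; t0 <- 298
  temps <- seq(278, 328, 10)
  R <- 8.314462618
  dH_t <- dH0 + dCp * (temps - t0)
  dS_t <- dS0 + dCp * log(temps / t0)
  K <- exp(-dH_t / (R * temps) + dS_t / R)
  vh <- vant_hoff(temps, K = K, mode = "nonlinear", t0 = t0)
  expect_rel_equal(vh$dCp, dCp, 0.01)
  expect_rel_equal(vh$dH, dH0, 0.01)
  expect_error(vant_hoff(c(280, 300), K = c(2, 1), mode = "nonlinear"),
               "at least 4")
  # with dCp = 0 the nonlinear fit collapses onto the linear one
  K0 <- exp(-dH0 / (R * temps) + dS0 / R)
  lin <- vant_hoff(temps, K = K0, mode = "linear")
  nl <- vant_hoff(temps, K = K0, mode = "nonlinear", t0 = t0)
  expect_rel_equal(nl$dH, lin$dH, 1e-4)
  expect_rel_equal(nl$dS, lin$dS, 1e-4)
  expect_lt(abs(nl$dCp), 1)
})

test_that("van't Hoff accepts populations directly", {
  temps <- seq(280, 320, 10)
  R <- 8.314462618
  K <- exp(-40e3 / (R * temps) + 80 / R)
  pb <- K / (1 + K)
  vh <- vant_hoff(temps, pb = pb, mode = "linear")
  expect_rel_equal(vh$dH, 40e3, 1e-6)
  expect_output(print(vh), "Van't Hoff")
})
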