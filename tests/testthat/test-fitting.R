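make_profile <- function(nu, r2eff, sigma, field = field_context(800)) {
  dispersion_profile(
    residue = 1,
    data = data.frame(field_mhz = field$frequency_mhz, nu_cpmg = nu,
                      r2eff = r2eff),
    sigma = stats::setNames(sigma, as.character(field$frequency_mhz)),
    fields = stats::setNames(list(field),
                             as.character(field$frequency_mhz)))
}

test_that("chi-square target matches its definition", {
  nu <- default_nu_grid
  truth <- r2eff_model2(nu, 15.23, 3750.3, 47457.4)
  prof <- make_profile(nu, truth, 0.3)
  expect_lt(chi2_profile(prof, 2, pars_fast), 1e-20)
  # one point, residual exactly one sigma
  p1 <- make_profile(c(100, 200, 300, 400, 500, 600),
                     r2eff_model1(1:6, 10) + c(0.5, 0, 0, 0, 0, 0), 0.5)
  expect_equal(chi2_profile(p1, 1, list(r20 = 10)), 1)
  # residuals of 1, 2, 2 sigma sum to 9
  p3 <- make_profile(c(100, 200, 300, 400, 500, 600),
                     rep(10, 6) + c(1, 2, 2, 0, 0, 0), 1)
  expect_equal(chi2_profile(p3, 1, list(r20 = 10)), 9)
})

test_that("noiseless fits recover the generating parameters", {
  p2 <- simulate_profile(2, pars_fast)
  f2 <- cpmg_fit(p2, 2)
  expect_lt(f2$chi2, 1e-8)
  expect_rel_equal(f2$pars$r20[[1]], 15.23, 1e-3)
  expect_rel_equal(f2$pars$kex, 3750.3, 1e-3)
  expect_rel_equal(f2$pars$phi, 47457.4, 1e-3)

  p3 <- simulate_profile(3, pars_slow)
  f3 <- cpmg_fit(p3, 3)
  expect_lt(f3$chi2, 1e-6)
  expect_rel_equal(f3$pars$r20[[1]], 15.23, 1e-3)
  expect_rel_equal(f3$pars$kex, 306.2, 1e-3)
  expect_rel_equal(f3$pars$pb, 0.072, 1e-3)
  expect_rel_equal(f3$pars$dw, 1875.5, 1e-3)

  # flat data and model 1
  pf <- make_profile(default_nu_grid, rep(10, 14), 0.1)
  f1 <- cpmg_fit(pf, 1)
  expect_equal(f1$pars$r20[[1]], 10, tolerance = 1e-8)
  expect_lt(f1$chi2, 1e-12)
})

test_that("parameter recovery holds over random draws within bounds", {
  set.seed(2024)
  for (i in 1:12) {
    r20 <- runif(1, 8, 30)
    kex <- 10^runif(1, 2.3, 3.8)
    pb <- runif(1, 0.02, 0.25)
    dw <- 10^runif(1, 2.8, 3.5)
    p3 <- simulate_profile(3, list(r20 = r20, kex = kex, pb = pb,
                                   dw = dw))
    f3 <- cpmg_fit(p3, 3)
    expect_lt(f3$chi2, 1e-6)
    expect_rel_equal(unname(coef(f3)), c(r20, kex, pb, dw), 1e-3)

    phi <- pb * (1 - pb) * dw^2
    p2 <- simulate_profile(2, list(r20 = r20, kex = kex, phi = phi))
    f2 <- cpmg_fit(p2, 2)
    expect_lt(f2$chi2, 1e-6)
    expect_rel_equal(unname(coef(f2)), c(r20, kex, phi), 1e-3)
  }
})

test_that("chi-square never worsens with model complexity", {
  set.seed(5)
  for (pars in list(pars_fast)) {
    prof <- simulate_profile(2, pars, noise_percent = 5)
    c1 <- cpmg_fit(prof, 1)$chi2
    c2 <- cpmg_fit(prof, 2)$chi2
    c3 <- cpmg_fit(prof, 3)$chi2
    expect_lte(c2, c1 + 1e-6)
    expect_lte(c3, c2 + 1e-6)
  }
})

test_that("global two-field fits share exchange parameters", {
  fields <- list(field_context(800, 800), field_context(600, 800))
  pg3 <- simulate_multifield(3, pars_slow, fields)
  fg3 <- cpmg_fit(pg3, 3)
  expect_rel_equal(fg3$pars$kex, 306.2, 1e-3)
  expect_rel_equal(fg3$pars$pb, 0.072, 1e-3)
  expect_rel_equal(fg3$pars$dw, 1875.5, 1e-3)
  expect_rel_equal(unname(fg3$pars$r20), c(15.23, 15.23), 1e-3)
  expect_equal(fg3$k, 5)

  pg2 <- simulate_multifield(2, pars_fast, fields)
  fg2 <- cpmg_fit(pg2, 2)
  expect_rel_equal(fg2$pars$kex, 3750.3, 1e-3)
  expect_rel_equal(unname(fg2$pars$r20), c(15.23, 15.23), 1e-3)

  # the 600 MHz data really carries the scaled dw: a single-field fit at
  # 600 MHz with ref 600 recovers 1406.625
  d600 <- pg3$data[pg3$data$field_mhz == 600, ]
  p600 <- make_profile(d600$nu_cpmg, d600$r2eff, pg3$sigma[["600"]],
                       field_context(600))
  f600 <- cpmg_fit(p600, 3)
  expect_rel_equal(f600$pars$dw, 1406.625, 1e-3)
})

test_that("global fit degenerates to the single-field fit", {
  prof <- simulate_multifield(3, pars_slow, list(field_context(800, 800)))
  f_single <- cpmg_fit(simulate_profile(3, pars_slow), 3)
  f_global <- cpmg_fit(prof, 3)
  expect_equal(coef(f_global), coef(f_single), tolerance = 1e-6)
})

test_that("cluster fit shares kex and pb and recovers per-residue values", {
  r20 <- c(12, 15, 18, 21)
  dw <- c(1200, 1875.5, 2500, 3100)
  cl <- simulate_cluster(3, list(kex = 306.15, pb = 0.072), r20, dw)
  fc <- cpmg_fit_cluster(cl, 3)
  expect_rel_equal(fc$shared$kex, 306.15, 1e-3)
  expect_rel_equal(fc$shared$pb, 0.072, 1e-3)
  for (i in 1:4) {
    expect_rel_equal(fc$fits[[i]]$pars$r20[[1]], r20[i], 1e-3)
    expect_rel_equal(fc$fits[[i]]$pars$dw, dw[i], 1e-3)
    expect_equal(fc$fits[[i]]$pars$kex, fc$shared$kex)
    expect_equal(fc$fits[[i]]$pars$pb, fc$shared$pb)
  }
  # joint chi2 equals the sum of the per-residue partial chi2
  parts <- vapply(fc$fits, `[[`, 0, "chi2_partial")
  expect_equal(unname(sum(parts)), fc$chi2, tolerance = 1e-6)

  # degenerate cluster of one behaves like a single-residue fit
  fc1 <- cpmg_fit_cluster(cl[1], 3)
  f1 <- cpmg_fit(cl[[1]], 3)
  expect_equal(coef(fc1$fits[[1]]), coef(f1), tolerance = 1e-6)
})

test_that("fit model methods are coherent", {
  prof <- simulate_profile(2, pars_fast, noise_percent = 2, seed = 9)
  f <- cpmg_fit(prof, 2)
  expect_s3_class(f, "cpmg_fit")
  expect_length(predict(f), 14)
  expect_equal(unname(predict(f, 1e6)), f$pars$r20[[1]],
               tolerance = 1e-3)
  r <- residuals(f, "pearson")
  expect_equal(sum(r^2), f$chi2, tolerance = 1e-10)
  sims <- simulate(f, nsim = 3, seed = 4)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "dispersion_profile")
  expect_output(print(f), "fast-limit")
  expect_output(print(summary(f)), "Coefficients")
})
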