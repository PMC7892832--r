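test_that("field strength and R2,eff conversions follow their definitions", {
  expect_equal(nu_from_tau(0.015), 33.333, tolerance = 1e-4)
  expect_equal(nu_from_tau(0.00125), 400)
  expect_lt(nu_from_tau(1e9), 1e-8)
  expect_error(nu_from_tau(0), "positive")

  expect_equal(compute_r2eff(1000, 1000, 0.030), 0)
  expect_equal(compute_r2eff(548.81, 1000, 0.030), 20, tolerance = 1e-4)
  # intensity above reference gives the (anomalous) negative rate
  expect_equal(compute_r2eff(1000, 548.81, 0.030), -20, tolerance = 1e-4)
  expect_error(compute_r2eff(-1, 100, 0.030), "positive")
})

test_that("exact model reduces to the intrinsic rate without exchange", {
  nus <- nu_grid12
  p_nodw <- two_site_params(k_ex = 500, p_b = 0.1, delta_omega = 0,
                            r2_0 = 9)
  expect_equal(simulate_r2eff_exact(p_nodw, nus), rep(9, 12))
  p_nopb <- two_site_params(k_ex = 500, p_b = 0, delta_omega = 800,
                            r2_0 = 9)
  expect_equal(simulate_r2eff_exact(p_nopb, nus), rep(9, 12))
  # high-field plateau approaches r2_0
  p <- two_site_params(k_ex = 1500, p_b = 0.04, delta_omega = 900,
                       r2_0 = 11)
  expect_equal(simulate_r2eff_exact(p, 50000), 11, tolerance = 1e-3)
})

test_that("exact model is monotone non-increasing in the field strength", {
  # from intermediate to fast exchange (k_ex >= delta_omega); slow-exchange
  # profiles genuinely oscillate at low field strengths where the few
  # refocusing pulses recouple the shift difference
  set.seed(11)
  for (i in 1:12) {
    dw <- exp(runif(1, log(100), log(4000)))
    p <- two_site_params(
      k_ex = dw * exp(runif(1, 0, log(20))),
      p_b = runif(1, 0.005, 0.3),
      delta_omega = dw,
      r2_0 = runif(1, 5, 20)
    )
    y <- simulate_r2eff_exact(p, nu_grid12)
    expect_true(all(diff(y) <= 1e-8))
  }
})

test_that("exact propagation matches the Luz-Meiboom fast-exchange oracle", {
  # closed-form evaluation at the example point
  p <- two_site_params(k_ex = 1e4, p_b = 0.05, delta_omega = 1e3, r2_0 = 0)
  expect_equal(luz_meiboom_r2eff(p, 250), 4.75 * (1 - 0.1 * tanh(10)),
               tolerance = 1e-12)
  # zero-frequency limit p_a p_b dw^2 / k_ex
  expect_equal(luz_meiboom_r2eff(p, 1e-4), 0.95 * 0.05 * 1e6 / 1e4,
               tolerance = 1e-3)
  # agreement within 5% relative exchange contribution for k_ex >= 10 dw
  set.seed(21)
  for (i in 1:10) {
    dw <- exp(runif(1, log(200), log(1500)))
    p <- two_site_params(k_ex = dw * runif(1, 10, 40),
                         p_b = runif(1, 0.02, 0.2),
                         delta_omega = dw, r2_0 = 10)
    ex <- simulate_r2eff_exact(p, nu_grid12) - 10
    lm_ <- luz_meiboom_r2eff(p, nu_grid12) - 10
    expect_lt(max(abs(ex - lm_) / lm_), 0.05)
  }
})

test_that("profile building averages repeat planes and floors sigma", {
  t_relax <- 0.030
  rec <- tibble::tibble(
    isoform = "0401", residue = 1L, aa = "A", field_MHz = 600,
    nu_cpmg_hz = c(0, 100, 100, 200),
    intensity = c(1000, 1000 * exp(-15 * t_relax) * c(0.99, 1.01),
                  1000 * exp(-12 * t_relax))
  )
  prof <- dispersion_profiles(rec, t_relax)
  expect_equal(nrow(prof), 2)
  p100 <- prof[prof$nu_cpmg_hz == 100, ]
  expect_equal(p100$n_planes, 2)
  expect_equal(p100$r2eff, 15, tolerance = 0.01)
  # repeat spread propagates into sigma, floored at max(1% R2eff, 0.05)
  expect_gte(p100$sigma, 0.01 * p100$r2eff)
  p200 <- prof[prof$nu_cpmg_hz == 200, ]
  expect_equal(p200$sigma, max(0.01 * p200$r2eff, 0.05))
  # non-positive intensities are QC-excluded, not fatal
  rec_bad <- rec
  rec_bad$intensity[4] <- -5
  expect_equal(nrow(dispersion_profiles(rec_bad, t_relax)), 1)
})

test_that("flat profiles select the null model and report zero amplitude", {
  set.seed(31)
  prof <- tibble::tibble(
    nu_cpmg_hz = nu_grid12,
    r2eff = 15 + rnorm(12, 0, 0.2),
    sigma = 0.2
  )
  f <- fit_dispersion(prof)
  expect_equal(f$preferred, "flat")
  expect_equal(f$delta_r2eff, 0)
  expect_equal(f$flat_model_r2, 15, tolerance = 0.1)
})

test_that("profiles with too few field strengths are reported unfittable", {
  prof <- make_profile(two_site_params(800, 0.03, 760, 12),
                       nus = nu_grid12[1:4])
  f <- fit_dispersion(prof)
  expect_equal(f$status, "unfittable")
  sm <- tibble::tibble(isoform = "x", residue = 1, delta_r2eff = NA_real_,
                       preferred = NA_character_, status = "unfittable")
  expect_equal(flexibility_summary(sm)$n_evaluated, rep(0, 4))
})

test_that("flexibility summary counts threshold exceedances per isoform", {
  fits <- tibble::tibble(
    isoform = "0401", residue = 1:4, status = "ok", preferred = "exchange",
    delta_r2eff = c(0.5, 2, 4, 12)
  )
  s <- flexibility_summary(fits, c(1, 3, 5, 10))
  expect_equal(s$percent_exceeding, c(75, 50, 25, 25))
  # percentages are non-increasing across ascending thresholds
  expect_true(all(diff(s$percent_exceeding) <= 0))
  fits$delta_r2eff <- 0
  expect_equal(flexibility_summary(fits)$percent_exceeding, rep(0, 4))
  # flat-preferred residues count as zero amplitude
  fits2 <- tibble::tibble(isoform = "a", residue = 1:2, status = "ok",
                          preferred = c("flat", "exchange"),
                          delta_r2eff = c(50, 5))
  expect_equal(flexibility_summary(fits2, 1)$percent_exceeding, 50)
  expect_error(flexibility_summary(fits[0, ]), "empty")
})

test_that("ppm/rad conversions invert and scale with the field", {
  x <- ppm_to_rad_s(3, 600, "15N")
  expect_equal(rad_s_to_ppm(x, 600, "15N"), 3)
  expect_equal(ppm_to_rad_s(3, 1200, "15N"), 2 * x)
})

test_that("tidy and glance expose dispersion fit results", {
  f <- fit_dispersion(make_profile(two_site_params(800, 0.03, 760, 12)))
  td <- tidy(f)
  expect_equal(td$term, c("k_ex", "p_b", "delta_omega", "r2_0"))
  gl <- glance(f)
  expect_equal(gl$preferred, "exchange")
  expect_s3_class(autoplot(f), "ggplot")
})
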