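test_that("half-life and affinity conversions match hand values", {
  expect_equal(half_life(log(2)), 60)
  expect_equal(half_life(0.924), 45.0, tolerance = 0.001)   # ~45 s
  expect_equal(half_life(0.495), 84.0, tolerance = 0.001)   # ~84 s
  expect_error(half_life(0), "positive")
  expect_equal(pka_to_ka(6.92) * 1e9, 120.2, tolerance = 1e-3)
  expect_equal(ka_to_pka(pka_to_ka(6.92)), 6.92, tolerance = 1e-9)
  expect_equal(pka_to_ka(5.97) * 1e9, 1071.5, tolerance = 1e-4)
})

test_that("single-concentration k_tau is Plateau x kobs with propagated se", {
  t <- default_grid()
  # noiseless trace built from the target parameters: 0.416 x 0.96
  y <- assoc_oracle(t, 0, 0.416, 0.96, 0.75)
  est <- ktau_single_conc(fit_association(time_course(t, y, "upward",
                                                      conc = 3.2e-5)))
  expect_equal(est$k_tau, 0.39936, tolerance = 1e-4)
  expect_equal(est$method, "single_conc")
  # zero plateau gives zero k_tau
  est0 <- ktau_single_conc(
    fit_association(time_course(t, rep(0, length(t)), "upward")))
  expect_lt(abs(est0$k_tau), 1e-6)
  # saturation warning from the K_A hint
  tc <- model_tc(1e-7)
  expect_warning(ktau_single_conc(fit_association(tc), k_a_hint = 1.2e-7),
                 "100 x K_A")
  # decay fits are rejected with advice to invert
  fd <- fit_decay(time_course(t, decay_oracle(t, 1, 0.6, 0.9, 0.75),
                              "downward"))
  expect_error(ktau_single_conc(fd), "invert")
})

test_that("dose-response k_tau reads the sigmoid top and L50 = K_A", {
  fits <- lapply(conc_series(), function(cc) fit_association(model_tc(cc)))
  est <- ktau_dose_response(fits)
  expect_equal(est$k_tau, 0.41, tolerance = 0.01)
  expect_equal(est$k_a, 1.2e-7, tolerance = 0.05)
  expect_equal(est$p_k_a, -log10(est$k_a), tolerance = 1e-9)
  # constant Plateau x kobs across concentrations: degenerate, warns
  same <- lapply(conc_series()[1:4], function(cc) {
    f <- fit_association(model_tc(3.2e-5))
    f$conc <- cc
    f
  })
  expect_warning(est2 <- ktau_dose_response(same), "degenerate")
  expect_equal(est2$k_tau, 0.41 * occupancy(3.2e-5, 1.2e-7),
               tolerance = 1e-3)
})

test_that("k_tau methods agree with each other and with the truth", {
  # noiseless: single saturating concentration vs dose-response, within 1%
  fits <- lapply(conc_series(), function(cc) fit_association(model_tc(cc)))
  dr <- ktau_dose_response(fits)
  sat <- ktau_single_conc(fit_association(model_tc(3.2e-3)))  # >> K_A
  expect_equal(sat$k_tau / dr$k_tau, 1, tolerance = 0.01)
  # k_tau barely depends on a small k_off
  p_off <- arrestin_params(0.41, 0.91763, k_off = 0.03, k_a = 1.2e-7)
  sat_off <- ktau_single_conc(fit_association(model_tc(3.2e-3, p = p_off)))
  expect_equal(sat_off$k_tau / sat$k_tau, 1, tolerance = 0.02)
  # noisy end-to-end: all three methods within 5% of each other and truth
  fx <- builtin_fixtures(3)
  tcs <- preprocess_plate(generate_arrestin_plate(fx$angii_arrestin))
  conc <- vapply(tcs, `[[`, numeric(1), "conc")
  per <- lapply(split(tcs, conc), fit_association)
  est_dr <- ktau_dose_response(per)
  est_sc <- ktau_single_conc(per[[length(per)]])
  est_gl <- suppressWarnings(ktau_global(tcs))
  ks <- c(est_dr$k_tau, est_sc$k_tau, est_gl$k_tau)
  expect_true(all(abs(ks - 0.41) / 0.41 < 0.05))
  expect_lt(diff(range(ks)) / mean(ks), 0.05)
})

test_that("global fit recovers all five mechanism parameters when noiseless", {
  tcs <- lapply(conc_series(), model_tc)
  est <- ktau_global(tcs)
  co <- est$details$coefficients
  expect_equal(unname(co["k_tau"]), 0.41, tolerance = 0.01)
  expect_equal(unname(co["c_scale"]), 0.91763, tolerance = 0.01)
  expect_equal(unname(co["k_off"]), 0.01, tolerance = 0.01 * 0.91763)
  expect_equal(unname(10^co["log10_ka"]), 1.2e-7, tolerance = 0.01)
  expect_equal(unname(co["n"]), 1, tolerance = 0.01)
  # single concentration has no leverage: refused
  expect_error(ktau_global(lapply(rep(3.2e-5, 3), model_tc)),
               "3 distinct")
})

test_that("normalization to the reference agonist matches the worked table", {
  df <- data.frame(ligand = c("AngII", "TRV055", "SII"),
                   k_tau = c(0.41, 0.38, 0.20))
  norm <- normalize_to_reference(df, "AngII")
  expect_equal(norm$percent_of_reference[norm$ligand == "AngII"], 100)
  expect_equal(norm$percent_of_reference[norm$ligand == "TRV055"],
               100 * 0.38 / 0.41, tolerance = 1e-9)  # 92.7 -> displays 93
  expect_equal(round(norm$percent_of_reference[norm$ligand == "SII"], 1),
               48.8)
  expect_error(normalize_to_reference(df, "nope"), "not measured")
})

test_that("k_tau scales with the display normalization; percent does not", {
  t <- default_grid()
  y <- assoc_oracle(t, 0, 0.44, 0.9, 0.75)
  est1 <- ktau_single_conc(fit_association(time_course(t, y, "upward")))
  est2 <- ktau_single_conc(fit_association(time_course(t, 2.5 * y, "upward")))
  expect_equal(est2$k_tau / est1$k_tau, 2.5, tolerance = 1e-6)
  df <- data.frame(ligand = c("A", "B"), k_tau = c(est1$k_tau, est1$k_tau / 2))
  df_scaled <- transform(df, k_tau = k_tau * 2.5)
  expect_equal(normalize_to_reference(df, "A")$percent_of_reference,
               normalize_to_reference(df_scaled, "A")$percent_of_reference)
})

test_that("endpoint EC50 decreases with the evaluation time", {
  fits <- lapply(conc_series(), function(cc) fit_association(model_tc(cc)))
  e1 <- endpoint_dose_response(fits, 1)
  e20 <- endpoint_dose_response(fits, 20)
  expect_gt(e1$ec50, e20$ec50)
})
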