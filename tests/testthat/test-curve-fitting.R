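test_that("association and decay fits recover noiseless parameters exactly", {
  t <- default_grid()
  truth <- c(y0 = 0.02, plateau = 0.45, k = 0.9, x0 = 0.8)
  fa <- fit_association(time_course(t, assoc_oracle(t, 0.02, 0.45, 0.9, 0.8),
                                    "upward"))
  expect_equal(coef(fa), truth, tolerance = 1e-4)
  expect_gt(fa$r2, 0.9999)
  fd <- fit_decay(time_course(t, decay_oracle(t, 1, 0.56, 0.9, 0.8),
                              "downward"))
  expect_equal(coef(fd), c(y0 = 1, plateau = 0.56, k = 0.9, x0 = 0.8),
               tolerance = 1e-4)
  # downward trace and its inversion give the same rate and onset
  tc_dn <- time_course(t, decay_oracle(t, 1, 0.56, 0.9, 0.8), "downward")
  fa2 <- fit_association(invert_downward(tc_dn))
  expect_equal(unname(coef(fa2)["k"]), unname(coef(fd)["k"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(fa2)["x0"]), unname(coef(fd)["x0"]),
               tolerance = 1e-6)
})

test_that("fitting is invariant to a constant time shift (free onset)", {
  t <- default_grid()
  y <- assoc_oracle(t, 0.02, 0.43, 0.9, 0.8)
  f1 <- fit_association(time_course(t, y, "upward"))
  f2 <- fit_association(time_course(t + 5, y, "upward"))
  expect_equal(unname(coef(f2)["x0"] - coef(f1)["x0"]), 5, tolerance = 1e-6)
  for (nm in c("y0", "plateau", "k"))
    expect_equal(unname(coef(f1)[nm]), unname(coef(f2)[nm]),
                 tolerance = 1e-6)
})

test_that("degenerate inputs are refused or flagged, never silently wrong", {
  t <- default_grid()
  # constant trace: flat fit with unidentifiable rate flagged by infinite se
  f <- fit_association(time_course(t, rep(0.5, length(t)), "upward"))
  expect_false(f$identifiable)
  expect_equal(unname(coef(f)["plateau"]), unname(coef(f)["y0"]),
               tolerance = 1e-8)
  expect_true(is.infinite(f$se[["k"]]))
  # too few post-onset points
  expect_error(
    fit_association(time_course(seq(0, 2, 0.25),
                                c(0, 0, 0, 0, 0, 0, 0.1, 0.15, 0.18),
                                "upward")),
    "post-onset")
  # wrong direction
  expect_error(fit_association(time_course(t, rep(1, length(t)), "downward")),
               "invert_downward")
})

test_that("replicates are pooled as separate points, not averaged", {
  t <- default_grid()
  y <- assoc_oracle(t, 0, 0.44, 0.9, 0.75)
  tcs <- list(time_course(t, y + 0.01, "upward", replicate = 1),
              time_course(t, y - 0.01, "upward", replicate = 2))
  f <- fit_association(tcs)
  expect_equal(length(f$data$values), 2 * length(t))
  expect_equal(f$n_traces, 2)
  expect_equal(unname(coef(f)["plateau"]), 0.44, tolerance = 1e-3)
})

test_that("rise-and-fall fit recovers noiseless parameters, with drift", {
  t <- default_grid()
  y <- risefall_oracle(t, 0.05, 1.7, 2, 0.2, 0.8)
  f <- fit_risefall(time_course(t, y, "upward"))
  expect_equal(coef(f), c(baseline = 0.05, c = 1.7, k1 = 2, k2 = 0.2,
                          x0 = 0.8), tolerance = 1e-4)
  yd <- risefall_oracle(t, 0.05, 1.7, 2, 0.2, 0.8, drift = -0.002)
  fd <- fit_risefall(time_course(t, yd, "upward"), drift = TRUE)
  expect_equal(unname(coef(fd)["drift"]), -0.002, tolerance = 1e-3)
  expect_equal(unname(coef(fd)["c"]), 1.7, tolerance = 1e-3)
  # rate ordering convention holds regardless of the generating order
  expect_gte(unname(coef(f)["k1"]), unname(coef(f)["k2"]))
})

test_that("drift is recoverable from noisy calcium-like traces", {
  sc <- plate_scenario(
    list(AngII = risefall_params(2.2, 3, 0.5, drift = -0.002)),
    3.2e-5, replicates = 3, direction = "upward", channel = "red",
    noise_cv = 0.03, seed = 71)
  f <- fit_risefall(preprocess_plate(generate_risefall_plate(sc)),
                    drift = TRUE)
  # recovery study bound: drift within 50% at 3% noise
  expect_lt(abs(coef(f)[["drift"]] - (-0.002)), 0.001)
  expect_lt(abs(coef(f)[["c"]] - 2.2) / 2.2, 0.15)
})

test_that("sigmoid fit round-trips and locates its midpoint", {
  cc <- 10^seq(-8.5, -4.5, 0.5)
  resp <- sigmoid_oracle(cc, top = 0.41, bottom = 0, log_l50 = -6.92,
                         hill = 1)
  f <- fit_sigmoid(cc, resp, fix_bottom = TRUE)
  expect_equal(coef(f), c(top = 0.41, log_l50 = -6.92, hill = 1),
               tolerance = 1e-4)
  # response at the L50 is half the top
  expect_equal(predict(f, f$l50), 0.41 / 2, tolerance = 1e-6)
  # free-bottom variant
  resp2 <- sigmoid_oracle(cc, 0.41, 0.05, -6.92, 1.2)
  f2 <- fit_sigmoid(cc, resp2, fix_bottom = FALSE)
  expect_equal(unname(coef(f2)["bottom"]), 0.05, tolerance = 1e-4)
  expect_error(fit_sigmoid(cc, rep(1, length(cc))), "unidentifiable")
  expect_error(fit_sigmoid(cc[1:3], resp[1:3]), "4 distinct")
})

test_that("sigmoid midpoint is recovered within 0.1 log units at 3% noise", {
  set.seed(9)
  cc <- rep(10^seq(-8.5, -4.5, 0.5), 3)
  resp <- sigmoid_oracle(cc, 0.41, 0, -6.92, 1) * (1 + rnorm(length(cc), 0, 0.03))
  f <- fit_sigmoid(cc, resp)
  expect_lt(abs(coef(f)[["log_l50"]] - (-6.92)), 0.1)
})

test_that("operational model: limits, round trip and noisy recovery", {
  cc <- 10^seq(-8, -4.5, 0.5)
  resp <- operational_oracle(cc, e_m = 0.259, tau = 1.8, k_a = 1.2e-6)
  f <- fit_operational(cc, resp, e_m = 0.259)
  expect_equal(unname(coef(f)["tau"]), 1.8, tolerance = 1e-3)
  expect_equal(unname(coef(f)["k_a"]), 1.2e-6, tolerance = 1e-3)
  # tau = 1 at saturation gives half the system maximum
  expect_equal(operational_oracle(1, 0.5, 1, 1e-9), 0.25, tolerance = 1e-6)
  # tau -> infinity approaches E_m at saturation
  expect_equal(operational_oracle(1e-3, 0.259, 1e5, 1.2e-6), 0.259,
               tolerance = 1e-3)
  # warning when the fixed E_m is not above the data
  expect_warning(fit_operational(cc, resp * 1.6, e_m = 0.259), "E_m")
  # noisy recovery within 15%
  set.seed(21)
  cc3 <- rep(cc, 3)
  noisy <- operational_oracle(cc3, 0.259, 1.8, 1.2e-6) *
    (1 + rnorm(length(cc3), 0, 0.03))
  fn <- fit_operational(cc3, noisy, e_m = 0.259)
  expect_lt(abs(coef(fn)[["tau"]] - 1.8) / 1.8, 0.15)
})

test_that("fits on study-quality data reach the reported R2 range", {
  sc <- plate_scenario(list(AngII = angii_truth()), conc_series(),
                       replicates = 2, noise_cv = 0.03, seed = 55)
  fits <- fit_plate(generate_arrestin_plate(sc))
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  # all effective concentrations fit well; the top ones exceed 0.95
  top <- r2[seq_along(r2) > length(r2) - 4]
  expect_true(all(top > 0.95))
})
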