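make_trace <- function(values, times = seq(0, 3, 0.25), addition = 1.3,
                       direction = "downward") {
  raw_trace(times, values, addition_time = addition, direction = direction)
}

test_that("delta-F/F divides by the pre-addition mean and is scale free", {
  t <- seq(0, 3, 0.25)
  v <- c(rep(1000, 6), rep(560, 7))
  tc <- delta_f_over_f(make_trace(v, t))
  expect_equal(tc$values[1:6], rep(1, 6))
  expect_equal(tc$values[7], 0.56)
  # ratio invariance under a constant gain
  tc2 <- delta_f_over_f(make_trace(v * 37.2, t))
  expect_equal(tc$values, tc2$values)
  expect_error(delta_f_over_f(make_trace(v - 1000, t)), "positive")
})

test_that("inversion maps dF/F to 1 - dF/F and is an involution", {
  t <- seq(0, 3, 0.25)
  tc <- delta_f_over_f(make_trace(c(rep(1000, 6), rep(560, 7)), t))
  inv <- invert_downward(tc)
  expect_equal(inv$values[7], 0.44)
  expect_equal(inv$values[1], 0)
  expect_equal(inv$direction, "upward")
  back <- invert_downward(inv)
  expect_equal(back$values, tc$values)
  expect_equal(back$direction, "downward")
})

test_that("preprocessing then fitting recovers the generating curve shape", {
  sc <- plate_scenario(list(AngII = angii_truth()), 3.2e-5, replicates = 1,
                       noise_cv = 0, jitter_sd = 0, seed = 1)
  tcs <- preprocess_plate(generate_arrestin_plate(sc))
  tc <- tcs[[1]]
  truth <- ifelse(tc$times < 0.75, 0,
                  arrestin_response(pmax(tc$times - 0.75, 0), 3.2e-5,
                                    angii_truth()))
  expect_equal(tc$values, truth, tolerance = 1e-10)
})

test_that("percent CV matches hand computation and flags identity", {
  t <- seq(0, 3, 0.25)
  mk <- function(v) time_course(t, rep(v, length(t)), "upward")
  ident <- percent_cv(list(mk(0.8), mk(0.8)))
  expect_equal(ident$cv, rep(0, length(t)))
  pair <- percent_cv(list(mk(0.9), mk(1.1)))
  expect_equal(pair$cv, rep(100 * sd(c(0.9, 1.1)) / 1, length(t)),
               tolerance = 1e-9)  # 14.14%
  expect_error(percent_cv(list(mk(1))), "2")
})

test_that("generated replicate CV is flat across the trace at ~noise level", {
  sc <- plate_scenario(list(AngII = angii_truth()), 3.2e-5, replicates = 4,
                       noise_cv = 0.03, seed = 17)
  dff <- lapply(generate_arrestin_plate(sc), delta_f_over_f)
  cv <- percent_cv(dff)
  # constant-CV noise model: early and late segments look alike
  early <- cv$cv[cv$time < 5]; late <- cv$cv[cv$time > 15]
  expect_lt(abs(median(early) - median(late)), 1.5)
  expect_gt(median(cv$cv), 1.2)
  expect_lt(median(cv$cv), 4.5)
})

test_that("Z-prime has its textbook boundary values and monotonicity", {
  t <- seq(0, 2, 0.25)
  mk <- function(v) time_course(t, rep(v, length(t)), "upward")
  # zero spread, separated means: perfect window
  z <- z_prime(list(mk(1), mk(1)), list(mk(0), mk(0)))
  expect_equal(z$z_prime, rep(1, length(t)))
  # sd_pos = sd_neg = separation/6 sits exactly at 0
  d <- 1 / (6 * sqrt(2))   # two points at +/- d have sample sd 1/6
  z0 <- z_prime(list(mk(1 - d), mk(1 + d)), list(mk(-d), mk(d)))
  expect_equal(z0$z_prime, rep(0, length(t)), tolerance = 1e-9)
  # no separation: sentinel
  zs <- z_prime(list(mk(1), mk(1)), list(mk(1), mk(1)))
  expect_true(all(zs$z_prime == -Inf))
  # widening either group's spread lowers Z'
  za <- z_prime(list(mk(0.95), mk(1.05)), list(mk(0), mk(0)))
  zb <- z_prime(list(mk(0.90), mk(1.10)), list(mk(0), mk(0)))
  expect_true(all(zb$z_prime < za$z_prime))
})

test_that("plateau-phase Z-prime is high and exceeds rise-phase Z-prime", {
  sc <- plate_scenario(list(AngII = angii_truth()), c(0, 1e-5),
                       replicates = 4, noise_cv = 0.03, seed = 19)
  tcs <- preprocess_plate(generate_arrestin_plate(sc))
  conc <- vapply(tcs, `[[`, numeric(1), "conc")
  z <- z_prime(tcs[conc > 0], tcs[conc == 0])
  rise <- z$z_prime[z$time > 0.9 & z$time < 1.6]
  plateau <- z$z_prime[z$time > 10]
  expect_gt(median(plateau), 0.5)
  expect_gt(median(plateau), median(rise))
})

test_that("a half-rate ligand looks partial early and near-full late", {
  fits_full <- lapply(conc_series(), function(cc) fit_association(model_tc(cc)))
  fits_half <- lapply(conc_series() * 3,
                      function(cc) fit_association(model_tc(cc, p = sii_truth())))
  e1f <- endpoint_dose_response(fits_full, 1)
  e1h <- endpoint_dose_response(fits_half, 1)
  e20f <- endpoint_dose_response(fits_full, 20)
  e20h <- endpoint_dose_response(fits_half, 20)
  expect_lt(e1h$e_max / e1f$e_max, 0.75)    # evident partial agonism at 1 min
  expect_gt(e20h$e_max / e20f$e_max, 0.85)  # masked at the plateau
})
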