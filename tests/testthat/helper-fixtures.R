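# Test helpers. Curve formulas here are written out independently of the
# package internals so round-trip tests check the implementation against a
# separately coded oracle.

default_grid <- function() seq(0, 20, by = 0.15)

# independent association-exponential oracle (piecewise baseline)
assoc_oracle <- function(t, y0, plateau, k, x0) {
  ifelse(t < x0, y0, y0 + (plateau - y0) * (1 - exp(-k * (t - x0))))
}

decay_oracle <- function(t, y0, plateau, k, x0) {
  ifelse(t < x0, y0, plateau + (y0 - plateau) * exp(-k * (t - x0)))
}

risefall_oracle <- function(t, baseline, c, k1, k2, x0, drift = 0) {
  core <- ifelse(t < x0, 0,
                 c / (k1 - k2) * (exp(-k2 * (t - x0)) - exp(-k1 * (t - x0))))
  baseline + drift * t + core
}

sigmoid_oracle <- function(conc, top, bottom, log_l50, hill) {
  x <- log10(conc)
  bottom + (top - bottom) / (1 + 10^((log_l50 - x) * hill))
}

operational_oracle <- function(conc, e_m, tau, k_a, n = 1) {
  rho <- conc^n / (k_a^n + conc^n)
  e_m * rho * tau / (1 + rho * tau)
}

# AngII-like ground truth: k_tau 0.41 NFU/min, K_A 120 nM, saturating
# kobs = ln2 / 0.75 min (45-s half-time) with k_off = 0.01
angii_truth <- function() arrestin_params(k_tau = 0.41, c_scale = 0.91763,
                                          k_off = 0.01, k_a = 1.2e-7)

# SII-like: half the rate, ~9-fold weaker affinity, 84-s half-time
sii_truth <- function() arrestin_params(k_tau = 0.20, c_scale = 0.50175,
                                        k_off = 0.01, k_a = 1.1e-6)

conc_series <- function() 10^seq(-8, -4.5, by = 0.5)

# noiseless model trace with onset x0, as a ready-to-fit time course
model_tc <- function(conc, p = angii_truth(), t = default_grid(), x0 = 0.75) {
  y <- ifelse(t < x0, 0, arrestin_response(pmax(t - x0, 0), conc, p))
  time_course(t, y, direction = "upward", conc = conc)
}
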