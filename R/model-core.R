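# Mechanistic forward models: arrestin recruitment (association exponential,
# observed rate rho_A * C + k_-N) and the two-regulation-mechanism rise-and-fall
# model for second-messenger signals. These are the ground truth used by the
# simulator and the independent reference for the fitters.

#' Fractional receptor occupancy
#'
#' Hill-type occupancy of the receptor by agonist,
#' \eqn{\rho_A = [A]^n / (K_A^n + [A]^n)}.
#'
#' @param conc Agonist concentration (molar), vectorised. Must be >= 0.
#' @param k_a Equilibrium dissociation constant \eqn{K_A} (molar), > 0.
#' @param n Binding slope factor (dimensionless), > 0. Default 1 (mass action).
#' @return Occupancy fraction in \[0, 1\].
#' @examples
#' occupancy(1.2e-7, k_a = 1.2e-7)        # 0.5 at K_A
#' occupancy(3.2e-5, k_a = 1.2e-7)        # near saturation
#' @export
occupancy <- function(conc, k_a, n = 1) {
  if (!is.numeric(k_a) || length(k_a) != 1L || !is.finite(k_a) || k_a <= 0)
    stop("'k_a' must be a single positive number (molar)")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a single positive number")
  if (any(conc < 0, na.rm = TRUE))
    stop("'conc' must be non-negative")
  out <- conc^n / (k_a^n + conc^n)
  out[is.infinite(conc)] <- 1
  out
}

#' Arrestin model parameter set
#'
#' Parameters of the receptor-arrestin interaction model. The individual
#' quantities total receptor, total arrestin and the association rate constant
#' are not separately identifiable from time-course data; the model is
#' parameterised by their products: `k_tau` (the initial recruitment rate,
#' total arrestin x total receptor x k_N, in normalized fluorescence units
#' per minute) and `c_scale` (the occupancy-independent part of the observed
#' rate constant, min^-1). Both the receptor-excess and arrestin-excess
#' stoichiometry scenarios reduce to this same parameterisation; the scenario
#' is recorded as metadata only.
#'
#' @param k_tau Initial recruitment rate (NFU min^-1), >= 0.
#' @param c_scale Occupancy-independent observed-rate scale C (min^-1), > 0.
#' @param k_off Arrestin-receptor dissociation rate constant k_-N (min^-1),
#'   >= 0. Default 0.
#' @param k_a Agonist equilibrium dissociation constant (molar), > 0.
#' @param n Binding slope factor, > 0. Default 1.
#' @param scenario Stoichiometry label, `"receptor_excess"` or
#'   `"arrestin_excess"`; metadata only.
#' @return An object of class `"arrestin_params"`.
#' @export
arrestin_params <- function(k_tau, c_scale, k_off = 0, k_a, n = 1,
                            scenario = c("receptor_excess", "arrestin_excess")) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(k_tau), length(k_tau) == 1L, k_tau >= 0,
            is.numeric(c_scale), length(c_scale) == 1L, c_scale > 0,
            is.numeric(k_off), length(k_off) == 1L, k_off >= 0,
            is.numeric(k_a), length(k_a) == 1L, k_a > 0,
            is.numeric(n), length(n) == 1L, n > 0)
  structure(list(k_tau = k_tau, c_scale = c_scale, k_off = k_off,
                 k_a = k_a, n = n, scenario = scenario),
            class = "arrestin_params")
}

#' @export
print.arrestin_params <- function(x, ...) {
  cat("Arrestin recruitment parameters (", x$scenario, ")\n", sep = "")
  cat(sprintf("  k_tau   %.4g NFU/min\n  c_scale %.4g /min\n  k_off   %.4g /min\n",
              x$k_tau, x$c_scale, x$k_off))
  cat(sprintf("  K_A     %.4g M (pK_A %.2f), slope n = %.3g\n",
              x$k_a, -log10(x$k_a), x$n))
  invisible(x)
}

#' Observed rate constant of arrestin recruitment
#'
#' \eqn{k_{obs} = \rho_A C + k_{-N}}: monotone non-decreasing in agonist
#' concentration, with saturation limit `c_scale + k_off`.
#'
#' @param conc Agonist concentration (molar), vectorised.
#' @param p An [arrestin_params()] object.
#' @return Rate constant(s), min^-1.
#' @export
arrestin_kobs <- function(conc, p) {
  stopifnot(inherits(p, "arrestin_params"))
  occupancy(conc, p$k_a, p$n) * p$c_scale + p$k_off
}

#' Arrestin recruitment time course (closed form)
#'
#' The ternary-complex level over time after agonist addition:
#' \deqn{[NRA]_t = \frac{\rho_A k_\tau}{k_{obs}} (1 - e^{-k_{obs} t})}
#' The initial slope is \eqn{\rho_A k_\tau} and the asymptote (Plateau) is
#' \eqn{\rho_A k_\tau / k_{obs}}, so Plateau x kobs recovers the
#' occupancy-scaled initial rate exactly. When `kobs` is zero the limiting
#' linear form \eqn{\rho_A k_\tau t} is used.
#'
#' @param t Time since agonist addition (minutes), >= 0, vectorised.
#' @param conc Agonist concentration (molar), scalar.
#' @param p An [arrestin_params()] object.
#' @return Signal in normalized fluorescence units.
#' @export
arrestin_response <- function(t, conc, p) {
  stopifnot(inherits(p, "arrestin_params"), length(conc) == 1L)
  if (any(t < 0)) stop("'t' must be non-negative")
  rho <- occupancy(conc, p$k_a, p$n)
  kobs <- rho * p$c_scale + p$k_off
  if (kobs == 0) return(rho * p$k_tau * t)
  rho * p$k_tau / kobs * (1 - exp(-kobs * t))
}

#' Rise-and-fall (biexponential) signaling time course
#'
#' The two-regulation-mechanism signaling model
#' \deqn{y = \frac{C}{k_1 - k_2}(e^{-k_2 t} - e^{-k_1 t}) + baseline + drift\, t}
#' whose initial slope equals `c` (the initial rate of signaling, k-tau for
#' the downstream pathway) regardless of `k1` and `k2`. Rates are exchanged
#' so that `k1 >= k2` (the expression is symmetric under exchange). Near the
#' `k1 = k2` degeneracy (relative gap below 1e-6) the analytic limit
#' \eqn{C t e^{-k t}} with the mean rate is used to avoid catastrophic
#' cancellation; `k2 = 0` reduces to the association exponential
#' \eqn{(C/k_1)(1 - e^{-k_1 t})}.
#'
#' @param t Time since onset (minutes), >= 0, vectorised.
#' @param c Initial rate constant C (NFU min^-1), >= 0.
#' @param k1,k2 Rate constants of the two exponential phases (min^-1), >= 0.
#' @param baseline Pre-stimulus signal level (NFU). Default 0.
#' @param drift Linear baseline drift (NFU min^-1). Default 0.
#' @return Signal in normalized fluorescence units.
#' @export
risefall_response <- function(t, c, k1, k2, baseline = 0, drift = 0) {
  stopifnot(is.numeric(c), c >= 0, is.numeric(k1), k1 >= 0,
            is.numeric(k2), k2 >= 0)
  if (any(t < 0)) stop("'t' must be non-negative")
  if (k1 < k2) { tmp <- k1; k1 <- k2; k2 <- tmp }
  core <- if (k1 <= 0) {
    c * t                              # both rates zero: pure initial-rate line
  } else if ((k1 - k2) / k1 < 1e-6) {
    km <- (k1 + k2) / 2                # degenerate limit, k1 -> k2
    c * t * exp(-km * t)
  } else {
    c / (k1 - k2) * (exp(-k2 * t) - exp(-k1 * t))
  }
  baseline + drift * t + core
}

#' Rise-and-fall model parameter set
#'
#' @param c Initial rate constant C (NFU min^-1), >= 0; equals k-tau for the
#'   signaling pathway.
#' @param k1,k2 Rate constants (min^-1); reordered so `k1 >= k2`.
#' @param baseline Pre-stimulus signal (NFU). Default 0.
#' @param drift Linear baseline drift (NFU min^-1). Default 0.
#' @return An object of class `"risefall_params"`.
#' @export
risefall_params <- function(c, k1, k2, baseline = 0, drift = 0) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0,
            is.numeric(k1), length(k1) == 1L, k1 >= 0,
            is.numeric(k2), length(k2) == 1L, k2 >= 0,
            is.numeric(baseline), length(baseline) == 1L,
            is.numeric(drift), length(drift) == 1L)
  if (k1 < k2) { tmp <- k1; k1 <- k2; k2 <- tmp }
  structure(list(c = c, k1 = k1, k2 = k2, baseline = baseline, drift = drift),
            class = "risefall_params")
}

#' @export
print.risefall_params <- function(x, ...) {
  cat(sprintf("Rise-and-fall parameters: C = %.4g NFU/min, k1 = %.4g, k2 = %.4g /min",
              x$c, x$k1, x$k2))
  if (x$drift != 0) cat(sprintf(", drift = %.4g NFU/min", x$drift))
  cat("\n")
  invisible(x)
}

#' Numerically integrate the arrestin recruitment mechanism
#'
#' Integrates \eqn{d[NRA]/dt = \rho_A k_\tau - [NRA] k_{obs}} from
#' \eqn{[NRA]_0 = 0} with `deSolve`. This is the independent oracle for
#' [arrestin_response()]: both must agree to high relative precision.
#'
#' @param conc Agonist concentration (molar), scalar.
#' @param p An [arrestin_params()] object.
#' @param t_grid Increasing time grid (minutes) starting at 0.
#' @param rtol,atol Solver tolerances passed to [deSolve::ode()].
#' @return Numeric vector of `[NRA]` at `t_grid`.
#' @export
simulate_arrestin_ode <- function(conc, p, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "arrestin_params"))
  if (length(t_grid) < 1L || t_grid[1] != 0 ||
      (length(t_grid) > 1L && any(diff(t_grid) <= 0)))
    stop("'t_grid' must be increasing and start at 0")
  rho <- occupancy(conc, p$k_a, p$n)
  kobs <- rho * p$c_scale + p$k_off
  if (length(t_grid) == 1L) return(0)
  deriv <- function(t, y, parms) list(rho * p$k_tau - y * kobs)
  sol <- deSolve::ode(y = c(nra = 0), times = t_grid, func = deriv,
                      parms = NULL, rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE solver failed to converge (istate = ", diagn[1], ")")
  if (nrow(sol) != length(t_grid))
    stop("ODE solver returned an incomplete solution")
  unname(sol[, "nra"])
}
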