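# Concentration-response fits: the variable-slope sigmoid (four-parameter
# logistic on log10 concentration) and the operational model of agonism with
# the system maximum fixed externally.

.sigmoid_curve <- function(x, top, bottom, log_l50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_l50 - x) * hill))
}

#' Fit the variable-slope sigmoid concentration-response curve
#'
#' Fits \eqn{y = Bottom + (Top - Bottom) / (1 + 10^{(\log L_{50} - x) Hill})}
#' with \eqn{x = \log_{10}} concentration. For the k-tau analysis (Plateau x
#' kobs plotted against concentration) the bottom is fixed at zero. The
#' midpoint is reported as L50 rather than EC50 because for the Plateau x
#' kobs plot it estimates the ligand equilibrium dissociation constant, not
#' a potency.
#'
#' @param conc Agonist concentrations (molar), > 0; at least 4 distinct
#'   values are required.
#' @param response Responses at `conc` (replicates as separate entries).
#' @param fix_bottom Logical; constrain the bottom asymptote to zero
#'   (default `TRUE`, the k-tau convention).
#' @return An object of class `c("sigmoid_fit", "ktau_fit")` with
#'   coefficients `top`, `log_l50`, `hill` (plus `bottom` when free) and a
#'   convenience field `l50` (molar).
#' @export
fit_sigmoid <- function(conc, response, fix_bottom = TRUE) {
  conc <- unname(as.numeric(conc)); response <- unname(as.numeric(response))
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("'conc' must be positive (molar) for the log fit")
  if (length(unique(conc)) < 4L)
    stop("at least 4 distinct concentrations are required")
  if (diff(range(response)) < 1e-12 * max(abs(response), 1))
    stop("responses are all equal; the sigmoid is unidentifiable")
  x <- log10(conc)
  top0 <- max(response)
  bottom0 <- if (fix_bottom) 0 else min(response)
  mid <- (top0 + bottom0) / 2
  l50_0 <- unname(x[which.min(abs(response - mid))])
  if (fix_bottom) {
    start <- c(top = top0, log_l50 = l50_0, hill = 1)
    model_fn <- function(p) .sigmoid_curve(x, p[1], 0, p[2], p[3])
  } else {
    start <- c(top = top0, bottom = bottom0, log_l50 = l50_0, hill = 1)
    model_fn <- function(p) .sigmoid_curve(x, p[1], p[2], p[3], p[4])
  }
  nlow <- length(start)
  lower <- rep(-Inf, nlow); upper <- rep(Inf, nlow)
  lower[names(start) == "hill"] <- 1e-3
  lower[names(start) == "log_l50"] <- min(x) - 3
  upper[names(start) == "log_l50"] <- max(x) + 3
  eng <- .nls_engine(start, lower, upper, model_fn, response)
  structure(c(eng,
              list(data = list(conc = conc, response = response),
                   fix_bottom = fix_bottom,
                   l50 = unname(10^eng$coefficients["log_l50"]))),
            class = c("sigmoid_fit", "ktau_fit"))
}

#' Fit the operational model of agonism with fixed system maximum
#'
#' Fits \eqn{y = E_m \rho_A \tau / (1 + \rho_A \tau)} with
#' \eqn{\rho_A = [A]^n / (K_A^n + [A]^n)}, holding the system maximum
#' \eqn{E_m} at an externally supplied constant (conventionally the fitted
#' Top of the reference full agonist at the same time point). The transducer
#' ratio \eqn{\tau} and affinity \eqn{K_A} are optimised on the log10 scale
#' for stability and reported on the natural scale with delta-method
#' standard errors.
#'
#' @inheritParams fit_sigmoid
#' @param e_m System maximal response (NFU), fixed.
#' @return An object of class `c("operational_fit", "ktau_fit")` with
#'   coefficients `tau`, `k_a` (molar) and `n`, and field `e_m`.
#' @export
fit_operational <- function(conc, response, e_m) {
  conc <- unname(as.numeric(conc)); response <- unname(as.numeric(response))
  stopifnot(length(conc) == length(response),
            is.numeric(e_m), length(e_m) == 1L, e_m > 0)
  if (any(conc <= 0)) stop("'conc' must be positive (molar)")
  if (length(unique(conc)) < 4L)
    stop("at least 4 distinct concentrations are required")
  maxr <- max(response)
  if (e_m <= maxr)
    warning("maximal observed response reaches the fixed E_m; ",
            "the transducer ratio will be poorly constrained (inflated)")
  tau0 <- maxr / max(e_m - maxr, 0.05 * e_m)
  tau0 <- min(max(tau0, 0.1), 50)
  ka0 <- conc[which.min(abs(response - maxr / 2))] * (1 + tau0)
  start <- c(log10_tau = log10(tau0), log10_ka = log10(ka0), n = 1)
  model_fn <- function(p) {
    tau <- 10^p[1]; ka <- 10^p[2]; n <- p[3]
    rho <- 1 / (1 + (ka / conc)^n)
    e_m * rho * tau / (1 + rho * tau)
  }
  eng <- .nls_engine(start,
                     lower = c(-4, log10(min(conc)) - 4, 0.05),
                     upper = c(6, log10(max(conc)) + 4, 10),
                     model_fn, response)
  lt <- eng$coefficients
  tau <- unname(10^lt["log10_tau"]); ka <- unname(10^lt["log10_ka"])
  jac <- diag(c(tau * log(10), ka * log(10), 1))
  vc_nat <- jac %*% eng$vcov %*% t(jac)
  co <- c(tau = tau, k_a = ka, n = unname(lt["n"]))
  dimnames(vc_nat) <- list(names(co), names(co))
  eng$coefficients <- co
  eng$se <- stats::setNames(sqrt(pmax(diag(vc_nat), 0)), names(co))
  eng$vcov <- vc_nat
  structure(c(eng,
              list(data = list(conc = conc, response = response), e_m = e_m)),
            class = c("operational_fit", "ktau_fit"))
}
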