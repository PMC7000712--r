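# Piecewise-baseline exponential fits. The signal is flat at y0 until the
# (free) onset time x0, then relaxes exponentially to the plateau. The free
# onset absorbs well-to-well differences in the time of agonist addition.
# Technical replicates are fitted as separate points, never pre-averaged.

.assoc_curve <- function(x, y0, plateau, k, x0) {
  ifelse(x < x0, y0, y0 + (plateau - y0) * (1 - exp(-k * (x - x0))))
}

.decay_curve <- function(x, y0, plateau, k, x0) {
  ifelse(x < x0, y0, plateau + (y0 - plateau) * exp(-k * (x - x0)))
}

.fit_exponential <- function(tc, decay) {
  tcs <- .as_tc_list(tc, direction = if (decay) "downward" else "upward")
  pts <- .pool_points(tcs)
  x <- pts$x; y <- pts$y
  init <- .exp_init(x, y, decay = decay)
  if (sum(x > init["x0"]) < 6L)
    stop("fewer than 6 post-onset points; refusing to fit")
  curve <- if (decay) .decay_curve else .assoc_curve
  model_fn <- function(p) curve(x, p[1], p[2], p[3], p[4])
  eng <- .nls_engine(start = init,
                     lower = c(-Inf, -Inf, 1e-8, min(x)),
                     upper = c(Inf, Inf, Inf, max(x)),
                     model_fn = model_fn, y = y)
  meta <- tcs[[1]]
  structure(c(eng,
              list(data = list(times = x, values = y),
                   ligand = meta$ligand, conc = meta$conc,
                   channel = meta$channel, n_traces = length(tcs))),
            class = c(if (decay) "decay_fit" else "assoc_fit",
                      "exp_fit", "ktau_fit"))
}

#' Fit the plateau-then-association exponential
#'
#' Fits the piecewise curve \eqn{y = y_0} for \eqn{x < x_0}, else
#' \eqn{y_0 + (Plateau - y_0)(1 - e^{-K(x - x_0)})}, to an upward time course
#' by unweighted least squares. All four parameters (`y0`, `plateau`, `k`,
#' `x0`) are free; the onset time is bounded to the observed time range and
#' the rate constant to be positive. Starting values are data-driven (see
#' the methods vignette). A list of replicate time courses is pooled and
#' fitted as separate points.
#'
#' @param tc A [time_course()] (direction `"upward"`) or list of replicate
#'   time courses. Downward traces must be inverted with [invert_downward()]
#'   first.
#' @return An object of class `c("assoc_fit", "exp_fit", "ktau_fit")` with
#'   components `coefficients` (`y0`, `plateau`, `k`, `x0`), `se`, `vcov`,
#'   `r2`, `fitted.values`, `residuals`, and the pooled `data`. Standard
#'   errors are infinite when a parameter is unidentifiable (e.g. the rate
#'   on a flat trace).
#' @seealso [fit_decay()] for downward traces, [ktau_single_conc()] and
#'   [ktau_dose_response()] for the efficacy analysis built on these fits.
#' @export
fit_association <- function(tc) .fit_exponential(tc, decay = FALSE)

#' Fit the plateau-then-decay exponential
#'
#' Downward-response counterpart of [fit_association()]:
#' \eqn{y = y_0} for \eqn{x < x_0}, else
#' \eqn{Plateau + (y_0 - Plateau) e^{-K(x - x_0)}}. Fitting a downward trace
#' with this equation and fitting its `1 - dF/F` inversion with the
#' association form are equivalent parameterisations of the same kinetics
#' (identical `k` and `x0`).
#'
#' @inheritParams fit_association
#' @return An object of class `c("decay_fit", "exp_fit", "ktau_fit")`;
#'   see [fit_association()].
#' @export
fit_decay <- function(tc) .fit_exponential(tc, decay = TRUE)

#' Fit the rise-and-fall biexponential
#'
#' Fits \eqn{y = Baseline + Drift\,x} for \eqn{x < x_0}, else
#' \eqn{Baseline + Drift\,x + \frac{C}{K_1-K_2}(e^{-K_2(x-x_0)} - e^{-K_1(x-x_0)})},
#' the two-regulation-mechanism signaling model whose fitted `c` equals the
#' initial rate of signaling (k-tau). The drift term accommodates a slowly
#' declining baseline (calcium sensors). The equation is symmetric under
#' exchange of the two rates, so `k1 >= k2` is enforced after convergence;
#' near-degenerate rates are evaluated on the analytic limit branch (see
#' [risefall_response()]), which keeps the objective continuous across the
#' degeneracy.
#'
#' @inheritParams fit_association
#' @param drift Logical; fit a linear baseline drift term? Default `FALSE`
#'   (drift fixed at 0).
#' @return An object of class `c("risefall_fit", "ktau_fit")` with
#'   coefficients `baseline`, `c`, `k1`, `k2`, `x0` and, when `drift = TRUE`,
#'   `drift`.
#' @export
fit_risefall <- function(tc, drift = FALSE) {
  tcs <- .as_tc_list(tc, direction = "upward")
  pts <- .pool_points(tcs)
  x <- pts$x; y <- pts$y
  ini <- .exp_init(x, y, decay = FALSE)
  x0 <- unname(ini["x0"])
  baseline <- unname(ini["y0"])
  kref <- unname(ini["k"])
  ys <- .smooth_for_init(y)
  peak <- max(ys) - baseline
  # the signal must start rising before the (smoothed) peak
  dt <- mean(diff(sort(unique(x))))
  x0_max <- max(x[which.max(ys)], min(x) + 2 * dt)
  x0 <- min(max(x0, min(x)), x0_max - dt / 10)
  # init baseline from the earliest reads (always pre-onset)
  baseline <- mean(y[x <= min(x) + 4 * dt])
  model_fn <- function(p) {
    dr <- if (drift) p[6] else 0
    base <- p[1] + dr * x
    resp <- ifelse(x < p[5], 0,
                   risefall_response(pmax(x - p[5], 0), p[2], p[3], p[4]))
    base + resp
  }
  lower <- c(-Inf, 0, 1e-8, 1e-8, min(x))
  upper <- c(Inf, Inf, Inf, Inf, x0_max)
  if (drift) {
    lower <- c(lower, -Inf); upper <- c(upper, Inf)
  }
  # the biexponential objective has competing ridges in (c, k1, x0); a small
  # deterministic multi-start over rate seeds picks the best basin
  seeds <- list(c(4, 0.25), c(2, 0.1), c(8, 0.5), c(1.5, 0.05))
  eng <- NULL
  for (sdk in seeds) {
    k1_0 <- sdk[1] * kref; k2_0 <- sdk[2] * kref
    c0 <- max(peak * k1_0 / 2, 1e-3)
    start <- c(baseline = baseline, c = c0, k1 = k1_0, k2 = k2_0, x0 = x0)
    if (drift) start <- c(start, drift = 0)
    cand <- tryCatch(suppressWarnings(
      .nls_engine(start, lower, upper, model_fn, y)),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(eng) || cand$rss < eng$rss)) eng <- cand
  }
  if (is.null(eng))
    stop("rise-and-fall fit did not converge from any starting point")
  # enforce the k1 >= k2 ordering convention on the report
  co <- eng$coefficients
  if (co["k1"] < co["k2"]) {
    ord <- names(co)
    ord[ord == "k1"] <- "kk"; ord[ord == "k2"] <- "k1"; ord[ord == "kk"] <- "k2"
    eng$coefficients <- stats::setNames(co, ord)[names(co)]
    eng$se <- stats::setNames(eng$se, ord)[names(co)]
    eng$vcov <- eng$vcov[ord, ord, drop = FALSE]
    dimnames(eng$vcov) <- list(names(co), names(co))
  }
  meta <- tcs[[1]]
  degenerate <- with(as.list(eng$coefficients),
                     k1 > 0 && (k1 - k2) / k1 < 1e-6)
  structure(c(eng,
              list(data = list(times = x, values = y), drift_fitted = drift,
                   degenerate = degenerate, ligand = meta$ligand,
                   conc = meta$conc, channel = meta$channel,
                   n_traces = length(tcs))),
            class = c("risefall_fit", "ktau_fit"))
}
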