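# Raw-trace preprocessing and plate quality control: delta-F/F baseline
# normalization, downward-sensor inversion, replicate %CV, the Z' screening
# window statistic, and single-time-point (endpoint) dose-response analysis.

#' Baseline-normalize a raw trace (delta-F/F)
#'
#' Divides every fluorescence value by the mean of the pre-addition
#' (baseline) values of the same well, yielding the delta-F/F scale. The
#' pre-addition segment is retained. Scaling the raw values by any constant
#' leaves the result unchanged.
#'
#' @param trace A [raw_trace()].
#' @return A [time_course()] on the delta-F/F scale (direction inherited).
#' @export
delta_f_over_f <- function(trace) {
  stopifnot(inherits(trace, "raw_trace"))
  base <- trace$fluorescence[trace$times < trace$addition_time]
  if (!length(base)) stop("baseline window is empty")
  m <- mean(base)
  if (m <= 0) stop("baseline mean must be positive; cannot normalize")
  time_course(trace$times, trace$fluorescence / m,
              direction = trace$direction, ligand = trace$ligand,
              conc = trace$conc, replicate = trace$replicate,
              channel = trace$channel)
}

#' Invert a downward sensor trace
#'
#' Replaces values by `1 - value` (1 - dF/F) and toggles the direction label,
#' so downward-responding sensors can be analyzed with the stimulation
#' (association) equations. Applying it twice is the identity.
#'
#' @param tc A [time_course()].
#' @return The inverted [time_course()].
#' @export
invert_downward <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  tc$values <- 1 - tc$values
  tc$direction <- if (tc$direction == "downward") "upward" else "downward"
  tc
}

#' Preprocess a plate for model fitting
#'
#' Applies [delta_f_over_f()] to every well and inverts downward traces, so
#' every response is an upward `1 - dF/F` signal whose pre-onset baseline
#' sits near zero (dF/F is ~1 before addition) — the form the stimulation
#' equations expect.
#'
#' @param plate A list of [raw_trace()] objects (class `"plate"` from the
#'   generator or [read_plate()]).
#' @return A list of upward [time_course()] objects.
#' @export
preprocess_plate <- function(plate) {
  stopifnot(is.list(plate))
  lapply(plate, function(tr) {
    tc <- delta_f_over_f(tr)
    if (tc$direction == "downward") invert_downward(tc) else tc
  })
}

#' Replicate coefficient of variation over time
#'
#' Percent CV (100 x sample sd / mean) of technical replicates at each
#' shared time point.
#'
#' @param tcs List of replicate [time_course()] objects with identical time
#'   grids (>= 2 replicates).
#' @return Data frame with columns `time` and `cv` (percent).
#' @export
percent_cv <- function(tcs) {
  stopifnot(is.list(tcs), length(tcs) >= 2L,
            all(vapply(tcs, inherits, logical(1), "time_course")))
  times <- tcs[[1]]$times
  for (tc in tcs[-1])
    if (!isTRUE(all.equal(tc$times, times)))
      stop("replicates must share the same time grid")
  vals <- do.call(cbind, lapply(tcs, `[[`, "values"))
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  data.frame(time = times, cv = 100 * s / m)
}

#' Z-prime screening-window statistic over time
#'
#' \eqn{Z' = 1 - 3(\sigma_+ + \sigma_-) / |\mu_+ - \mu_-|} at each time
#' point, computed from positive-control and negative-control replicate
#' wells (sample standard deviations). Zero mean separation yields `-Inf`
#' as a "no window" sentinel.
#'
#' @param pos,neg Lists of replicate [time_course()] objects (identical time
#'   grids) for the positive and negative controls.
#' @return Data frame with columns `time` and `z_prime` (bounded above by 1).
#' @export
z_prime <- function(pos, neg) {
  grab <- function(tcs) do.call(cbind, lapply(tcs, `[[`, "values"))
  times <- pos[[1]]$times
  vp <- grab(pos); vn <- grab(neg)
  if (nrow(vp) != nrow(vn)) stop("control groups must share the time grid")
  sep <- abs(rowMeans(vp) - rowMeans(vn))
  spread <- apply(vp, 1, stats::sd) + apply(vn, 1, stats::sd)
  z <- ifelse(sep == 0, -Inf, 1 - 3 * spread / sep)
  data.frame(time = times, z_prime = z)
}

#' Endpoint (single-time-point) dose-response analysis
#'
#' Evaluates each per-concentration fitted time-course model at a fixed time
#' after signal onset and fits the variable-slope sigmoid to the resulting
#' responses. Responses are read from the fitted curves, not raw wells,
#' which removes well-to-well addition-time offsets (each well is evaluated
#' at its own fitted onset plus `time_point`). Used to contrast endpoint
#' pharmacology (time-dependent EC50/Emax) with the kinetic k-tau method.
#'
#' @param fits List of converged time-course fits spanning the concentration
#'   range (one per concentration; association, decay or rise-and-fall).
#' @param time_point Time after onset (minutes) at which to read the
#'   response.
#' @return An object of class `"endpoint_dr"`: list with `time_point`,
#'   `ec50` (molar), `e_max` (NFU), `hill`, the per-concentration `conc` and
#'   `response`, and the underlying sigmoid `fit`.
#' @export
endpoint_dose_response <- function(fits, time_point) {
  stopifnot(is.list(fits), length(fits) >= 4L, time_point > 0)
  conc <- vapply(fits, `[[`, numeric(1), "conc")
  resp <- vapply(fits, function(f) {
    co <- coef(f)
    base_par <- intersect(c("y0", "baseline"), names(co))[1]
    yhat <- predict(f, newdata = unname(co["x0"]) + time_point)
    mag <- yhat - unname(co[base_par])
    if (inherits(f, "decay_fit")) -mag else mag
  }, numeric(1))
  sf <- fit_sigmoid(conc, resp, fix_bottom = TRUE)
  structure(list(time_point = time_point, ec50 = sf$l50,
                 e_max = unname(coef(sf)["top"]),
                 hill = unname(coef(sf)["hill"]),
                 conc = conc, response = resp, fit = sf),
            class = "endpoint_dr")
}

#' @export
print.endpoint_dr <- function(x, ...) {
  cat(sprintf("Endpoint dose-response at %.3g min after onset:\n",
              x$time_point))
  cat(sprintf("  EC50 = %.4g M, Emax = %.4g NFU, Hill = %.3g\n",
              x$ec50, x$e_max, x$hill))
  invisible(x)
}
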