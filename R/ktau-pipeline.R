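# The k-tau measurement workflows. k-tau, the initial rate of recruitment or
# signaling by the agonist-occupied receptor, equals Plateau x kobs at a
# maximally effective agonist concentration. It can be estimated from a full
# concentration-response (asymptote of the Plateau x kobs sigmoid), from a
# single saturating concentration, from the rise-and-fall C parameter, or by
# global fitting of all concentrations simultaneously.

new_ktau_estimate <- function(k_tau, se, method, ligand, pathway = NA_character_,
                              k_a = NA_real_, details = NULL) {
  structure(list(k_tau = unname(k_tau), se = unname(se),
                 k_a = unname(k_a),
                 p_k_a = if (is.na(k_a)) NA_real_ else -log10(k_a),
                 method = method, ligand = ligand, pathway = pathway,
                 details = details),
            class = "ktau_estimate")
}

#' @export
print.ktau_estimate <- function(x, ...) {
  cat(sprintf("k_tau estimate (%s method): %s", x$method, x$ligand))
  if (!is.na(x$pathway)) cat(" /", x$pathway)
  cat("\n")
  cat(sprintf("  k_tau = %.4g +/- %.2g NFU/min\n", x$k_tau, x$se))
  if (!is.na(x$k_a))
    cat(sprintf("  K_A   = %.4g M (pK_A %.2f)\n", x$k_a, x$p_k_a))
  invisible(x)
}

#' @export
as.data.frame.ktau_estimate <- function(x, ...) {
  data.frame(ligand = x$ligand, pathway = x$pathway, method = x$method,
             k_tau = x$k_tau, se = x$se, k_a = x$k_a, p_k_a = x$p_k_a,
             stringsAsFactors = FALSE)
}

#' Measure k-tau from a concentration-response of exponential fits
#'
#' Computes Plateau x kobs for each per-concentration association fit, fits
#' the variable-slope sigmoid (bottom fixed at zero) against log
#' concentration, and reads k-tau off the top of the curve. The midpoint
#' L50 estimates the ligand equilibrium dissociation constant K_A.
#'
#' @param fits List of [fit_association()] results, one per concentration
#'   (>= 4 concentrations), each carrying its concentration metadata.
#' @return A `"ktau_estimate"` with `method = "dose_response"`, the fitted
#'   `k_a`/`p_k_a`, and the underlying sigmoid fit in `$details`.
#' @export
ktau_dose_response <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "assoc_fit")))
  conc <- vapply(fits, `[[`, numeric(1), "conc")
  if (length(unique(conc)) < 4L)
    stop("at least 4 concentrations with converged fits are required")
  pk <- vapply(fits, function(f) {
    co <- coef(f); unname(co["plateau"] * co["k"])
  }, numeric(1))
  if (diff(range(pk)) < 1e-10 * max(abs(pk), 1)) {
    warning("Plateau x kobs is constant across concentrations; ",
            "the sigmoid is degenerate, reporting the mean")
    return(new_ktau_estimate(mean(pk), stats::sd(pk) / sqrt(length(pk)),
                             method = "dose_response",
                             ligand = fits[[1]]$ligand))
  }
  sf <- fit_sigmoid(conc, pk, fix_bottom = TRUE)
  if (sf$l50 > max(conc) / 3)
    warning("no saturation within the tested concentration range; ",
            "k_tau is effectively a lower bound")
  new_ktau_estimate(coef(sf)["top"], sf$se["top"],
                    method = "dose_response", ligand = fits[[1]]$ligand,
                    k_a = sf$l50, details = sf)
}

#' Measure k-tau from a single saturating concentration
#'
#' At a maximally effective concentration the occupancy is ~1 and
#' Plateau x kobs equals k-tau directly. The standard error is obtained by
#' first-order propagation using the fit covariance of (Plateau, kobs).
#'
#' @param fit A converged [fit_association()] result at a saturating
#'   concentration.
#' @param k_a_hint Optional known K_A (molar); a warning is attached when the
#'   fitted concentration is below `100 * k_a_hint` (the saturation
#'   criterion).
#' @return A `"ktau_estimate"` with `method = "single_conc"` (no affinity).
#' @export
ktau_single_conc <- function(fit, k_a_hint = NULL) {
  if (inherits(fit, "decay_fit"))
    stop("invert the downward trace (invert_downward) and refit with ",
         "fit_association before measuring k_tau")
  stopifnot(inherits(fit, "assoc_fit"))
  co <- coef(fit)
  p <- unname(co["plateau"]); k <- unname(co["k"])
  vc <- vcov(fit)
  cov_pk <- if (all(is.finite(vc[c("plateau", "k"), c("plateau", "k")])))
    vc["plateau", "k"] else 0
  se_p <- fit$se["plateau"]; se_k <- fit$se["k"]
  v <- (k * se_p)^2 + (p * se_k)^2 + 2 * p * k * cov_pk
  if (!is.null(k_a_hint) && is.finite(fit$conc) && fit$conc < 100 * k_a_hint)
    warning("concentration ", signif(fit$conc, 3), " M is below 100 x K_A; ",
            "the saturation assumption may not hold and k_tau will be ",
            "underestimated by the occupancy factor")
  new_ktau_estimate(p * k, sqrt(max(v, 0)), method = "single_conc",
                    ligand = fit$ligand, details = fit)
}

#' Measure k-tau from a rise-and-fall fit
#'
#' For rise-and-fall (second messenger) responses at a saturating agonist
#' concentration the fitted initial-rate constant `c` is k-tau.
#'
#' @param fit A converged [fit_risefall()] result.
#' @return A `"ktau_estimate"` with `method = "risefall"`.
#' @export
ktau_risefall <- function(fit) {
  stopifnot(inherits(fit, "risefall_fit"))
  new_ktau_estimate(coef(fit)["c"], fit$se["c"], method = "risefall",
                    ligand = fit$ligand, details = fit)
}

#' Measure k-tau by global fitting across concentrations
#'
#' Simultaneously fits all time courses of one ligand to the mechanistic
#' model with a concentration-dependent observed rate,
#' \deqn{y = \frac{\rho_{A,n} k_\tau}{\rho_{A,n} C + k_{-N}}
#'   (1 - e^{-(\rho_{A,n} C + k_{-N})(t - x_0)})}
#' with \eqn{\rho_{A,n} = [A]^n/(K_A^n + [A]^n)}, sharing
#' (k_tau, c_scale, k_off, K_A, n) and a single onset time across wells.
#' Traces must be preprocessed (baseline ~0, upward). Replicates are fitted
#' as separate points. A warning is raised when `c_scale` and `k_off` are
#' nearly perfectly anti-correlated (identifiability limit).
#'
#' @param tcs List of upward [time_course()] objects for one ligand spanning
#'   at least 3 distinct concentrations.
#' @return A `"ktau_estimate"` with `method = "global"`; `$details$coefficients`
#'   holds the full parameter vector.
#' @export
ktau_global <- function(tcs) {
  tcs <- .as_tc_list(tcs, direction = "upward")
  conc <- vapply(tcs, `[[`, numeric(1), "conc")
  ligand <- unique(vapply(tcs, `[[`, character(1), "ligand"))
  if (length(ligand) != 1L) stop("all traces must share one ligand")
  if (length(unique(conc)) < 3L)
    stop("global fitting requires at least 3 distinct concentrations")
  # per-concentration association fits seed the global parameters
  per <- lapply(split(tcs, conc), fit_association)
  ks <- vapply(per, function(f) unname(coef(f)["k"]), numeric(1))
  pk <- vapply(per, function(f) unname(coef(f)["plateau"] * coef(f)["k"]),
               numeric(1))
  x0s <- vapply(per, function(f) unname(coef(f)["x0"]), numeric(1))
  kt0 <- max(pk)
  c0 <- max(max(ks) - min(ks), 0.05)
  koff0 <- max(min(ks) / 2, 1e-4)
  ka0 <- tryCatch(fit_sigmoid(as.numeric(names(per)), pk)$l50,
                  error = function(e) stats::median(conc))
  all_t <- unlist(lapply(tcs, `[[`, "times"))
  y <- unlist(lapply(tcs, `[[`, "values"))
  conc_pt <- rep(conc, vapply(tcs, function(z) length(z$times), integer(1)))
  start <- c(k_tau = kt0, c_scale = c0, k_off = koff0,
             log10_ka = log10(ka0), n = 1, x0 = mean(x0s))
  model_fn <- function(p) {
    rho <- 1 / (1 + (10^p[4] / conc_pt)^p[5])
    kobs <- rho * p[2] + p[3]
    ifelse(all_t < p[6], 0,
           rho * p[1] / kobs * (1 - exp(-kobs * (all_t - p[6]))))
  }
  eng <- .nls_engine(start,
                     lower = c(0, 1e-6, 0, log10(min(conc)) - 4, 0.2,
                               min(all_t)),
                     upper = c(Inf, Inf, Inf, log10(max(conc)) + 4, 5,
                               max(all_t)),
                     model_fn, y)
  vc <- eng$vcov
  if (all(is.finite(vc[c("c_scale", "k_off"), c("c_scale", "k_off")]))) {
    denom <- sqrt(vc["c_scale", "c_scale"] * vc["k_off", "k_off"])
    if (denom > 0 && abs(vc["c_scale", "k_off"] / denom) > 0.98)
      warning("c_scale and k_off are nearly perfectly anti-correlated; ",
              "their split is not identifiable from these data")
  }
  co <- eng$coefficients
  new_ktau_estimate(co["k_tau"], eng$se["k_tau"], method = "global",
                    ligand = ligand, k_a = unname(10^co["log10_ka"]),
                    details = eng)
}

#' Half-life of an exponential process
#'
#' Converts an observed rate constant (min^-1) to a half-life in seconds,
#' \eqn{t_{1/2} = 60 \ln 2 / k}.
#'
#' @param k Rate constant(s), min^-1, > 0.
#' @return Half-life in seconds.
#' @examples
#' half_life(log(2))   # 60 s
#' half_life(0.924)    # ~45 s, a fast arrestin response
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("'k' must be positive")
  60 * log(2) / k
}

#' pK_A / K_A conversions
#'
#' @param p_k_a Negative base-10 log of K_A in molar.
#' @param k_a K_A in molar.
#' @return The converted value (molar, or pK_A units).
#' @examples
#' pka_to_ka(6.92) * 1e9   # ~120 nM
#' @export
pka_to_ka <- function(p_k_a) 10^(-p_k_a)

#' @rdname pka_to_ka
#' @export
ka_to_pka <- function(k_a) {
  if (any(k_a <= 0)) stop("'k_a' must be positive (molar)")
  -log10(k_a)
}

#' Normalize k-tau estimates to a reference agonist
#'
#' Expresses each ligand's mean k-tau as a percentage of the reference
#' agonist's mean k-tau, separately within each pathway. Values are not
#' rounded; rounding happens only at display.
#'
#' @param estimates A list of `"ktau_estimate"` objects or a data frame with
#'   columns `ligand`, `k_tau` and optionally `pathway` and `se`. `NA` k-tau
#'   marks a response below detection and propagates as `NA` percent.
#' @param reference Reference ligand label; must be measured (k_tau > 0) in
#'   every pathway present.
#' @return A data frame with columns `ligand`, `pathway`, `k_tau`, `se`
#'   (NA when unavailable) and `percent_of_reference`.
#' @export
normalize_to_reference <- function(estimates, reference) {
  df <- .estimates_df(estimates)
  out <- do.call(rbind, lapply(split(df, df$pathway), function(d) {
    ref <- d$k_tau[d$ligand == reference]
    if (!length(ref) || all(is.na(ref)))
      stop("reference ligand '", reference, "' not measured in pathway '",
           d$pathway[1], "'")
    refm <- mean(ref, na.rm = TRUE)
    if (refm <= 0) stop("reference k_tau must be positive")
    agg <- .aggregate_ktau(d)
    agg$percent_of_reference <- 100 * agg$k_tau / refm
    agg
  }))
  rownames(out) <- NULL
  out
}

.estimates_df <- function(estimates) {
  if (is.data.frame(estimates)) {
    df <- estimates
    stopifnot(all(c("ligand", "k_tau") %in% names(df)))
    if (is.null(df$pathway)) df$pathway <- "default"
    if (is.null(df$se)) df$se <- NA_real_
    df[c("ligand", "pathway", "k_tau", "se")]
  } else {
    stopifnot(is.list(estimates),
              all(vapply(estimates, inherits, logical(1), "ktau_estimate")))
    do.call(rbind, lapply(estimates, function(e) {
      data.frame(ligand = e$ligand,
                 pathway = if (is.na(e$pathway)) "default" else e$pathway,
                 k_tau = e$k_tau, se = e$se, stringsAsFactors = FALSE)
    }))
  }
}

# mean k_tau per (ligand, pathway), pooling experiments; se combined in
# quadrature when available
.aggregate_ktau <- function(d) {
  out <- do.call(rbind, lapply(split(d, d$ligand), function(g) {
    n <- sum(!is.na(g$k_tau))
    data.frame(ligand = g$ligand[1], pathway = g$pathway[1],
               k_tau = if (n) mean(g$k_tau, na.rm = TRUE) else NA_real_,
               se = if (n && any(is.finite(g$se)))
                 sqrt(sum(g$se^2, na.rm = TRUE)) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[match(unique(d$ligand), out$ligand), , drop = FALSE]
}
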