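# Standard modelling-object methods shared by all fit classes.

#' @export
coef.ktau_fit <- function(object, ...) object$coefficients

#' @export
vcov.ktau_fit <- function(object, ...) object$vcov

#' @export
fitted.ktau_fit <- function(object, ...) object$fitted.values

#' @export
residuals.ktau_fit <- function(object, ...) object$residuals

.fit_label <- function(object) {
  switch(class(object)[1],
         assoc_fit = "Plateau-then-association exponential fit",
         decay_fit = "Plateau-then-decay exponential fit",
         risefall_fit = "Rise-and-fall biexponential fit",
         sigmoid_fit = "Variable-slope sigmoid concentration-response fit",
         operational_fit = "Operational-model fit (fixed E_m)",
         "Nonlinear least-squares fit")
}

#' @export
print.ktau_fit <- function(x, digits = 4, ...) {
  cat(.fit_label(x), "\n")
  if (!is.null(x$ligand))
    cat(sprintf("  %s at %.3g M, %d point(s)\n", x$ligand, x$conc,
                length(x$data$values)))
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.4f, residual sd = %.4g\n", x$r2, x$sigma))
  if (!x$identifiable)
    cat("note: some parameters are unidentifiable (infinite standard error)\n")
  invisible(x)
}

#' @export
summary.ktau_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se[names(object$coefficients)])
  structure(list(label = .fit_label(object), coefficients = tab,
                 r2 = object$r2, sigma = object$sigma,
                 df.residual = object$df.residual,
                 identifiable = object$identifiable),
            class = "summary.ktau_fit")
}

#' @export
print.summary.ktau_fit <- function(x, digits = 4, ...) {
  cat(x$label, "\n\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("\nR2 = %.4f, residual sd = %.4g on %d df\n",
              x$r2, x$sigma, x$df.residual))
  if (!x$identifiable)
    cat("note: some parameters are unidentifiable (infinite standard error)\n")
  invisible(x)
}

#' Predicted values from fitted time-course and dose-response models
#'
#' @param object A fitted object from [fit_association()], [fit_decay()],
#'   [fit_risefall()], [fit_sigmoid()] or [fit_operational()].
#' @param newdata Optional numeric vector at which to evaluate the fitted
#'   curve: times (minutes) for time-course fits, concentrations (molar) for
#'   dose-response fits. Defaults to the data used in fitting.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @name predict.ktau_fit
NULL

#' @rdname predict.ktau_fit
#' @export
predict.assoc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$times else newdata
  p <- object$coefficients
  unname(.assoc_curve(x, p["y0"], p["plateau"], p["k"], p["x0"]))
}

#' @rdname predict.ktau_fit
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$times else newdata
  p <- object$coefficients
  unname(.decay_curve(x, p["y0"], p["plateau"], p["k"], p["x0"]))
}

#' @rdname predict.ktau_fit
#' @export
predict.risefall_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$times else newdata
  p <- object$coefficients
  dr <- if ("drift" %in% names(p)) p["drift"] else 0
  base <- p["baseline"] + dr * x
  resp <- ifelse(x < p["x0"], 0,
                 risefall_response(pmax(x - p["x0"], 0),
                                   p["c"], p["k1"], p["k2"]))
  unname(base + resp)
}

#' @rdname predict.ktau_fit
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata
  p <- object$coefficients
  bottom <- if (object$fix_bottom) 0 else p["bottom"]
  unname(.sigmoid_curve(log10(conc), p["top"], bottom, p["log_l50"], p["hill"]))
}

#' @rdname predict.ktau_fit
#' @export
predict.operational_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata
  p <- object$coefficients
  rho <- 1 / (1 + (p["k_a"] / conc)^p["n"])
  unname(object$e_m * rho * p["tau"] / (1 + rho * p["tau"]))
}

#' @export
plot.ktau_fit <- function(x, n_grid = 200, ...) {
  dose <- inherits(x, c("sigmoid_fit", "operational_fit"))
  if (dose) {
    xs <- x$data$conc; ys <- x$data$response
    graphics::plot(log10(xs), ys, xlab = "log10 concentration (M)",
                   ylab = "response (NFU)", ...)
    grid <- 10^seq(log10(min(xs)), log10(max(xs)), length.out = n_grid)
    graphics::lines(log10(grid), predict(x, grid))
  } else {
    xs <- x$data$times; ys <- x$data$values
    graphics::plot(xs, ys, xlab = "time (min)", ylab = "signal (NFU)", ...)
    grid <- seq(min(xs), max(xs), length.out = n_grid)
    graphics::lines(grid, predict(x, grid))
  }
  invisible(x)
}
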