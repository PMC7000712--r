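# Shared Levenberg-Marquardt driver. Unweighted least squares (plate-reader
# convention), asymptotic (Jacobian-based) standard errors, R^2 reported as
# 1 - RSS/TSS. Singular information matrices (e.g. an unidentifiable rate on
# a flat trace) yield infinite standard errors rather than an error.

.nls_engine <- function(start, lower, upper, model_fn, y) {
  resid_fn <- function(par) y - model_fn(par)
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                         ptol = 1e-10, maxfev = 10000))
  if (!(fit$info %in% 1:4))
    stop("nonlinear least-squares fit did not converge: ", fit$message,
         " (info = ", fit$info, ")", call. = FALSE)
  est <- fit$par
  names(est) <- names(start)
  n <- length(y); p <- length(est)
  rss <- sum(fit$fvec^2)
  dfres <- max(n - p, 1L)
  sigma2 <- rss / dfres
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc)) {
    se <- rep(Inf, p)
    vc <- matrix(NA_real_, p, p)
    identifiable <- FALSE
  } else {
    se <- sqrt(pmax(diag(vc), 0))
    identifiable <- all(is.finite(se))
  }
  names(se) <- names(start)
  dimnames(vc) <- list(names(start), names(start))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  fitted <- model_fn(est)
  list(coefficients = est, se = se, vcov = vc, r2 = r2, rss = rss,
       sigma = sqrt(sigma2), df.residual = n - p, fitted.values = fitted,
       residuals = y - fitted, identifiable = identifiable,
       niter = fit$niter)
}

# Running-mean smoother used only for starting-value heuristics (the fit
# itself always sees the raw points).
.smooth_for_init <- function(y) {
  n <- length(y)
  w <- max(3L, min(9L, round(n / 25)))
  if (w %% 2 == 0) w <- w + 1L
  if (n < w + 2L) return(y)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Data-driven starting values for the piecewise exponential fits: onset at the
# largest first difference of the smoothed trace, baseline from pre-onset
# points, plateau from the last 10% of points, rate from time-to-half-change.
.exp_init <- function(x, y, decay = FALSE) {
  ys <- .smooth_for_init(y)
  d <- diff(ys) / diff(x)
  d[!is.finite(d)] <- 0
  i <- if (decay) which.min(d) else which.max(d)
  x0 <- x[i]
  x0 <- min(max(x0, x[2]), x[max(length(x) - 3L, 2L)])
  pre <- y[x < x0]
  y0 <- if (length(pre)) mean(pre) else y[1]
  plateau <- mean(utils::tail(y, max(3L, ceiling(0.1 * length(y)))))
  half <- y0 + 0.5 * (plateau - y0)
  post_x <- x[x >= x0]; post_y <- ys[x >= x0]
  cross <- if (decay) which(post_y <= half) else which(post_y >= half)
  dt <- mean(diff(sort(unique(x))))
  t_half <- if (length(cross)) post_x[cross[1]] - x0 else (max(x) - x0) / 2
  k <- log(2) / max(t_half, dt)
  c(y0 = y0, plateau = plateau, k = k, x0 = x0)
}

.pool_points <- function(tcs) {
  x <- unlist(lapply(tcs, `[[`, "times"))
  y <- unlist(lapply(tcs, `[[`, "values"))
  o <- order(x)
  list(x = x[o], y = y[o])
}
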