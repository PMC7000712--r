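# Containers for single-well data. A raw_trace holds plate-reader fluorescence
# in arbitrary units together with the nominal agonist addition time; a
# time_course holds baseline-normalized (delta-F/F scale) values ready for
# fitting. Both are light classed lists; time is minutes, concentration molar.

#' Raw plate-reader trace for one well
#'
#' @param times Measurement times (minutes), strictly increasing.
#' @param fluorescence Raw fluorescence (arbitrary units), same length.
#' @param addition_time Nominal agonist addition time (minutes). At least 5
#'   measurements must precede it (they define the baseline window).
#' @param well Well label.
#' @param ligand Ligand label.
#' @param conc Agonist concentration (molar), >= 0.
#' @param replicate Technical replicate index.
#' @param channel Detection channel, `"green"` or `"red"`.
#' @param direction Sensor response direction, `"downward"` (fluorescence
#'   decreases on activation) or `"upward"`.
#' @return An object of class `"raw_trace"`.
#' @export
raw_trace <- function(times, fluorescence, addition_time, well = "W001",
                      ligand = "ligand", conc = 0, replicate = 1L,
                      channel = c("green", "red"),
                      direction = c("downward", "upward")) {
  channel <- match.arg(channel)
  direction <- match.arg(direction)
  times <- as.numeric(times); fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence))
    stop("'times' and 'fluorescence' must have the same length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (!is.numeric(conc) || conc < 0) stop("'conc' must be >= 0 (molar)")
  if (sum(times < addition_time) < 5L)
    stop("at least 5 baseline points before 'addition_time' are required")
  structure(list(times = times, fluorescence = fluorescence,
                 addition_time = addition_time, well = well, ligand = ligand,
                 conc = conc, replicate = as.integer(replicate),
                 channel = channel, direction = direction),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("Raw trace %s: %s at %.3g M (rep %d, %s %s sensor)\n",
              x$well, x$ligand, x$conc, x$replicate, x$channel, x$direction))
  cat(sprintf("  %d points, %.2f-%.2f min, addition at %.2f min\n",
              length(x$times), min(x$times), max(x$times), x$addition_time))
  invisible(x)
}

#' Normalized fluorescence time course for one well
#'
#' Values are on the delta-F/F scale (or its `1 - dF/F` inversion); see
#' [delta_f_over_f()] and [invert_downward()].
#'
#' @param times Measurement times (minutes), strictly increasing; >= 8 points.
#' @param values Normalized fluorescence (NFU), same length.
#' @param direction `"upward"` or `"downward"`.
#' @param ligand Ligand label.
#' @param conc Agonist concentration (molar), >= 0.
#' @param replicate Technical replicate index.
#' @param channel `"green"` or `"red"`.
#' @return An object of class `"time_course"`.
#' @export
time_course <- function(times, values, direction = c("upward", "downward"),
                        ligand = "ligand", conc = 0, replicate = 1L,
                        channel = c("green", "red")) {
  direction <- match.arg(direction)
  channel <- match.arg(channel)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (length(times) < 8L) stop("a time course needs at least 8 points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (!is.numeric(conc) || conc < 0) stop("'conc' must be >= 0 (molar)")
  structure(list(times = times, values = values, direction = direction,
                 ligand = ligand, conc = conc, replicate = as.integer(replicate),
                 channel = channel),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %s at %.3g M (rep %d, %s, %s)\n",
              x$ligand, x$conc, x$replicate, x$channel, x$direction))
  cat(sprintf("  %d points, %.2f-%.2f min, values %.3g-%.3g NFU\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  data.frame(time = x$times, value = x$values, ligand = x$ligand,
             conc = x$conc, replicate = x$replicate, channel = x$channel,
             direction = x$direction, stringsAsFactors = FALSE)
}

# Normalise fitter input to a list of time_course objects sharing a direction.
.as_tc_list <- function(tc, direction) {
  tcs <- if (inherits(tc, "time_course")) list(tc) else tc
  if (!is.list(tcs) || !all(vapply(tcs, inherits, logical(1), "time_course")))
    stop("expected a time_course or a list of time_course objects")
  dirs <- vapply(tcs, `[[`, character(1), "direction")
  if (any(dirs != direction)) {
    hint <- if (direction == "upward")
      " (apply invert_downward() to downward traces first)" else ""
    stop("all traces must be '", direction, "'", hint)
  }
  tcs
}
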