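# Seeded generator of realistic raw plate-reader experiments with known
# ground truth. Emulates the study conditions: 9-s read spacing, >= 5
# baseline reads before agonist addition, per-well onset-time jitter
# (sd 3 s), multiplicative Gaussian noise with constant CV, and downward
# or upward fluorescent sensors whose signal is a linear map of the model
# response (gain 1: model NFU = dF/F change).

#' Define a synthetic plate scenario
#'
#' Collects ligand ground-truth parameters, the concentration series, the
#' acquisition grid and the noise model into a reproducible scenario. The
#' mandatory seed makes every generated plate bit-reproducible.
#'
#' @param ligands Named list of [arrestin_params()] or [risefall_params()]
#'   objects (all of one kind per scenario).
#' @param concentrations Agonist concentrations (molar), e.g. a half-log
#'   dilution series up to 32 uM.
#' @param replicates Technical replicates per (ligand, concentration).
#'   Default 2 (duplicates).
#' @param t_max Total acquisition time (minutes). Default 20.
#' @param dt Read interval (minutes). Default 0.15 (9 s).
#' @param addition_time Nominal agonist addition time (minutes); at least 5
#'   reads must precede it. Default 0.75.
#' @param jitter_sd Per-well onset-time jitter sd (minutes). Default 0.05
#'   (3 s).
#' @param noise_cv Multiplicative noise CV (fraction), in \[0, 0.10\].
#'   Default 0.03.
#' @param f0 Baseline fluorescence level (arbitrary units). Default 1000.
#' @param gain Scalar mapping model signal (NFU) to the sensor dF/F span.
#'   Default 1.
#' @param direction Sensor direction. Default `"downward"` (arrestin and
#'   DAG sensors); use `"upward"` for calcium.
#' @param channel Detection channel label.
#' @param seed Mandatory integer seed.
#' @return An object of class `"plate_scenario"`.
#' @export
plate_scenario <- function(ligands, concentrations, replicates = 2L,
                           t_max = 20, dt = 0.15, addition_time = 0.75,
                           jitter_sd = 0.05, noise_cv = 0.03, f0 = 1000,
                           gain = 1, direction = c("downward", "upward"),
                           channel = c("green", "red"), seed) {
  direction <- match.arg(direction)
  channel <- match.arg(channel)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a scalar integer 'seed' is mandatory")
  if (!is.list(ligands) || is.null(names(ligands)) || any(names(ligands) == ""))
    stop("'ligands' must be a named list of parameter objects")
  kinds <- vapply(ligands, function(p)
    inherits(p, "arrestin_params") || inherits(p, "risefall_params"),
    logical(1))
  if (!all(kinds))
    stop("each ligand needs arrestin_params or risefall_params")
  if (noise_cv < 0 || noise_cv > 0.10)
    stop("'noise_cv' must be within [0, 0.10]")
  if (any(concentrations < 0)) stop("concentrations must be >= 0 (molar)")
  times <- seq(0, t_max, by = dt)
  if (sum(times < addition_time) < 5L)
    stop("fewer than 5 baseline reads before 'addition_time'")
  structure(list(ligands = ligands, concentrations = concentrations,
                 replicates = as.integer(replicates), times = times,
                 addition_time = addition_time, jitter_sd = jitter_sd,
                 noise_cv = noise_cv, f0 = f0, gain = gain,
                 direction = direction, channel = channel,
                 seed = as.integer(seed)),
            class = "plate_scenario")
}

#' @export
print.plate_scenario <- function(x, ...) {
  cat(sprintf("Plate scenario: %d ligand(s) x %d conc x %d rep, %d reads (%.2g-min spacing)\n",
              length(x$ligands), length(x$concentrations), x$replicates,
              length(x$times), x$times[2] - x$times[1]))
  cat(sprintf("  noise CV %.3g, onset jitter sd %.3g min, %s %s sensor, seed %d\n",
              x$noise_cv, x$jitter_sd, x$channel, x$direction, x$seed))
  invisible(x)
}

.generate_plate <- function(scenario, signal_fn) {
  set.seed(scenario$seed)
  times <- scenario$times
  # keep at least 5 reads strictly before the jittered onset
  min_x0 <- times[5] + 1e-6
  traces <- list()
  i <- 0L
  for (lig in names(scenario$ligands)) {
    p <- scenario$ligands[[lig]]
    for (conc in scenario$concentrations) {
      for (r in seq_len(scenario$replicates)) {
        i <- i + 1L
        x0 <- max(scenario$addition_time +
                    stats::rnorm(1, 0, scenario$jitter_sd), min_x0)
        sig <- signal_fn(times, x0, conc, p) * scenario$gain
        f_true <- if (scenario$direction == "downward")
          scenario$f0 * (1 - sig) else scenario$f0 * (1 + sig)
        f_obs <- f_true * (1 + stats::rnorm(length(times), 0,
                                            scenario$noise_cv))
        traces[[i]] <- raw_trace(times, f_obs,
                                 addition_time = scenario$addition_time,
                                 well = sprintf("W%03d", i), ligand = lig,
                                 conc = conc, replicate = r,
                                 channel = scenario$channel,
                                 direction = scenario$direction)
      }
    }
  }
  structure(traces, class = "plate", scenario = scenario)
}

#' Generate a synthetic arrestin-recruitment plate
#'
#' Forward-simulates the arrestin recruitment model for every (ligand,
#' concentration, replicate) well: a flat baseline at `f0` until the
#' jittered onset, then `f0 * (1 - gain * NRA(t - x0))` for the downward
#' sensor, with multiplicative Gaussian noise at the scenario CV.
#' Deterministic under a fixed seed.
#'
#' @param scenario A [plate_scenario()] whose ligands carry
#'   [arrestin_params()].
#' @return A list of [raw_trace()] objects (class `"plate"`), with the
#'   scenario attached as an attribute.
#' @export
generate_arrestin_plate <- function(scenario) {
  stopifnot(inherits(scenario, "plate_scenario"),
            all(vapply(scenario$ligands, inherits, logical(1),
                       "arrestin_params")))
  .generate_plate(scenario, function(times, x0, conc, p)
    arrestin_response(pmax(times - x0, 0), conc, p))
}

#' Generate a synthetic rise-and-fall signaling plate
#'
#' As [generate_arrestin_plate()], with the biexponential rise-and-fall
#' forward model (DAG- or calcium-like responses). A negative `drift` in the
#' ligand parameters produces the slowly declining baseline seen for
#' calcium sensors; the drift acts from time zero.
#'
#' @param scenario A [plate_scenario()] whose ligands carry
#'   [risefall_params()].
#' @return A `"plate"` list of [raw_trace()] objects.
#' @export
generate_risefall_plate <- function(scenario) {
  stopifnot(inherits(scenario, "plate_scenario"),
            all(vapply(scenario$ligands, inherits, logical(1),
                       "risefall_params")))
  .generate_plate(scenario, function(times, x0, conc, p) {
    core <- ifelse(times < x0, 0,
                   risefall_response(pmax(times - x0, 0), p$c, p$k1, p$k2))
    p$drift * times + core
  })
}

#' Built-in ground-truth scenarios
#'
#' Named scenarios with documented ground truth, modelled on the AT1
#' receptor study conditions. `angii_arrestin` uses the full agonist values
#' (k_tau 0.41 NFU/min, K_A 120 nM, saturating kobs 0.924 /min i.e. 45-s
#' half-time); `sii_arrestin` is the slow partial agonist (about half the
#' rate, ~9-fold weaker affinity, 84-s half-time); `trv055_arrestin` a
#' near-full agonist; `angii_single_conc` the single saturating
#' concentration (32 uM) design with triplicates; `angii_dag` and
#' `angii_calcium` rise-and-fall pathways (DAG C = 1.7, calcium C = 2.2
#' NFU/min, the calcium sensor upward with a slight negative drift); and
#' `bias_two_pathway` a two-pathway pair (arrestin + calcium) containing a
#' reference ligand and a ligand with a built-in arrestin/calcium kinetic
#' bias factor of 3.
#'
#' @param seed Base seed; sub-scenarios use fixed offsets from it.
#' @return Named list; each element is a [plate_scenario()] except
#'   `bias_two_pathway`, which is a list of two scenarios (`arrestin`,
#'   `calcium`).
#' @export
builtin_fixtures <- function(seed = 1L) {
  seed <- as.integer(seed)
  angii <- arrestin_params(k_tau = 0.41, c_scale = 0.91763, k_off = 0.01,
                           k_a = 1.2e-7)
  sii <- arrestin_params(k_tau = 0.20, c_scale = 0.50175, k_off = 0.01,
                         k_a = 1.1e-6)
  trv055 <- arrestin_params(k_tau = 0.38, c_scale = 0.92, k_off = 0.01,
                            k_a = 1.3e-7)
  conc8 <- 10^seq(-8, -4.5, by = 0.5)   # 10 nM .. 32 uM, half-log steps
  sat <- 3.2e-5
  list(
    angii_arrestin = plate_scenario(list(AngII = angii), conc8,
                                    replicates = 3L, seed = seed),
    angii_single_conc = plate_scenario(list(AngII = angii), sat,
                                       replicates = 3L, seed = seed + 1L),
    sii_arrestin = plate_scenario(list(SII = sii), conc8, replicates = 3L,
                                  seed = seed + 2L),
    sii_single_conc = plate_scenario(list(SII = sii), sat, replicates = 3L,
                                     seed = seed + 3L),
    trv055_arrestin = plate_scenario(list(TRV055 = trv055), conc8,
                                     replicates = 3L, seed = seed + 4L),
    angii_dag = plate_scenario(
      list(AngII = risefall_params(c = 1.7, k1 = 2, k2 = 0.2)), sat,
      replicates = 3L, channel = "red", seed = seed + 5L),
    angii_calcium = plate_scenario(
      list(AngII = risefall_params(c = 2.2, k1 = 3, k2 = 0.5,
                                   drift = -0.002)), sat,
      replicates = 3L, direction = "upward", channel = "red",
      seed = seed + 6L),
    bias_two_pathway = list(
      arrestin = plate_scenario(
        list(REF = arrestin_params(0.40, 0.92, 0.01, 1.2e-7),
             BIASED = arrestin_params(0.36, 0.92, 0.01, 1.2e-7)),
        sat, replicates = 3L, seed = seed + 7L),
      calcium = plate_scenario(
        list(REF = risefall_params(2.2, 2, 0.2),
             BIASED = risefall_params(0.66, 2, 0.2)),
        sat, replicates = 3L, direction = "upward", channel = "red",
        seed = seed + 8L)))
}
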