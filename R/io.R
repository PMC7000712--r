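# Plate file input/output and result serialization. Plate files are long
# delimited text, one row per (time, well) observation; time is stored in
# seconds in files (plate readers report seconds) and converted to minutes
# internally. Concentrations are molar in files. Results round-trip through
# a structured YAML tree.

.plate_columns <- c("time_s", "well", "ligand", "conc_molar", "replicate",
                    "channel", "direction", "fluorescence")

#' Write a plate to delimited text
#'
#' One row per (time, well) observation with the columns `time_s`, `well`,
#' `ligand`, `conc_molar`, `replicate`, `channel`, `direction`,
#' `fluorescence`, `addition_time_s`.
#'
#' @param plate A list of [raw_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(is.list(plate),
            all(vapply(plate, inherits, logical(1), "raw_trace")))
  rows <- do.call(rbind, lapply(plate, function(tr) {
    data.frame(time_s = tr$times * 60, well = tr$well, ligand = tr$ligand,
               conc_molar = tr$conc, replicate = tr$replicate,
               channel = tr$channel, direction = tr$direction,
               fluorescence = tr$fluorescence,
               addition_time_s = tr$addition_time * 60,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate file
#'
#' Reads and validates a long-format plate CSV (schema of [write_plate()]).
#' Malformed rows are reported with their line numbers; missing required
#' columns, non-monotone times within a well and duplicate (time, well)
#' pairs are hard errors.
#'
#' @param path CSV path.
#' @return A list of [raw_trace()] objects (class `"plate"`), one per well.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.plate_columns, names(df))
  if (length(missing_cols))
    stop("plate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"addition_time_s" %in% names(df))
    stop("plate file is missing required column(s): addition_time_s")
  num_cols <- c("time_s", "conc_molar", "replicate", "fluorescence",
                "addition_time_s")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad))
      stop("non-numeric value in column '", cn, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (file line(s) ", paste(utils::head(bad + 1L, 5), collapse = ", "),
           ")")
    df[[cn]] <- v
  }
  if (anyDuplicated(df[c("time_s", "well")]))
    stop("duplicate (time, well) observations: rows ",
         paste(utils::head(which(duplicated(df[c("time_s", "well")])), 5),
               collapse = ", "))
  wells <- split(df, factor(df$well, levels = unique(df$well)))
  traces <- lapply(wells, function(d) {
    if (any(diff(d$time_s) <= 0))
      stop("times are not strictly increasing in well ", d$well[1])
    raw_trace(d$time_s / 60, d$fluorescence,
              addition_time = d$addition_time_s[1] / 60, well = d$well[1],
              ligand = d$ligand[1], conc = d$conc_molar[1],
              replicate = d$replicate[1], channel = d$channel[1],
              direction = d$direction[1])
  })
  names(traces) <- NULL
  structure(traces, class = "plate")
}

#' @export
print.plate <- function(x, ...) {
  cat(sprintf("Plate with %d well(s); ligands: %s\n", length(x),
              paste(unique(vapply(x, `[[`, character(1), "ligand")),
                    collapse = ", ")))
  invisible(x)
}

#' Fit every (ligand, concentration) group of a plate
#'
#' Preprocesses the plate ([preprocess_plate()]) and fits each (ligand,
#' concentration) group with the requested time-course model, pooling
#' technical replicates as separate points.
#'
#' @param plate A `"plate"` list of [raw_trace()] objects.
#' @param model `"association"` (default) or `"risefall"`.
#' @param drift Passed to [fit_risefall()].
#' @return Named list of fits (`"ligand@conc"`).
#' @export
fit_plate <- function(plate, model = c("association", "risefall"),
                      drift = FALSE) {
  model <- match.arg(model)
  tcs <- preprocess_plate(plate)
  key <- vapply(tcs, function(z) sprintf("%s@%.6g", z$ligand, z$conc),
                character(1))
  groups <- split(tcs, factor(key, levels = unique(key)))
  lapply(groups, function(g)
    if (model == "association") fit_association(g)
    else fit_risefall(g, drift = drift))
}

# ---- structured results ----

.encode_results <- function(x) {
  if (is.data.frame(x)) {
    c(list(`_type` = "data.frame"), lapply(as.list(x), .encode_results))
  } else if (is.list(x)) {
    lapply(x, .encode_results)
  } else x
}

.decode_results <- function(x) {
  if (is.list(x)) {
    if (identical(x$`_type`, "data.frame")) {
      x$`_type` <- NULL
      as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
    } else lapply(x, .decode_results)
  } else x
}

#' Write / read structured results
#'
#' Serializes a results tree (lists, atomic vectors, data frames) to YAML
#' together with the tool version, the seed and an input-file checksum, such
#' that `read_results(write_results(x, ...))$results` reproduces `x`.
#'
#' @param results A list / data frame tree of plain values.
#' @param path Output YAML path.
#' @param seed Optional seed to record.
#' @param input Optional input file path; its MD5 checksum is recorded.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NULL, input = NULL) {
  payload <- list(
    tool = "ktau",
    version = as.character(utils::packageVersion("ktau")),
    seed = seed,
    input_md5 = if (!is.null(input)) unname(tools::md5sum(input)) else NULL,
    results = .encode_results(results))
  payload <- payload[!vapply(payload, is.null, logical(1))]
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  x <- yaml::read_yaml(path)
  x$results <- .decode_results(x$results)
  x
}
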