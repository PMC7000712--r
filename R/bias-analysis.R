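# Kinetic biased-agonism quantification: ratios of reference-normalized
# k-tau values between pathways. Undetectable responses are carried as NA
# ("below detection"), never as zero, so ratios against them are flagged
# rather than infinite.

#' Kinetic bias ratio
#'
#' Ratio of two reference-normalized k-tau percentages, e.g. arrestin over
#' calcium. The reference agonist's ratio is 1 by construction. A
#' non-positive or missing denominator marks "no measurable response" and
#' yields `NA`, not infinity.
#'
#' @param norm_a Numerator pathway percent-of-reference.
#' @param norm_b Denominator pathway percent-of-reference.
#' @return Dimensionless ratio(s); `NA` where the denominator is undetectable.
#' @examples
#' bias_ratio(93, 30)   # ~3.1, an arrestin-biased ligand
#' bias_ratio(100, 100) # 1, the reference agonist
#' @export
bias_ratio <- function(norm_a, norm_b) {
  ifelse(is.na(norm_b) | norm_b <= 0, NA_real_, norm_a / norm_b)
}

#' Build a kinetic bias table
#'
#' Normalizes per-pathway k-tau values to a reference agonist and forms
#' between-pathway ratios of the normalized values. Pathways in which the
#' reference was not measured are refused (dropped with a warning). Ligands
#' with a below-detection denominator response are flagged.
#'
#' @param estimates A data frame with columns `ligand`, `pathway`, `k_tau`
#'   (NA = below detection) and optionally `se`, or a list of
#'   `"ktau_estimate"` objects carrying pathway labels.
#' @param reference Reference ligand label (measured in every pathway).
#' @param pathway_pairs Optional list of length-2 character vectors
#'   `c(numerator, denominator)`. Default: the first pathway (in order of
#'   appearance) over each of the others.
#' @return An object of class `"bias_table"`: a list with `percent` (the
#'   normalized table), `ratios` (ligand, numerator, denominator, ratio,
#'   ratio_se, note) and `reference`.
#' @export
build_bias_table <- function(estimates, reference, pathway_pairs = NULL) {
  df <- .estimates_df(estimates)
  pathways <- unique(df$pathway)
  ok <- vapply(pathways, function(pw) {
    ref <- df$k_tau[df$pathway == pw & df$ligand == reference]
    length(ref) > 0 && any(is.finite(ref) & ref > 0)
  }, logical(1))
  if (any(!ok)) {
    warning("reference '", reference, "' missing in pathway(s): ",
            paste(pathways[!ok], collapse = ", "), "; dropped")
    df <- df[df$pathway %in% pathways[ok], , drop = FALSE]
    pathways <- pathways[ok]
  }
  if (length(pathways) < 2L)
    stop("at least two pathways with the reference measured are required")
  norm <- normalize_to_reference(df, reference)
  if (is.null(pathway_pairs))
    pathway_pairs <- lapply(pathways[-1], function(pw) c(pathways[1], pw))
  ligands <- unique(df$ligand)
  ratios <- do.call(rbind, lapply(pathway_pairs, function(pair) {
    a <- norm[norm$pathway == pair[1], ]
    b <- norm[norm$pathway == pair[2], ]
    do.call(rbind, lapply(ligands, function(lg) {
      pa <- a$percent_of_reference[a$ligand == lg]
      pb <- b$percent_of_reference[b$ligand == lg]
      pa <- if (length(pa)) pa else NA_real_
      pb <- if (length(pb)) pb else NA_real_
      r <- bias_ratio(pa, pb)
      note <- if (is.na(r)) "no measurable response in denominator" else ""
      rse <- .ratio_se(a, b, lg, reference, r)
      data.frame(ligand = lg, numerator = pair[1], denominator = pair[2],
                 norm_numerator = pa, norm_denominator = pb,
                 ratio = r, ratio_se = rse, note = note,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(ratios) <- NULL
  structure(list(percent = norm, ratios = ratios, reference = reference),
            class = "bias_table")
}

# first-order propagation over the four k_tau estimates entering the ratio
.ratio_se <- function(a, b, ligand, reference, r) {
  if (is.na(r)) return(NA_real_)
  rel2 <- 0
  for (d in list(a, b)) {
    for (lg in c(ligand, reference)) {
      row <- d[d$ligand == lg, ]
      if (nrow(row) && is.finite(row$se) && is.finite(row$k_tau) &&
          row$k_tau > 0)
        rel2 <- rel2 + (row$se / row$k_tau)^2
      else return(NA_real_)
    }
  }
  abs(r) * sqrt(rel2)
}

#' @export
print.bias_table <- function(x, digits = 3, ...) {
  cat("Kinetic bias table (reference:", x$reference, ")\n\n")
  wide <- stats::reshape(
    x$percent[c("ligand", "pathway", "percent_of_reference")],
    idvar = "ligand", timevar = "pathway", direction = "wide")
  names(wide) <- sub("percent_of_reference\\.", "% ", names(wide))
  print(format(wide, digits = digits), row.names = FALSE)
  cat("\nk_tau ratios:\n")
  r <- x$ratios
  r$ratio <- signif(r$ratio, digits)
  print(r[c("ligand", "numerator", "denominator", "ratio", "note")],
        row.names = FALSE)
  invisible(x)
}
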