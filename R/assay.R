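#' Specific median fluorescence intensity
#'
#' sMFI = MFI of the antigen-specific staining minus MFI of the matched
#' negative control. A negative result (staining below control) is reported
#' as-is, never clamped; the \code{"flag"} attribute marks such entries.
#'
#' @param specific,control non-negative MFI values (vectorised).
#' @return numeric vector of sMFI values with a character \code{"flag"}
#'   attribute (\code{"below control"} where negative, \code{""} otherwise).
#' @export
smfi <- function(specific, control) {
  stopifnot(is.finite(specific), is.finite(control))
  out <- specific - control
  attr(out, "flag") <- ifelse(out < 0, "below control", "")
  out
}

#' Transmigration percentage in a flow-chamber assay
#'
#' Fraction of interacting (adherent + transmigrated) leukocytes that
#' crossed the endothelial monolayer, as a percentage.
#'
#' @param adherent,transmigrated non-negative cell counts (vectorised).
#' @return percentage in [0, 100]; \code{NA} (flagged undefined) when both
#'   counts are zero.
#' @export
transmigrationPct <- function(adherent, transmigrated) {
  stopifnot(adherent >= 0, transmigrated >= 0)
  total <- adherent + transmigrated
  out <- ifelse(total > 0, 100 * transmigrated / total, NA_real_)
  attr(out, "flag") <- ifelse(total > 0, "", "undefined: no interacting cells")
  out
}

#' Normalise flow-assay counts to a reference endothelium
#'
#' Expresses each count field of a condition as a percentage of the same
#' field in the reference condition (e.g. HUVEC = 100%).
#'
#' @param counts data frame with columns \code{condition}, \code{rolling},
#'   \code{adherent}, \code{transmigrated} (one row per condition).
#' @param reference name of the reference condition present in
#'   \code{counts}, or a single-row data frame of the same shape.
#' @return data frame of percentages per condition and field; a field whose
#'   reference count is zero is \code{NA} (undefined), the others are still
#'   computed.
#' @export
normalizeToReference <- function(counts, reference) {
  fields <- c("rolling", "adherent", "transmigrated")
  stopifnot(all(c("condition", fields) %in% colnames(counts)))
  if (is.character(reference)) {
    sel <- counts$condition == reference
    if (sum(sel) != 1L) stop("reference condition not found: ", reference)
    ref <- counts[sel, ]
  } else {
    ref <- reference
  }
  out <- counts[, "condition", drop = FALSE]
  for (f in fields) {
    out[[f]] <- if (ref[[f]] > 0) 100 * counts[[f]] / ref[[f]] else NA_real_
  }
  out
}
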