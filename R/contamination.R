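# Marker-gene-based estimation of cross-contamination between two
# LCM-derived cell-type transcriptomes. A marker assumed absent from the
# pure target cell type but abundant in the source cell type gives the
# upper-bound estimate fraction = TPM(marker in target) / TPM(marker in
# source).

#' Estimate cross-contamination from a marker gene
#'
#' @param target Expression profile (data.frame `transcript_id`, `tpm`) of
#'   the possibly contaminated sample.
#' @param source Expression profile of the contaminating cell type; the
#'   marker must be present with TPM > 0.
#' @param marker_id Transcript id of a marker assumed absent from the pure
#'   target cell type (e.g. a Rubisco small-subunit transcript when the
#'   target is a non-green secretory cell).
#' @param markers Optional character vector of additional marker ids; when
#'   given, the reported fraction is the median of the per-marker ratios
#'   (single-marker estimation is the default behavior).
#' @return Object of class `contamination_estimate` with fields
#'   `target_cell_type`, `source_cell_type`, `marker_id`, `target_tpm`,
#'   `source_tpm`, `fraction` and `flagged` (`TRUE` when the fraction
#'   exceeds 1, i.e. the marker assumption is violated). Estimates above 1
#'   are reported, not clamped: the ratio is an upper bound on
#'   contamination.
#' @export
estimate_contamination <- function(target, source, marker_id,
                                   markers = NULL) {
  one <- function(m) {
    src <- source$tpm[match(m, source$transcript_id)]
    if (is.na(src) || src <= 0)
      stop("uninformative marker '", m,
           "': absent from the source profile or zero TPM")
    tgt <- target$tpm[match(m, target$transcript_id)]
    if (is.na(tgt)) tgt <- 0
    c(target = tgt, source = src, fraction = tgt / src)
  }
  main <- one(marker_id)
  fraction <- main[["fraction"]]
  if (!is.null(markers) && length(markers) > 0L) {
    all_m <- unique(c(marker_id, markers))
    fraction <- stats::median(vapply(all_m, function(m) one(m)[["fraction"]],
                                     0))
  }
  structure(list(
    target_cell_type = attr(target, "cell_type") %||% "target",
    source_cell_type = attr(source, "cell_type") %||% "source",
    marker_id = marker_id,
    target_tpm = main[["target"]],
    source_tpm = main[["source"]],
    fraction = fraction,
    flagged = fraction > 1), class = "contamination_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf(
    "<contamination_estimate> %s contribution of '%s' to '%s' (marker %s: %g / %g TPM)%s\n",
    format_percent(x$fraction), x$source_cell_type, x$target_cell_type,
    x$marker_id, x$target_tpm, x$source_tpm,
    if (x$flagged) " [FLAGGED: ratio > 1, marker assumption violated]" else ""))
  invisible(x)
}

#' Render a contamination fraction as a percentage
#'
#' @param fraction Numeric fraction.
#' @param digits Decimal places (default 1, matching the conventional
#'   reporting precision).
#' @return String such as `"40.8%"`.
#' @export
format_percent <- function(fraction, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), 100 * fraction)
}
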