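#' Operational no-reflow criteria
#'
#' No-reflow (persistent microvascular hypoperfusion despite successful
#' large-vessel recanalization) is called when all three hold: near-complete
#' or complete recanalization (eTICI 2c or 3), a whole-infarct percent CBF
#' difference strictly below -15, and relative hypoperfusion in at least 50%
#' of the infarct territory. The "< -15" bound is strict and the ">= 50%"
#' bound inclusive, exactly as worded. The visual volume judgment of human
#' raters is replaced here by the voxelwise [hypoperfused_fraction()]; every
#' output flags this as the operationalized criterion.
#'
#' @param percent_diff_threshold Percent CBF difference bound (strict <).
#'   Default -15.
#' @param volume_fraction_threshold Hypoperfused-fraction bound (inclusive
#'   >=), in (0, 1\]. Default 0.5.
#' @param qualifying_etici eTICI grades counting as successful
#'   recanalization. Default c("2c", "3").
#' @return An object of class `noreflow_criteria`.
#' @export
noreflow_criteria <- function(percent_diff_threshold = -15,
                              volume_fraction_threshold = 0.5,
                              qualifying_etici = c("2c", "3")) {
  if (!is.finite(percent_diff_threshold))
    stop("`percent_diff_threshold` must be finite")
  if (!is.finite(volume_fraction_threshold) ||
      volume_fraction_threshold <= 0 || volume_fraction_threshold > 1)
    stop("`volume_fraction_threshold` must lie in (0, 1]")
  legal <- c("0", "1", "2a", "2b", "2c", "3")
  if (!all(qualifying_etici %in% legal))
    stop("`qualifying_etici` must be a subset of ", paste(legal, collapse = ", "))
  structure(list(percent_diff_threshold = percent_diff_threshold,
                 volume_fraction_threshold = volume_fraction_threshold,
                 qualifying_etici = qualifying_etici),
            class = "noreflow_criteria")
}

#' Classify a subject as no-reflow
#'
#' Conjunction of the three component criteria; each component flag is
#' returned so a negative call can be traced to the failing criterion.
#'
#' @param readout A `perfusion_readout` (from [percent_cbf_difference()]),
#'   or any list with `percent_cbf_difference` and `hypoperfused_fraction`.
#' @param etici The subject's eTICI grade ("0", "1", "2a", "2b", "2c", "3").
#' @param criteria A [noreflow_criteria()].
#' @return An object of class `noreflow_result`: `is_noreflow` plus the
#'   component flags `etici_ok`, `diff_ok`, `fraction_ok`, the echoed inputs,
#'   and `operationalized = TRUE` marking the voxelwise substitution for the
#'   visual rating.
#' @export
classify_noreflow <- function(readout, etici, criteria = noreflow_criteria()) {
  stopifnot(inherits(criteria, "noreflow_criteria"))
  if (!is.list(readout) ||
      is.null(readout$percent_cbf_difference) ||
      is.null(readout$hypoperfused_fraction))
    stop("`readout` must carry percent_cbf_difference and hypoperfused_fraction")
  etici <- as.character(etici)
  legal <- c("0", "1", "2a", "2b", "2c", "3")
  if (length(etici) != 1L || !etici %in% legal)
    stop("`etici` must be one of ", paste(legal, collapse = ", "))
  pct <- readout$percent_cbf_difference
  frac <- readout$hypoperfused_fraction
  etici_ok <- etici %in% criteria$qualifying_etici
  diff_ok <- pct < criteria$percent_diff_threshold        # strict
  fraction_ok <- frac >= criteria$volume_fraction_threshold  # inclusive
  structure(list(
    is_noreflow = etici_ok && diff_ok && fraction_ok,
    etici_ok = etici_ok, diff_ok = diff_ok, fraction_ok = fraction_ok,
    percent_cbf_difference = pct, hypoperfused_fraction = frac,
    etici = etici, criteria = criteria, operationalized = TRUE
  ), class = "noreflow_result")
}

#' @export
print.noreflow_result <- function(x, ...) {
  cat(sprintf(
    paste0("noreflow_result: %s (operationalized criterion)\n",
           "  eTICI %s in {%s}: %s | %%CBF diff %.1f < %.1f: %s | ",
           "fraction %.2f >= %.2f: %s\n"),
    if (x$is_noreflow) "NO-REFLOW" else "not no-reflow",
    x$etici, paste(x$criteria$qualifying_etici, collapse = ","), x$etici_ok,
    x$percent_cbf_difference, x$criteria$percent_diff_threshold, x$diff_ok,
    x$hypoperfused_fraction, x$criteria$volume_fraction_threshold, x$fraction_ok))
  invisible(x)
}
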