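# Small experimental quantification formulas: blot densitometry arithmetic,
# colony-assay percent of control, caliper tumor volume.

#' Activated signal from total and phospho densitometry
#'
#' Raw activated signal = total - phospho; negative values clamp to 0 (a
#' lane whose phospho signal exceeds its total has no detectable active
#' pool). All values are then rescaled so the reference sample's activated
#' value equals 100.
#'
#' @param total_signal,phospho_signal non-negative densitometry values.
#' @param sample_id sample identifiers.
#' @param reference_id the sample scaled to 100.
#' @return data.frame with `sample_id`, `activated_raw`, `activated_scaled`.
#' @export
activated_signal <- function(total_signal, phospho_signal, sample_id,
                             reference_id) {
  if (any(total_signal < 0) || any(phospho_signal < 0)) {
    stop_sx("densitometry signals must be non-negative")
  }
  if (!reference_id %in% sample_id) stop_sx("reference sample not present")
  raw <- total_signal - phospho_signal
  n_clamped <- sum(raw < 0)
  if (n_clamped > 0L) sx_log(n_clamped, " negative activated value(s) set to 0")
  raw <- pmax(raw, 0)
  ref <- raw[match(reference_id, sample_id)]
  if (ref == 0) stop_sx("unscalable reference: activated value is 0 after clamping")
  data.frame(sample_id = as.character(sample_id), activated_raw = raw,
             activated_scaled = 100 * raw / ref, stringsAsFactors = FALSE)
}

#' Change in phospho-to-total ratio relative to an untreated sample
#'
#' `(phospho_t/total_t) / (phospho_u/total_u)`.
#'
#' @param treated_phospho,treated_total treated-sample signals.
#' @param untreated_phospho,untreated_total untreated-sample signals.
#' @return the fold change of the phospho ratio.
#' @export
phospho_ratio_change <- function(treated_phospho, treated_total,
                                 untreated_phospho, untreated_total) {
  if (treated_total <= 0) stop_sx("treated total signal must be positive")
  if (untreated_total <= 0) stop_sx("untreated total signal must be positive")
  if (untreated_phospho <= 0) stop_sx("untreated phospho signal must be positive")
  (treated_phospho / treated_total) / (untreated_phospho / untreated_total)
}

#' Percent-of-control viability from absorbance readings
#'
#' `100 * od_treated / od_control` per replicate; when `od_treated` holds
#' replicates they are summarized as mean and sample sd.
#'
#' @param od_treated OD570 reading(s) of the treated well(s).
#' @param od_control OD570 reading of the untreated control (must be > 0).
#' @return list with `percent` (per replicate), `mean`, `sd` (NA for a
#'   single replicate).
#' @export
percent_of_control <- function(od_treated, od_control) {
  if (length(od_control) != 1L || od_control <= 0) {
    stop_sx("od_control must be a single positive value")
  }
  pct <- 100 * od_treated / od_control
  list(percent = pct, mean = mean(pct),
       sd = if (length(pct) > 1L) stats::sd(pct) else NA_real_)
}

#' Xenograft tumor volume from caliper measurements
#'
#' `volume = 1/2 * length * width^2` (mm^3). The two axes are canonicalized
#' so that width is the smaller one before the asymmetric formula is applied.
#'
#' @param length_mm,width_mm caliper measurements in mm (vectors recycled
#'   elementwise).
#' @return tumor volume(s) in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop_sx("caliper dimensions must be positive")
  }
  l <- pmax(length_mm, width_mm)
  w <- pmin(length_mm, width_mm)
  0.5 * l * w^2
}
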