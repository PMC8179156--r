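# Isotope-enrichment fractions and tracer sulfur-budget arithmetic.

#' Labeled fraction of a metabolite
#'
#' Fraction of the heavy-isotope channel relative to the summed
#' monoisotopic + labeled channels,
#' `i_labeled / (i_mono + i_labeled)`. The two intensities are taken as
#' given (e.g. designated MS/MS fragment-ion channels); no
#' natural-abundance correction is applied.
#'
#' @param i_mono,i_labeled Non-negative intensities of the monoisotopic
#'   and labeled channels (vectorized).
#' @return Fraction(s) in `[0, 1]`.
#' @examples
#' labeled_fraction(58, 42) # 0.42
#' @export
labeled_fraction <- function(i_mono, i_labeled) {
  stopifnot(length(i_mono) == length(i_labeled))
  if (any(i_mono < 0 | i_labeled < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  tot <- i_mono + i_labeled
  if (any(tot == 0)) {
    stop("labeled fraction undefined when both channels are zero",
         call. = FALSE)
  }
  i_labeled / tot
}

#' Tracer dose available per plant
#'
#' A tracer applied at `concentration_um` micromolar in `volume_ml`
#' milliliters of medium shared by `n_plants` plants supplies
#' `concentration * volume / n_plants` nanomoles per plant
#' (uM * mL = nmol).
#'
#' @param concentration_um Tracer concentration in uM (> 0).
#' @param volume_ml Medium volume in mL (> 0).
#' @param n_plants Number of plants sharing the medium (> 0).
#' @return Dose in nmol per plant.
#' @examples
#' dose_per_plant(150, 2, 10) # 30 nmol
#' @export
dose_per_plant <- function(concentration_um, volume_ml, n_plants) {
  if (any(concentration_um <= 0) || any(volume_ml <= 0) ||
      any(n_plants <= 0)) {
    stop("concentration, volume and plant count must all be > 0",
         call. = FALSE)
  }
  concentration_um * volume_ml / n_plants
}

#' Percentage of the supplied label recovered in measured pools
#'
#' @param retained_nmol Numeric vector of labeled amounts recovered in
#'   individual pools, nmol per plant (may be empty).
#' @param dose_nmol Label supplied per plant, nmol (> 0).
#' @return Recovery in percent: `100 * sum(retained) / dose`.
#' @examples
#' recovery_percent(c(0.076, 0.150), 30) # ~0.75 %
#' @export
recovery_percent <- function(retained_nmol, dose_nmol) {
  stopifnot(length(dose_nmol) == 1L)
  if (dose_nmol <= 0) stop("dose must be > 0", call. = FALSE)
  if (any(retained_nmol < 0)) {
    stop("retained amounts must be non-negative", call. = FALSE)
  }
  100 * sum(retained_nmol) / dose_nmol
}
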