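# Preprocessing: noise flooring and internal-standard normalization.

#' Preprocessing configuration
#'
#' Defaults follow the untargeted workflow: a noise floor of 500
#' intensity units, lidocaine (m/z 235.1805) as the positive-mode
#' internal standard and 10-camphorsulfonic acid (m/z 231.0697) as the
#' negative-mode internal standard, matched within 0.01 Da. For
#' targeted matrices a noise floor of 10 is conventional.
#'
#' @param noise_floor Minimum reportable intensity (> 0).
#' @param is_positive_mz,is_negative_mz Internal-standard m/z per ion
#'   mode.
#' @param is_match_tol_da Da window used to locate the internal-standard
#'   feature.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(noise_floor = 500,
                              is_positive_mz = 235.1805,
                              is_negative_mz = 231.0697,
                              is_match_tol_da = 0.01) {
  stopifnot(noise_floor > 0, is_match_tol_da > 0,
            is_positive_mz > 0, is_negative_mz > 0)
  structure(list(noise_floor = noise_floor,
                 is_positive_mz = is_positive_mz,
                 is_negative_mz = is_negative_mz,
                 is_match_tol_da = is_match_tol_da),
            class = "preprocess_config")
}

#' Floor intensities at the noise level
#'
#' Every intensity below the noise floor, and every missing cell,
#' becomes exactly the noise floor; all other values are unchanged.
#' Idempotent.
#'
#' @param table A `feature_table`.
#' @param config A [preprocess_config()].
#' @return Floored `feature_table` (with `floored = TRUE`).
#' @export
floor_noise <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "preprocess_config"))
  m <- table$intensities
  m[is.na(m) | m < config$noise_floor] <- config$noise_floor
  table$intensities <- m
  table$floored <- TRUE
  table$noise_floor <- config$noise_floor
  table
}

# Locate the internal-standard feature of one ion mode by m/z match.
.find_is_feature <- function(table, mode, target_mz, tol) {
  f <- table$features
  cand <- which(f$ion_mode == mode & abs(f$mz - target_mz) <= tol)
  if (length(cand) == 0) {
    stop("no internal-standard feature found in ", mode,
         " mode within ", tol, " Da of m/z ", target_mz, call. = FALSE)
  }
  if (length(cand) > 1) {
    totals <- rowSums(table$intensities[cand, , drop = FALSE], na.rm = TRUE)
    keep <- cand[which.max(totals)]
    message("multiple internal-standard candidates in ", mode,
            " mode (", paste(f$id[cand], collapse = ", "),
            "); keeping most intense: ", f$id[keep])
    cand <- keep
  }
  cand
}

#' Divide intensities by the per-sample internal standard
#'
#' Within each ion mode, every sample column is divided by that
#' sample's internal-standard intensity in the same mode, so the
#' internal standard's own normalized value is 1 in every sample. The
#' pre-normalization matrix is retained (`raw_intensities`) so that
#' thresholds stated in raw intensity units (e.g. twice the noise
#' level) can still be evaluated. Re-normalizing an already normalized
#' table is refused.
#'
#' @param table A floored `feature_table`.
#' @param config A [preprocess_config()].
#' @return Normalized `feature_table` (with `normalized = TRUE` and
#'   `is_info` recording the internal-standard feature ids and
#'   per-sample intensities).
#' @export
normalize_internal_standard <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "preprocess_config"))
  if (table$normalized) {
    stop("table is already internal-standard normalized; ",
         "refusing to normalize twice", call. = FALSE)
  }
  if (!table$floored) {
    stop("floor_noise() must be applied before normalization", call. = FALSE)
  }
  m <- table$intensities
  modes_present <- intersect(c("positive", "negative"),
                             unique(table$features$ion_mode))
  is_rows <- list()
  for (mode in modes_present) {
    target <- if (mode == "positive") config$is_positive_mz else config$is_negative_mz
    row <- .find_is_feature(table, mode, target, config$is_match_tol_da)
    is_int <- m[row, ]
    at_floor <- is_int <= table$noise_floor
    if (any(at_floor)) {
      warning("internal standard at the noise floor in sample(s): ",
              paste(colnames(m)[at_floor], collapse = ", "),
              " (", mode, " mode)", call. = FALSE)
    }
    rows_mode <- which(table$features$ion_mode == mode)
    m[rows_mode, ] <- sweep(m[rows_mode, , drop = FALSE], 2, is_int, "/")
    is_rows[[mode]] <- list(id = table$features$id[row], intensities = is_int)
  }
  table$raw_intensities <- table$intensities
  table$intensities <- m
  table$normalized <- TRUE
  table$is_info <- is_rows
  table
}
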