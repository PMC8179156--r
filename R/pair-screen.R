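# Isotopologue pair screen: detect (unlabeled, labeled) feature pairs
# produced by heavy-label tracer feeding.
#
# Four criteria, applied per ion mode:
#   1. intensity  - some (treatment, time) group mean exceeds twice the
#                   noise level (strict), for both pair members;
#   2. mass shift - m/z difference matches the incorporation of an
#                   allowed number of label atoms within a ppm tolerance
#                   of the query (lighter member's) m/z;
#   3. co-elution - retention times agree within a tolerance (inclusive);
#   4. treatment  - the unlabeled member attains its highest group mean
#                   under the unlabeled tracer and the labeled member
#                   under the labeled tracer.

#' Screening configuration
#'
#' Defaults are the deuterium screen parameters: threshold at 2x the
#' noise floor of 500, the printed deuterium shift table, +/- 20 ppm
#' mass tolerance scaled to the query m/z, and +/- 0.05 min co-elution
#' tolerance.
#'
#' @param noise_floor Noise floor in raw intensity units.
#' @param intensity_multiplier Criterion-1 multiplier of the noise floor.
#' @param shift_spec A [label_shift_spec()]; default [deuterium_shift()].
#' @param delta_ppm_tol Mass-difference tolerance in ppm of the query m/z.
#' @param rt_tol_min Retention-time tolerance in minutes (inclusive).
#' @param use_normalized Evaluate criterion 1 on normalized intensities
#'   instead of the raw floored matrix. The default keeps the threshold
#'   in raw units because the noise level is stated in raw units.
#' @param treatment_max `"group_mean"` (default) evaluates criterion 4
#'   and the co-behavior extremum criterion on group means;
#'   `"sample_max"` on individual samples.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(noise_floor = 500, intensity_multiplier = 2,
                          shift_spec = deuterium_shift(),
                          delta_ppm_tol = 20, rt_tol_min = 0.05,
                          use_normalized = FALSE,
                          treatment_max = c("group_mean", "sample_max")) {
  treatment_max <- match.arg(treatment_max)
  stopifnot(noise_floor > 0, intensity_multiplier > 0, delta_ppm_tol > 0,
            rt_tol_min > 0, inherits(shift_spec, "label_shift_spec"))
  structure(list(noise_floor = noise_floor,
                 intensity_multiplier = intensity_multiplier,
                 shift_spec = shift_spec, delta_ppm_tol = delta_ppm_tol,
                 rt_tol_min = rt_tol_min, use_normalized = use_normalized,
                 treatment_max = treatment_max),
            class = "screen_config")
}

# Matrix criterion 1 is evaluated on: raw floored values when available
# and requested, otherwise the table's current intensities.
.criterion1_matrix <- function(table, config) {
  if (!config$use_normalized && !is.null(table$raw_intensities)) {
    table$raw_intensities
  } else {
    table$intensities
  }
}

#' Criterion 1: group-mean intensity above twice the noise level
#'
#' A feature passes when the maximum over (treatment, time point) group
#' means is strictly greater than
#' `intensity_multiplier * noise_floor`.
#'
#' @param table A floored `feature_table`.
#' @param config A [screen_config()].
#' @return Named logical vector over all features.
#' @export
criterion_intensity <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$floored) stop("table must be floored first", call. = FALSE)
  gm <- group_means(table, .criterion1_matrix(table, config))
  out <- apply(gm, 1, max) > config$intensity_multiplier * config$noise_floor
  stats::setNames(as.logical(out), table$features$id)
}

# Per-feature extremum over group means (or samples, in "sample_max"
# mode): which treatments attain the extreme value. A tie across
# treatments (e.g. a floored/flat profile, tied in every group
# including controls) disqualifies because the extremum then does not
# belong to one treatment class; a tie within the qualifying
# treatment(s) is fine.
.group_extreme <- function(table, config, which = c("max", "min")) {
  which <- match.arg(which)
  if (config$treatment_max == "sample_max") {
    m <- table$intensities
    treat <- table$design$treatment
  } else {
    m <- group_means(table)
    treat <- attr(m, "groups")$treatment
  }
  ext <- if (which == "max") apply(m, 1, max) else apply(m, 1, min)
  at <- m == ext  # features x columns: attains the extremum
  att <- vapply(.TREATMENTS, function(tr) {
    rowSums(at[, treat == tr, drop = FALSE]) > 0
  }, logical(nrow(m)))
  if (nrow(m) == 1L) att <- matrix(att, nrow = 1,
                                   dimnames = list(NULL, .TREATMENTS))
  data.frame(
    id = table$features$id,
    all_unlabeled = att[, "unlabeled_tracer"] & !att[, "control"] &
      !att[, "labeled_tracer"],
    all_labeled = att[, "labeled_tracer"] & !att[, "control"] &
      !att[, "unlabeled_tracer"],
    all_tracer = (att[, "unlabeled_tracer"] | att[, "labeled_tracer"]) &
      !att[, "control"],
    stringsAsFactors = FALSE
  )
}

#' Criterion 2: mass difference matches a label shift
#'
#' Tests whether `mz_b - mz_a` matches `label_delta(spec, n)` for some
#' allowed count `n`, within `delta_ppm_tol` ppm of the query m/z
#' (`mz_a`, the lighter member). Vectorized over pairs.
#'
#' @param mz_a,mz_b m/z of the lighter and heavier feature
#'   (`mz_a < mz_b`).
#' @param config A [screen_config()].
#' @return data.frame with `pass`, `n_label` (smallest matching count,
#'   `NA` if none), `observed_delta` and `delta_ppm_error`.
#' @export
criterion_mass_shift <- function(mz_a, mz_b, config = screen_config()) {
  stopifnot(length(mz_a) == length(mz_b), all(mz_b > mz_a))
  spec <- config$shift_spec
  deltas <- vapply(spec$allowed_counts, function(n) label_delta(spec, n),
                   numeric(1))
  obs <- mz_b - mz_a
  tol <- config$delta_ppm_tol * 1e-6 * mz_a
  n_label <- rep(NA_integer_, length(obs))
  err_ppm <- rep(NA_real_, length(obs))
  for (k in seq_along(deltas)) {  # ascending counts: first hit is smallest n
    hit <- is.na(n_label) & abs(obs - deltas[k]) <= tol
    n_label[hit] <- spec$allowed_counts[k]
    err_ppm[hit] <- ppm_error(obs[hit], deltas[k], mz_a[hit])
  }
  data.frame(pass = !is.na(n_label), n_label = n_label,
             observed_delta = obs, delta_ppm_error = err_ppm)
}

#' Criterion 3: co-elution within the retention-time tolerance
#'
#' @param rt_a,rt_b Retention times in minutes.
#' @param config A [screen_config()].
#' @return Logical; `TRUE` when `|rt_a - rt_b| <= rt_tol_min`
#'   (boundary inclusive; a 1e-9 min guard keeps the boundary robust
#'   to floating-point representation of decimal retention times).
#' @export
criterion_coelution <- function(rt_a, rt_b, config = screen_config()) {
  abs(rt_a - rt_b) <= config$rt_tol_min + 1e-9
}

#' Criterion 4: members peak under their matching tracer treatment
#'
#' The unlabeled (lighter) member must attain its maximal group mean
#' only in unlabeled-tracer groups and the labeled member only in
#' labeled-tracer groups (any time point). A maximum tied with a group
#' of any other treatment disqualifies (a floored/flat profile ties
#' everywhere and is noise).
#'
#' @param table A floored `feature_table`.
#' @param unlabeled_id,labeled_id Feature ids of the pair members.
#' @param config A [screen_config()].
#' @return Logical vector over pairs.
#' @export
criterion_treatment_max <- function(table, unlabeled_id, labeled_id,
                                    config = screen_config()) {
  ext <- .group_extreme(table, config, "max")
  ia <- match(unlabeled_id, ext$id)
  ib <- match(labeled_id, ext$id)
  ext$all_unlabeled[ia] & ext$all_labeled[ib]
}

#' Screen a feature table for isotopologue pairs
#'
#' Applies criteria 1-4 per ion mode and returns every (unlabeled,
#' labeled) candidate pair, ordered by ion mode, unlabeled m/z, then
#' labeled m/z. A feature may belong to several candidate pairs;
#' de-duplication across adduct forms is the job of
#' [consolidate_pairs()]. The attribute `"screen_log"` tallies
#' rejections per criterion.
#'
#' @param table A floored (optionally normalized) `feature_table`.
#' @param config A [screen_config()].
#' @return data.frame of pair candidates: `unlabeled_id`, `labeled_id`,
#'   `n_label`, `observed_delta`, `delta_ppm_error`, `rt_diff`,
#'   `ion_mode`, `unlabeled_mz`, `labeled_mz`, `rt`,
#'   `unlabeled_max_intensity`, `labeled_max_intensity`.
#' @export
screen_pairs <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$floored) stop("table must be floored first", call. = FALSE)
  pass1 <- criterion_intensity(table, config)
  gm_cur <- group_means(table)
  max_cur <- apply(gm_cur, 1, max)
  spec <- config$shift_spec
  deltas <- vapply(spec$allowed_counts, function(n) label_delta(spec, n),
                   numeric(1))

  log <- list(n_features = nrow(table$features),
              n_fail_criterion1 = sum(!pass1),
              n_candidates_mass = 0L, n_fail_rt = 0L,
              n_fail_treatment_max = 0L, n_pairs = 0L)
  out <- list()
  for (mode in intersect(c("positive", "negative"),
                         unique(table$features$ion_mode))) {
    fidx <- which(table$features$ion_mode == mode & pass1)
    if (length(fidx) < 2) next
    f <- table$features[fidx, , drop = FALSE]
    ord <- order(f$mz)
    f <- f[ord, , drop = FALSE]
    fidx <- fidx[ord]
    mz <- f$mz
    # windowed candidate search: for each query feature and allowed
    # count, locate heavier partners whose m/z lies in the tolerance
    # window around mz + delta
    ia <- integer(0); ib <- integer(0)
    for (k in seq_along(deltas)) {
      tol <- config$delta_ppm_tol * 1e-6 * mz
      lo <- findInterval(mz + deltas[k] - tol, mz)
      hi <- findInterval(mz + deltas[k] + tol, mz)
      n_hit <- hi - lo
      has <- which(n_hit > 0)
      if (length(has) == 0) next
      ia <- c(ia, rep(has, n_hit[has]))
      ib <- c(ib, unlist(lapply(has, function(i) seq(lo[i] + 1L, hi[i]))))
    }
    if (length(ia) == 0) next
    keep <- !duplicated(cbind(ia, ib)) & ib != ia
    ia <- ia[keep]; ib <- ib[keep]
    ms <- criterion_mass_shift(mz[ia], mz[ib], config)
    log$n_candidates_mass <- log$n_candidates_mass + sum(ms$pass)
    ok <- ms$pass
    rt_ok <- criterion_coelution(f$rt[ia], f$rt[ib], config)
    log$n_fail_rt <- log$n_fail_rt + sum(ok & !rt_ok)
    ok <- ok & rt_ok
    tm_ok <- criterion_treatment_max(table, f$id[ia], f$id[ib], config)
    log$n_fail_treatment_max <- log$n_fail_treatment_max + sum(ok & !tm_ok)
    ok <- ok & tm_ok
    if (!any(ok)) next
    sel <- which(ok)
    out[[mode]] <- data.frame(
      unlabeled_id = f$id[ia[sel]], labeled_id = f$id[ib[sel]],
      n_label = ms$n_label[sel], observed_delta = ms$observed_delta[sel],
      delta_ppm_error = ms$delta_ppm_error[sel],
      rt_diff = f$rt[ib[sel]] - f$rt[ia[sel]],
      ion_mode = mode,
      unlabeled_mz = mz[ia[sel]], labeled_mz = mz[ib[sel]],
      rt = f$rt[ia[sel]],
      unlabeled_max_intensity = max_cur[fidx[ia[sel]]],
      labeled_max_intensity = max_cur[fidx[ib[sel]]],
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) == 0) {
    data.frame(unlabeled_id = character(0), labeled_id = character(0),
               n_label = integer(0), observed_delta = numeric(0),
               delta_ppm_error = numeric(0), rt_diff = numeric(0),
               ion_mode = character(0), unlabeled_mz = numeric(0),
               labeled_mz = numeric(0), rt = numeric(0),
               unlabeled_max_intensity = numeric(0),
               labeled_max_intensity = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  res <- res[order(match(res$ion_mode, .ION_MODES), res$unlabeled_mz,
                   res$labeled_mz), , drop = FALSE]
  rownames(res) <- NULL
  log$n_pairs <- nrow(res)
  attr(res, "screen_log") <- log
  res
}
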