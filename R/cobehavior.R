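# Co-behavior screen: features whose abundance responds to both tracer
# treatments in the same manner regardless of the label (criteria 1, 5
# and 6).

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (average-rank tie handling),
#' delegated to [stats::cor()]. A constant input vector has no defined
#' rank correlation and raises an error rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

# Threshold clause of criterion 6: tracer-tracer correlation strictly
# above `high`, both control correlations at or below `low`.
.cobehavior_thresholds_ok <- function(rho_tracers, rho_control_unlabeled,
                                      rho_control_labeled,
                                      thresholds = list(high = 0.4, low = 0.2)) {
  rho_tracers > thresholds$high &
    rho_control_unlabeled <= thresholds$low &
    rho_control_labeled <= thresholds$low
}

#' Criterion 5: extremum attained under a tracer treatment
#'
#' A feature passes when its global maximum or global minimum of group
#' means is attained only in tracer groups (unlabeled or labeled; a
#' tie between the two tracer treatments still qualifies, a tie
#' involving a control group does not). The direction records which
#' extremum qualified; when both do, the maximum takes precedence.
#'
#' @param table A floored `feature_table`.
#' @param config A [screen_config()].
#' @return data.frame over features: `id`, `pass`, `direction`
#'   (`"max_in_tracer"`, `"min_in_tracer"` or `NA`).
#' @export
criterion_extremum <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$floored) stop("table must be floored first", call. = FALSE)
  mx <- .group_extreme(table, config, "max")
  mn <- .group_extreme(table, config, "min")
  max_ok <- mx$all_tracer
  min_ok <- mn$all_tracer
  direction <- ifelse(max_ok, "max_in_tracer",
                      ifelse(min_ok, "min_in_tracer", NA_character_))
  data.frame(id = table$features$id, pass = max_ok | min_ok,
             direction = direction, stringsAsFactors = FALSE)
}

#' Screen a feature table for tracer co-behaving features
#'
#' Applies criteria 1, 5 and 6. Criterion 6 correlates replicate-level
#' intensity vectors between treatments, with samples matched
#' positionally by (time point, replicate); with the standard 3 x 4 x 3
#' design these are 12-point vectors. Four-point group-mean vectors are
#' available via `vector_mode = "group_mean"`, but a rank correlation
#' on so few points takes only coarse values. Features with a constant
#' vector in any treatment have no defined rank correlation and are
#' rejected; constancy is assessed on pre-normalization (floored)
#' intensities when available, because a feature flat at the noise
#' floor carries no rank information of its own - any variation that
#' appears after internal-standard division is the standard's noise,
#' not the feature's.
#'
#' @param table A floored (optionally normalized) `feature_table` with
#'   a complete design (same time x replicate layout per treatment).
#' @param thresholds List with `high` (tracer-tracer correlation must
#'   be strictly greater) and `low` (both control correlations must be
#'   at or below); defaults 0.4 and 0.2.
#' @param config A [screen_config()] (criterion 1 and extremum
#'   settings).
#' @param vector_mode `"replicate"` (default) or `"group_mean"`.
#' @return data.frame of passing features: `feature_id`, `ion_mode`,
#'   `direction`, `rho_tracers`, `rho_control_unlabeled`,
#'   `rho_control_labeled`, `mz`, `rt`, `max_intensity`; ordered by
#'   ion mode then m/z. Attribute `"screen_log"` tallies rejections.
#' @export
screen_cobehavior <- function(table, thresholds = list(high = 0.4, low = 0.2),
                              config = screen_config(),
                              vector_mode = c("replicate", "group_mean")) {
  stopifnot(inherits(table, "feature_table"))
  vector_mode <- match.arg(vector_mode)
  if (!table$floored) stop("table must be floored first", call. = FALSE)
  pass1 <- criterion_intensity(table, config)
  ext <- criterion_extremum(table, config)
  cand <- which(pass1 & ext$pass)
  log <- list(n_features = nrow(table$features),
              n_fail_criterion1 = sum(!pass1),
              n_fail_extremum = sum(pass1 & !ext$pass),
              n_constant_vector = 0L, n_fail_correlation = 0L,
              n_records = 0L)

  raw <- if (!is.null(table$raw_intensities)) table$raw_intensities else
    table$intensities
  if (vector_mode == "replicate") {
    ids_by_tr <- .samples_by_treatment(table)
    vecs <- lapply(ids_by_tr, function(s) {
      table$intensities[, s, drop = FALSE]
    })
    raw_vecs <- lapply(ids_by_tr, function(s) raw[, s, drop = FALSE])
  } else {
    gm <- group_means(table)
    groups <- attr(gm, "groups")
    gm_raw <- group_means(table, raw)
    mk <- function(g) {
      lapply(.TREATMENTS, function(tr) {
        sel <- which(groups$treatment == tr)
        sel <- sel[order(groups$time_h[sel])]
        g[, sel, drop = FALSE]
      })
    }
    vecs <- stats::setNames(mk(gm), .TREATMENTS)
    raw_vecs <- stats::setNames(mk(gm_raw), .TREATMENTS)
  }

  rows <- list()
  for (i in cand) {
    xc <- vecs[["control"]][i, ]
    xu <- vecs[["unlabeled_tracer"]][i, ]
    xl <- vecs[["labeled_tracer"]][i, ]
    constant_raw <- any(vapply(raw_vecs, function(v) {
      min(v[i, ]) == max(v[i, ])
    }, logical(1)))
    if (constant_raw ||
        min(xc) == max(xc) || min(xu) == max(xu) || min(xl) == max(xl)) {
      log$n_constant_vector <- log$n_constant_vector + 1L
      next
    }
    rho_t <- spearman_rho(xu, xl)
    rho_cu <- spearman_rho(xc, xu)
    rho_cl <- spearman_rho(xc, xl)
    if (.cobehavior_thresholds_ok(rho_t, rho_cu, rho_cl, thresholds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = table$features$id[i],
        ion_mode = table$features$ion_mode[i],
        direction = ext$direction[i],
        rho_tracers = rho_t, rho_control_unlabeled = rho_cu,
        rho_control_labeled = rho_cl,
        mz = table$features$mz[i], rt = table$features$rt[i],
        stringsAsFactors = FALSE
      )
    } else {
      log$n_fail_correlation <- log$n_fail_correlation + 1L
    }
  }
  res <- if (length(rows) == 0) {
    data.frame(feature_id = character(0), ion_mode = character(0),
               direction = character(0), rho_tracers = numeric(0),
               rho_control_unlabeled = numeric(0),
               rho_control_labeled = numeric(0), mz = numeric(0),
               rt = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  gm_cur <- group_means(table)
  res$max_intensity <- apply(gm_cur, 1, max)[match(res$feature_id,
                                                   table$features$id)]
  res <- res[order(match(res$ion_mode, .ION_MODES), res$mz), , drop = FALSE]
  rownames(res) <- NULL
  log$n_records <- nrow(res)
  attr(res, "screen_log") <- log
  res
}
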