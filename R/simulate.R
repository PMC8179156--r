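# Seeded synthetic feature-table generator with planted ground truth.
#
# Emulates the statistical structure of a tracer-feeding untargeted
# metabolomics experiment: 3 treatments (control, unlabeled tracer,
# labeled tracer) x 4 time points (3, 9, 24, 48 h) x 3 replicates, two
# ion modes, a noise floor of 500, internal-standard channels, planted
# isotopologue pairs with deuterium mass shifts, planted co-behaving
# features and decoy classes that each violate exactly one screening
# criterion.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions: 1,200 positive-
#' and 800 negative-mode features, 20 planted isotopologue pairs,
#' 15 co-behaving features (8 up, 7 down) and 200 decoys (100
#' ppm-near-miss, 50 retention-time-miss, 50 control-max), on the
#' 3 treatment x 4 time point x 3 replicate design.
#'
#' Planted pairs draw their observed mass shift uniformly within half
#' the screen's ppm tolerance of the configured label shift, so they
#' are recoverable by construction; decoy shifts are offset by 2-4x
#' the tolerance and are never recoverable. Contradictory settings
#' (decoy jitter inside the screen tolerance, planted jitter beyond
#' it) are refused.
#'
#' @param seed Integer RNG seed.
#' @param n_features Named vector: number of features per ion mode.
#' @param n_planted_pairs Number of (unlabeled, labeled) pairs planted
#'   across modes.
#' @param n_cobehaving_up,n_cobehaving_down Number of co-behaving
#'   features accumulating (up) or transiently depleted (down) under
#'   both tracer treatments.
#' @param n_decoys Named vector of decoy counts per class:
#'   `ppm_near_miss`, `rt_miss`, `control_max`.
#' @param time_points_h,n_replicates Design layout.
#' @param noise_floor Noise floor in intensity units.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline
#'   intensity of background features.
#' @param profile_noise_sd Multiplicative (log-scale) noise sd of
#'   background features.
#' @param planted_noise_sd Multiplicative noise sd of planted profiles.
#' @param shift_spec Label shift specification ([deuterium_shift()]).
#' @param delta_ppm_tol,rt_tol_min Screen tolerances the generator
#'   plants against.
#' @param pair_delta_ppm_jitter Max |mass-shift jitter| of planted
#'   pairs in ppm; must be at most `delta_ppm_tol / 2`.
#' @param pair_rt_jitter_min Max |RT offset| between planted pair
#'   members; must be below `rt_tol_min`.
#' @param decoy_ppm_factor Range (in multiples of the ppm tolerance)
#'   of the mass-shift offset of ppm-near-miss decoys; lower bound
#'   must be >= 2.
#' @param decoy_rt_range_min Range of the RT offset of rt-miss decoys;
#'   lower bound must be >= 2x `rt_tol_min`.
#' @param missing_rate Fraction of background cells recorded as
#'   missing.
#' @param is_mz Internal-standard m/z per mode.
#' @param is_log_mean,is_log_sd Internal-standard intensity
#'   distribution (log scale).
#' @param mz_range,rt_range Ranges features are drawn from.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_features = c(positive = 1200, negative = 800),
                              n_planted_pairs = 20,
                              n_cobehaving_up = 8, n_cobehaving_down = 7,
                              n_decoys = c(ppm_near_miss = 100, rt_miss = 50,
                                           control_max = 50),
                              time_points_h = c(3, 9, 24, 48),
                              n_replicates = 3,
                              noise_floor = 500,
                              baseline_log_mean = log(5000),
                              baseline_log_sd = 0.8,
                              profile_noise_sd = 0.25,
                              planted_noise_sd = 0.15,
                              shift_spec = deuterium_shift(),
                              delta_ppm_tol = 20, rt_tol_min = 0.05,
                              pair_delta_ppm_jitter = 10,
                              pair_rt_jitter_min = 0.02,
                              decoy_ppm_factor = c(2, 4),
                              decoy_rt_range_min = c(0.2, 0.5),
                              missing_rate = 0.02,
                              is_mz = c(positive = 235.1805,
                                        negative = 231.0697),
                              is_log_mean = log(5e4), is_log_sd = 0.02,
                              mz_range = c(100, 1000), rt_range = c(0.5, 12)) {
  cfg <- list(seed = as.integer(seed), n_features = n_features,
              n_planted_pairs = n_planted_pairs,
              n_cobehaving_up = n_cobehaving_up,
              n_cobehaving_down = n_cobehaving_down,
              n_decoys = n_decoys, time_points_h = time_points_h,
              n_replicates = n_replicates, noise_floor = noise_floor,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              profile_noise_sd = profile_noise_sd,
              planted_noise_sd = planted_noise_sd,
              shift_spec = shift_spec, delta_ppm_tol = delta_ppm_tol,
              rt_tol_min = rt_tol_min,
              pair_delta_ppm_jitter = pair_delta_ppm_jitter,
              pair_rt_jitter_min = pair_rt_jitter_min,
              decoy_ppm_factor = decoy_ppm_factor,
              decoy_rt_range_min = decoy_rt_range_min,
              missing_rate = missing_rate, is_mz = is_mz,
              is_log_mean = is_log_mean, is_log_sd = is_log_sd,
              mz_range = mz_range, rt_range = rt_range)
  stopifnot(all(c("positive", "negative") %in% names(cfg$n_features)),
            all(cfg$n_features >= 0), cfg$n_planted_pairs >= 0,
            cfg$n_cobehaving_up >= 0, cfg$n_cobehaving_down >= 0,
            all(c("ppm_near_miss", "rt_miss", "control_max") %in%
                  names(cfg$n_decoys)),
            all(cfg$n_decoys >= 0), cfg$n_replicates >= 1,
            cfg$noise_floor > 0, cfg$missing_rate >= 0,
            cfg$missing_rate < 1,
            inherits(cfg$shift_spec, "label_shift_spec"))
  if (cfg$pair_delta_ppm_jitter > cfg$delta_ppm_tol / 2) {
    stop("contradictory config: planted mass-shift jitter exceeds half ",
         "the screen tolerance", call. = FALSE)
  }
  if (cfg$pair_rt_jitter_min >= cfg$rt_tol_min) {
    stop("contradictory config: planted RT jitter is not inside the ",
         "co-elution tolerance", call. = FALSE)
  }
  if (cfg$decoy_ppm_factor[1] < 2) {
    stop("contradictory config: ppm-near-miss decoy offset must be at ",
         "least 2x the screen tolerance", call. = FALSE)
  }
  if (cfg$decoy_rt_range_min[1] < 2 * cfg$rt_tol_min) {
    stop("contradictory config: rt-miss decoy offset must be at least ",
         "2x the co-elution tolerance", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Largest-count-first proportional split of a total across ion modes.
.split_by_mode <- function(total, n_features) {
  w <- n_features / sum(n_features)
  pos <- round(total * w[["positive"]])
  c(positive = pos, negative = total - pos)
}

#' Generate a synthetic tracer-feeding feature table
#'
#' Deterministic for a fixed seed. Planted labeled features rise above
#' the noise floor only in labeled-tracer samples and their unlabeled
#' partners only in unlabeled-tracer samples; co-behaving features
#' share a time profile across both tracer treatments (accumulation,
#' or a transient dip at 9 h) while control samples drift mildly in
#' the opposite direction; background features are
#' treatment-independent. Background noise draws are resampled when a
#' random fluctuation would let a background feature satisfy the
#' co-behavior correlation clause, and feature m/z values are placed
#' so that no unintended co-eluting pair falls near a label mass
#' shift: the emitted ground truth is exact, not probabilistic.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a [feature_table()]) and `truth`, a list
#'   of data.frames: `pairs` (`unlabeled_id`, `labeled_id`, `n_label`,
#'   `ion_mode`), `cobehaving` (`feature_id`, `direction`,
#'   `ion_mode`), `decoys` (`unlabeled_id`, `labeled_id`, `class`,
#'   `ion_mode`).
#' @export
simulate_feature_table <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  treatments <- .TREATMENTS
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        time_h = config$time_points_h,
                        treatment = treatments,
                        stringsAsFactors = FALSE)
  design <- design[, c("treatment", "time_h", "replicate")]
  design$sample_id <- sprintf("S%02d", seq_len(nrow(design)))
  design$batch <- paste0("B", design$replicate)
  design <- design[, c("sample_id", "treatment", "time_h", "replicate",
                       "batch")]
  ns <- nrow(design)
  tidx <- match(design$time_h, config$time_points_h)
  ntp <- length(config$time_points_h)

  # per-treatment sample indices ordered by (time, replicate), for the
  # correlation guard
  ord_idx <- lapply(treatments, function(tr) {
    i <- which(design$treatment == tr)
    i[order(design$time_h[i], design$replicate[i])]
  })
  names(ord_idx) <- treatments

  spec <- config$shift_spec
  deltas <- vapply(spec$allowed_counts, function(n) label_delta(spec, n),
                   numeric(1))

  n_pair <- .split_by_mode(config$n_planted_pairs, config$n_features)
  n_up <- .split_by_mode(config$n_cobehaving_up, config$n_features)
  n_down <- .split_by_mode(config$n_cobehaving_down, config$n_features)
  n_dec <- lapply(names(config$n_decoys), function(cl) {
    .split_by_mode(config$n_decoys[[cl]], config$n_features)
  })
  names(n_dec) <- names(config$n_decoys)

  pair_shapes <- list(c(1, 3, 10, 6),   # transient peak at 24 h
                      c(1, 2, 5, 10),   # late accumulation
                      c(2, 10, 5, 2))   # early transient
  up_shape <- c(1, 2, 5, 12)
  up_ctrl <- c(1.3, 1.2, 1.1, 1.0)
  down_shape <- c(1, 0.2, 0.7, 0.95)
  down_ctrl <- c(0.9, 1.2, 1.1, 1.0)
  stopifnot(ntp == 4L)  # planted profile shapes assume the 4-point design

  sub_floor <- function(n) stats::runif(n, 0.2, 0.8) * config$noise_floor
  pnoise <- function(n, sd = config$planted_noise_sd) exp(stats::rnorm(n, 0, sd))

  # guard: TRUE when the row, floored (and, once the mode's internal
  # standard exists, also IS-normalized), could satisfy the co-behavior
  # correlation clause too easily (tracer-tracer rank correlation above
  # a conservative 0.2 margin)
  rho_tracers_of <- function(r) {
    xu <- r[ord_idx$unlabeled_tracer]
    xl <- r[ord_idx$labeled_tracer]
    if (min(xu) == max(xu) || min(xl) == max(xl)) return(-Inf)
    stats::cor(xu, xl, method = "spearman")
  }
  coherent_by_chance <- function(row, is_row = NULL) {
    r <- row
    r[is.na(r)] <- config$noise_floor
    r <- pmax(r, config$noise_floor)
    if (rho_tracers_of(r) > 0.2) return(TRUE)
    if (!is.null(is_row)) return(rho_tracers_of(r / is_row) > 0.2)
    FALSE
  }

  gt_pairs <- list(); gt_cobe <- list(); gt_decoys <- list()
  tables <- list()

  for (mode in c("positive", "negative")) {
    n_feat <- config$n_features[[mode]]
    if (n_feat == 0) next
    n_special <- 1L + 2L * (n_pair[[mode]] + sum(vapply(n_dec, function(x)
      x[[mode]], numeric(1)))) + n_up[[mode]] + n_down[[mode]]
    if (n_special > n_feat) {
      stop("n_features[", mode, "] too small for the planted structure (",
           n_special, " needed)", call. = FALSE)
    }
    prefix <- if (mode == "positive") "P" else "N"
    mzs <- numeric(0); rts <- numeric(0)
    rows <- list()

    # m/z placement hygiene: refuse an m/z that would create an
    # unintended label-shift window with any co-eluting feature
    conflicts <- function(mz, rt, exempt = integer(0)) {
      if (length(mzs) == 0) return(FALSE)
      keep <- setdiff(seq_along(mzs), exempt)
      if (length(keep) == 0) return(FALSE)
      near <- keep[abs(rts[keep] - rt) <= 4 * config$rt_tol_min]
      if (length(near) == 0) return(FALSE)
      dmz <- abs(mzs[near] - mz)
      margin <- 3 * config$delta_ppm_tol * 1e-6 * config$mz_range[2]
      any(vapply(deltas, function(d) any(abs(dmz - d) <= margin),
                 logical(1)))
    }
    commit <- function(mz, rt) {
      mzs[length(mzs) + 1L] <<- mz
      rts[length(rts) + 1L] <<- rt
      length(mzs)
    }
    place <- function(rt) {
      for (try in 1:1000) {
        mz <- stats::runif(1, config$mz_range[1], config$mz_range[2])
        if (!conflicts(mz, rt)) return(commit(mz, rt))
      }
      stop("m/z placement failed after 1000 tries; feature space too dense",
           call. = FALSE)
    }
    # place two partner features atomically: both members must clear the
    # hygiene check against all previously committed features; on any
    # conflict the whole pair geometry is redrawn
    place_pair <- function(geometry) {
      for (try in 1:1000) {
        g <- geometry()
        if (!conflicts(g$mz_a, g$rt_a) && !conflicts(g$mz_b, g$rt_b)) {
          return(list(ia = commit(g$mz_a, g$rt_a),
                      ib = commit(g$mz_b, g$rt_b)))
        }
      }
      stop("pair placement failed after 1000 tries; feature space too dense",
           call. = FALSE)
    }
    draw_rt <- function() stats::runif(1, config$rt_range[1], config$rt_range[2])

    # internal standard: near-constant channel at the configured m/z
    is_idx <- commit(config$is_mz[[mode]], mean(config$rt_range))
    repeat {
      row <- exp(stats::rnorm(ns, config$is_log_mean, config$is_log_sd))
      if (!coherent_by_chance(row)) break
    }
    rows[[is_idx]] <- row

    tracer_profile_row <- function(amp, shape, target_treatment) {
      row <- sub_floor(ns)
      sel <- which(design$treatment == target_treatment)
      row[sel] <- amp * shape[tidx[sel]] * pnoise(length(sel))
      row
    }

    # planted isotopologue pairs
    for (p in seq_len(n_pair[[mode]])) {
      n_lab <- spec$allowed_counts[1L + (p - 1L) %% length(spec$allowed_counts)]
      pl <- place_pair(function() {
        rt_a <- draw_rt()
        mz_a <- stats::runif(1, config$mz_range[1], config$mz_range[2])
        jit <- stats::runif(1, -1, 1) * config$pair_delta_ppm_jitter * 1e-6 * mz_a
        list(mz_a = mz_a, rt_a = rt_a,
             mz_b = mz_a + label_delta(spec, n_lab) + jit,
             rt_b = rt_a + stats::runif(1, -1, 1) * config$pair_rt_jitter_min)
      })
      ia <- pl$ia; ib <- pl$ib
      amp <- stats::rlnorm(1, log(40 * config$noise_floor), 0.4)
      shape <- pair_shapes[[1L + (p - 1L) %% length(pair_shapes)]]
      rows[[ia]] <- tracer_profile_row(amp, shape, "unlabeled_tracer")
      rows[[ib]] <- tracer_profile_row(amp, shape, "labeled_tracer")
      gt_pairs[[length(gt_pairs) + 1L]] <- data.frame(
        unlabeled_id = sprintf("%s%04d", prefix, ia),
        labeled_id = sprintf("%s%04d", prefix, ib),
        n_label = n_lab, ion_mode = mode, stringsAsFactors = FALSE)
    }

    # decoys: each class breaks exactly one criterion
    for (cl in names(config$n_decoys)) {
      for (d in seq_len(n_dec[[cl]][[mode]])) {
        n_lab <- spec$allowed_counts[1L + (d - 1L) %% length(spec$allowed_counts)]
        delta <- label_delta(spec, n_lab)
        pl <- place_pair(function() {
          rt_a <- draw_rt()
          mz_a <- stats::runif(1, config$mz_range[1], config$mz_range[2])
          tol_da <- config$delta_ppm_tol * 1e-6 * mz_a
          if (cl == "ppm_near_miss") {
            off <- sample(c(-1, 1), 1) *
              stats::runif(1, config$decoy_ppm_factor[1],
                           config$decoy_ppm_factor[2]) * tol_da
            rt_b <- rt_a + stats::runif(1, -1, 1) * config$pair_rt_jitter_min
          } else if (cl == "rt_miss") {
            off <- stats::runif(1, -1, 1) * config$pair_delta_ppm_jitter *
              1e-6 * mz_a
            rt_b <- rt_a + sample(c(-1, 1), 1) *
              stats::runif(1, config$decoy_rt_range_min[1],
                           config$decoy_rt_range_min[2])
            rt_b <- min(max(rt_b, 0), config$rt_range[2] + 1)
          } else {  # control_max
            off <- stats::runif(1, -1, 1) * config$pair_delta_ppm_jitter *
              1e-6 * mz_a
            rt_b <- rt_a + stats::runif(1, -1, 1) * config$pair_rt_jitter_min
          }
          list(mz_a = mz_a, rt_a = rt_a, mz_b = mz_a + delta + off,
               rt_b = rt_b)
        })
        ia <- pl$ia; ib <- pl$ib
        amp <- stats::rlnorm(1, log(40 * config$noise_floor), 0.4)
        shape <- pair_shapes[[1L + (d - 1L) %% length(pair_shapes)]]
        rows[[ia]] <- tracer_profile_row(amp, shape, "unlabeled_tracer")
        rows[[ib]] <- tracer_profile_row(
          amp, shape,
          if (cl == "control_max") "control" else "labeled_tracer")
        gt_decoys[[length(gt_decoys) + 1L]] <- data.frame(
          unlabeled_id = sprintf("%s%04d", prefix, ia),
          labeled_id = sprintf("%s%04d", prefix, ib),
          class = cl, ion_mode = mode, stringsAsFactors = FALSE)
      }
    }

    # planted co-behaving features: shared profile under both tracers,
    # mild opposite drift in controls
    cobe_row <- function(direction) {
      if (direction == "up") {
        shape <- up_shape; cshape <- up_ctrl; camp_factor <- 0.5
      } else {
        shape <- down_shape; cshape <- down_ctrl; camp_factor <- 1.3
      }
      for (try in 1:100) {
        amp <- stats::rlnorm(1, log(16 * config$noise_floor), 0.2)
        row <- numeric(ns)
        for (tr in c("unlabeled_tracer", "labeled_tracer")) {
          sel <- which(design$treatment == tr)
          row[sel] <- amp * shape[tidx[sel]] * pnoise(length(sel))
        }
        selc <- which(design$treatment == "control")
        row[selc] <- camp_factor * amp * cshape[tidx[selc]] *
          pnoise(length(selc), 0.05)
        margins_ok <- function(r) {
          xu <- r[ord_idx$unlabeled_tracer]
          xl <- r[ord_idx$labeled_tracer]
          xc <- r[ord_idx$control]
          stats::cor(xu, xl, method = "spearman") > 0.5 &&
            stats::cor(xc, xu, method = "spearman") < 0.1 &&
            stats::cor(xc, xl, method = "spearman") < 0.1
        }
        if (margins_ok(row) && margins_ok(row / rows[[is_idx]])) return(row)
      }
      stop("could not realize a planted co-behaving profile", call. = FALSE)
    }
    for (u in seq_len(n_up[[mode]])) {
      i <- place(draw_rt())
      rows[[i]] <- cobe_row("up")
      gt_cobe[[length(gt_cobe) + 1L]] <- data.frame(
        feature_id = sprintf("%s%04d", prefix, i),
        direction = "max_in_tracer", ion_mode = mode,
        stringsAsFactors = FALSE)
    }
    for (dn in seq_len(n_down[[mode]])) {
      i <- place(draw_rt())
      rows[[i]] <- cobe_row("down")
      gt_cobe[[length(gt_cobe) + 1L]] <- data.frame(
        feature_id = sprintf("%s%04d", prefix, i),
        direction = "min_in_tracer", ion_mode = mode,
        stringsAsFactors = FALSE)
    }

    # treatment-independent background
    n_bg <- n_feat - length(mzs)
    for (b in seq_len(n_bg)) {
      i <- place(draw_rt())
      base <- stats::rlnorm(1, config$baseline_log_mean, config$baseline_log_sd)
      for (try in 1:100) {
        row <- base * exp(stats::rnorm(ns, 0, config$profile_noise_sd))
        if (config$missing_rate > 0) {
          row[stats::runif(ns) < config$missing_rate] <- NA_real_
        }
        if (!coherent_by_chance(row, rows[[is_idx]])) break
      }
      rows[[i]] <- row
    }

    tables[[mode]] <- list(
      features = data.frame(id = sprintf("%s%04d", prefix, seq_along(mzs)),
                            mz = mzs, rt = rts, ion_mode = mode,
                            stringsAsFactors = FALSE),
      intensities = do.call(rbind, rows)
    )
  }

  features <- do.call(rbind, lapply(tables, `[[`, "features"))
  intensities <- do.call(rbind, lapply(tables, `[[`, "intensities"))
  rownames(features) <- NULL
  table <- feature_table(features, design, intensities)

  bind_or_empty <- function(lst, cols) {
    if (length(lst) > 0) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else {
      as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                    cols), stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    pairs = bind_or_empty(gt_pairs, c("unlabeled_id", "labeled_id",
                                      "n_label", "ion_mode")),
    cobehaving = bind_or_empty(gt_cobe, c("feature_id", "direction",
                                          "ion_mode")),
    decoys = bind_or_empty(gt_decoys, c("unlabeled_id", "labeled_id",
                                        "class", "ion_mode"))
  )
  list(table = table, truth = truth)
}

#' Write a simulation (matrix, design and ground truth) to CSV
#'
#' @param sim Output of [simulate_feature_table()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.csv"),
             design = file.path(dir, "design.csv"),
             pairs = file.path(dir, "truth_pairs.csv"),
             cobehaving = file.path(dir, "truth_cobehaving.csv"),
             decoys = file.path(dir, "truth_decoys.csv"))
  write_feature_table(sim$table, paths[["matrix"]], paths[["design"]])
  utils::write.csv(sim$truth$pairs, paths[["pairs"]], row.names = FALSE)
  utils::write.csv(sim$truth$cobehaving, paths[["cobehaving"]],
                   row.names = FALSE)
  utils::write.csv(sim$truth$decoys, paths[["decoys"]], row.names = FALSE)
  invisible(paths)
}
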