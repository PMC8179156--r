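# Shared fixtures and independent brute-force oracles.

# Minimal complete design: 3 treatments x `times` x `reps` replicates.
make_design <- function(times = c(3, 9, 24, 48), reps = 3) {
  d <- expand.grid(replicate = seq_len(reps), time_h = times,
                   treatment = c("control", "unlabeled_tracer",
                                 "labeled_tracer"),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("S%02d", seq_len(nrow(d))),
             treatment = d$treatment, time_h = d$time_h,
             replicate = d$replicate, batch = "B1",
             stringsAsFactors = FALSE)
}

# Hand-built feature table: `profiles` is a list of per-feature
# functions(treatment, time_h) -> mean intensity; replicate values are
# that mean exactly (no noise) unless `jitter` is supplied.
make_table <- function(mz, rt, ion_mode, profiles,
                       design = make_design(), jitter = NULL) {
  n <- length(mz)
  ids <- sprintf("F%02d", seq_len(n))
  m <- matrix(0, n, nrow(design))
  for (i in seq_len(n)) {
    m[i, ] <- mapply(profiles[[i]], design$treatment, design$time_h)
  }
  if (!is.null(jitter)) m <- m * jitter
  feature_table(
    data.frame(id = ids, mz = mz, rt = rt, ion_mode = ion_mode,
               stringsAsFactors = FALSE),
    design, m)
}

flat_profile <- function(level) function(treatment, time_h) level

peak_profile <- function(target_treatment, level, base = 500) {
  function(treatment, time_h) if (treatment == target_treatment) level else base
}

# O(n^2) reference enumeration of the pair screen: checks every ordered
# feature pair against all four criteria individually, with no shared
# code path with screen_pairs() beyond the exported single-pair
# criterion helpers' definitions re-derived here.
brute_force_pairs <- function(table, config = screen_config()) {
  stopifnot(table$floored)
  f <- table$features
  spec <- config$shift_spec
  deltas <- vapply(spec$allowed_counts, function(n) label_delta(spec, n),
                   numeric(1))
  m <- if (!config$use_normalized && !is.null(table$raw_intensities)) {
    table$raw_intensities
  } else table$intensities
  gm_raw <- group_means(table, m)
  pass1 <- apply(gm_raw, 1, max) > config$intensity_multiplier * config$noise_floor
  gm_cur <- group_means(table)
  groups <- attr(gm_cur, "groups")
  u_only <- logical(nrow(f)); l_only <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    at_tr <- unique(groups$treatment[gm_cur[i, ] == max(gm_cur[i, ])])
    u_only[i] <- identical(at_tr, "unlabeled_tracer")
    l_only[i] <- identical(at_tr, "labeled_tracer")
  }
  out <- list()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(f))) {
      if (i == j || f$mz[j] <= f$mz[i]) next
      if (f$ion_mode[i] != f$ion_mode[j]) next
      if (!pass1[i] || !pass1[j]) next
      obs <- f$mz[j] - f$mz[i]
      tol <- config$delta_ppm_tol * 1e-6 * f$mz[i]
      hits <- which(abs(obs - deltas) <= tol)
      if (length(hits) == 0) next
      if (abs(f$rt[i] - f$rt[j]) > config$rt_tol_min + 1e-9) next
      if (!(u_only[i] && l_only[j])) next
      out[[length(out) + 1L]] <- data.frame(
        unlabeled_id = f$id[i], labeled_id = f$id[j],
        n_label = spec$allowed_counts[hits[1]], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(unlabeled_id = character(0), labeled_id = character(0),
                      n_label = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Vectorized variant of the same O(n^2) enumeration (full cross tables
# of all feature pairs), usable at the full simulation scale.
brute_force_pairs_outer <- function(table, config = screen_config()) {
  stopifnot(table$floored)
  f <- table$features
  spec <- config$shift_spec
  deltas <- vapply(spec$allowed_counts, function(n) label_delta(spec, n),
                   numeric(1))
  m <- if (!config$use_normalized && !is.null(table$raw_intensities)) {
    table$raw_intensities
  } else table$intensities
  gm_raw <- group_means(table, m)
  pass1 <- apply(gm_raw, 1, max) > config$intensity_multiplier * config$noise_floor
  gm_cur <- group_means(table)
  groups <- attr(gm_cur, "groups")
  at <- gm_cur == apply(gm_cur, 1, max)
  att <- sapply(c("control", "unlabeled_tracer", "labeled_tracer"),
                function(tr) rowSums(at[, groups$treatment == tr,
                                        drop = FALSE]) > 0)
  u_ok <- att[, "unlabeled_tracer"] & !att[, "control"] & !att[, "labeled_tracer"]
  l_ok <- att[, "labeled_tracer"] & !att[, "control"] & !att[, "unlabeled_tracer"]
  out <- list()
  for (mode in unique(f$ion_mode)) {
    idx <- which(f$ion_mode == mode)
    mz <- f$mz[idx]; rt <- f$rt[idx]
    D <- -outer(mz, mz, "-")            # D[i, j] = mz[j] - mz[i]
    tol <- 20e-6 * mz                   # per query row
    hit <- matrix(FALSE, length(idx), length(idx))
    nmat <- matrix(NA_integer_, length(idx), length(idx))
    for (k in rev(seq_along(deltas))) { # ascending counts win on overlap
      h <- abs(D - deltas[k]) <= config$delta_ppm_tol * 1e-6 * mz
      hit <- hit | h
      nmat[h] <- spec$allowed_counts[k]
    }
    ok <- hit & outer(mz, mz, "<") &
      (abs(outer(rt, rt, "-")) <= config$rt_tol_min + 1e-9) &
      outer(pass1[idx], pass1[idx], function(a, b) a & b) &
      outer(u_ok[idx], l_ok[idx], function(a, b) a & b)
    w <- which(ok, arr.ind = TRUE)
    if (nrow(w) > 0) {
      out[[mode]] <- data.frame(unlabeled_id = f$id[idx[w[, 1]]],
                                labeled_id = f$id[idx[w[, 2]]],
                                n_label = nmat[w],
                                stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(unlabeled_id = character(0), labeled_id = character(0),
                      n_label = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Direct per-feature loop for the co-behavior screen, with the rank
# correlation computed from first principles as Pearson on average
# ranks.
rank_pearson <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

brute_force_cobehavior <- function(table, thresholds = list(high = 0.4, low = 0.2),
                                   config = screen_config()) {
  stopifnot(table$floored)
  d <- table$design
  ord <- function(tr) {
    i <- which(d$treatment == tr)
    d$sample_id[i][order(d$time_h[i], d$replicate[i])]
  }
  sc <- ord("control"); su <- ord("unlabeled_tracer"); sl <- ord("labeled_tracer")
  m_raw <- if (!config$use_normalized && !is.null(table$raw_intensities)) {
    table$raw_intensities
  } else table$intensities
  gm_raw <- group_means(table, m_raw)
  gm_cur <- group_means(table)
  groups <- attr(gm_cur, "groups")
  tracers <- c("unlabeled_tracer", "labeled_tracer")
  keep <- character(0)
  for (i in seq_len(nrow(table$features))) {
    if (!(max(gm_raw[i, ]) > config$intensity_multiplier * config$noise_floor)) next
    mx_tr <- unique(groups$treatment[gm_cur[i, ] == max(gm_cur[i, ])])
    mn_tr <- unique(groups$treatment[gm_cur[i, ] == min(gm_cur[i, ])])
    max_ok <- all(mx_tr %in% tracers)
    min_ok <- all(mn_tr %in% tracers)
    if (!max_ok && !min_ok) next
    rc <- m_raw[i, sc]; ru <- m_raw[i, su]; rl <- m_raw[i, sl]
    if (min(rc) == max(rc) || min(ru) == max(ru) || min(rl) == max(rl)) next
    xc <- table$intensities[i, sc]; xu <- table$intensities[i, su]
    xl <- table$intensities[i, sl]
    if (min(xc) == max(xc) || min(xu) == max(xu) || min(xl) == max(xl)) next
    if (rank_pearson(xu, xl) > thresholds$high &&
        rank_pearson(xc, xu) <= thresholds$low &&
        rank_pearson(xc, xl) <= thresholds$low) {
      keep <- c(keep, table$features$id[i])
    }
  }
  keep
}

# Small simulation for module-level tests (fast; full scale is used in
# the acceptance suite).
small_sim_config <- function(seed = 42) {
  simulation_config(
    seed = seed,
    n_features = c(positive = 150, negative = 100),
    n_planted_pairs = 6, n_cobehaving_up = 3, n_cobehaving_down = 2,
    n_decoys = c(ppm_near_miss = 6, rt_miss = 4, control_max = 4)
  )
}

pair_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$unlabeled_id, df$labeled_id))
}
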