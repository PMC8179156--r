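# The synthetic generator: determinism, structure, ground-truth
# guarantees and config validation.

test_that("the same seed reproduces the table exactly", {
  a <- simulate_feature_table(small_sim_config(seed = 3))
  b <- simulate_feature_table(small_sim_config(seed = 3))
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$table$features, b$table$features)
  expect_identical(a$truth, b$truth)
  c <- simulate_feature_table(small_sim_config(seed = 4))
  expect_false(identical(a$table$intensities, c$table$intensities))
})

test_that("the generated table is valid and structured as configured", {
  cfg <- small_sim_config(seed = 8)
  sim <- simulate_feature_table(cfg)
  tab <- sim$table
  expect_s3_class(tab, "feature_table")
  expect_equal(sum(tab$features$ion_mode == "positive"),
               unname(cfg$n_features[["positive"]]))
  expect_equal(sum(tab$features$ion_mode == "negative"),
               unname(cfg$n_features[["negative"]]))
  expect_equal(nrow(tab$design), 3 * 4 * 3)
  # internal standards exist at the configured m/z in both modes
  for (mode in c("positive", "negative")) {
    expect_true(any(tab$features$ion_mode == mode &
                      abs(tab$features$mz - cfg$is_mz[[mode]]) < 1e-9))
  }
  # ground-truth ids exist in the table and classes are disjoint
  ids <- tab$features$id
  expect_true(all(unlist(sim$truth$pairs[, 1:2]) %in% ids))
  expect_true(all(sim$truth$cobehaving$feature_id %in% ids))
  expect_true(all(unlist(sim$truth$decoys[, 1:2]) %in% ids))
  planted <- c(unlist(sim$truth$pairs[, 1:2]),
               sim$truth$cobehaving$feature_id,
               unlist(sim$truth$decoys[, 1:2]))
  expect_false(anyDuplicated(planted) > 0)
})

test_that("planted pair geometry respects the screen tolerances; decoys break them", {
  sim <- simulate_feature_table(small_sim_config(seed = 15))
  f <- sim$table$features
  spec <- deuterium_shift()
  for (i in seq_len(nrow(sim$truth$pairs))) {
    p <- sim$truth$pairs[i, ]
    mza <- f$mz[f$id == p$unlabeled_id]; mzb <- f$mz[f$id == p$labeled_id]
    expect_lte(abs((mzb - mza) - label_delta(spec, p$n_label)),
               10e-6 * mza)  # within half the 20 ppm tolerance
    expect_lt(abs(f$rt[f$id == p$labeled_id] - f$rt[f$id == p$unlabeled_id]),
              0.05)
  }
  dec <- sim$truth$decoys
  for (i in seq_len(nrow(dec))) {
    mza <- f$mz[f$id == dec$unlabeled_id[i]]
    mzb <- f$mz[f$id == dec$labeled_id[i]]
    rta <- f$rt[f$id == dec$unlabeled_id[i]]
    rtb <- f$rt[f$id == dec$labeled_id[i]]
    err <- min(abs((mzb - mza) -
                     vapply(spec$allowed_counts, function(n)
                       label_delta(spec, n), numeric(1))))
    if (dec$class[i] == "ppm_near_miss") {
      expect_gte(err, 2 * 20e-6 * mza)  # never recoverable
    } else if (dec$class[i] == "rt_miss") {
      expect_gt(abs(rtb - rta), 0.1)
    }
  }
})

test_that("zero planted structure yields empty screens", {
  cfg <- simulation_config(seed = 2,
                           n_features = c(positive = 60, negative = 40),
                           n_planted_pairs = 0, n_cobehaving_up = 0,
                           n_cobehaving_down = 0,
                           n_decoys = c(ppm_near_miss = 0, rt_miss = 0,
                                        control_max = 0))
  sim <- simulate_feature_table(cfg)
  fl <- floor_noise(sim$table)
  expect_equal(nrow(screen_pairs(fl)), 0)
  expect_equal(nrow(screen_cobehavior(fl)), 0)
})

test_that("with zero jitter recovery is exactly 100%", {
  cfg <- small_sim_config(seed = 6)
  cfg$pair_delta_ppm_jitter <- 0
  cfg$pair_rt_jitter_min <- 0
  cfg$missing_rate <- 0
  sim <- simulate_feature_table(cfg)
  fl <- floor_noise(sim$table)
  expect_setequal(pair_key(screen_pairs(fl)), pair_key(sim$truth$pairs))
})

test_that("contradictory configurations are refused", {
  expect_error(simulation_config(pair_delta_ppm_jitter = 15),
               "contradictory")
  expect_error(simulation_config(pair_rt_jitter_min = 0.05),
               "contradictory")
  expect_error(simulation_config(decoy_ppm_factor = c(1, 4)),
               "contradictory")
  expect_error(simulation_config(decoy_rt_range_min = c(0.05, 0.5)),
               "contradictory")
})

test_that("written simulation round-trips through the readers", {
  sim <- simulate_feature_table(
    simulation_config(seed = 12, n_features = c(positive = 40, negative = 30),
                      n_planted_pairs = 2, n_cobehaving_up = 1,
                      n_cobehaving_down = 1,
                      n_decoys = c(ppm_near_miss = 2, rt_miss = 1,
                                   control_max = 1)))
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  back <- read_feature_table(paths[["matrix"]], paths[["design"]])
  expect_equal(back$features, sim$table$features)
  expect_identical(back$intensities, sim$table$intensities)
  truth_pairs <- utils::read.csv(paths[["pairs"]], stringsAsFactors = FALSE)
  expect_equal(truth_pairs, sim$truth$pairs)
})
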