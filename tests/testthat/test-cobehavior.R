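# Spearman correlation, the extremum criterion and the co-behavior
# screen.

test_that("spearman_rho matches Pearson on average ranks, including ties", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  expect_equal(spearman_rho(x, y), 1)
  expect_equal(spearman_rho(x, rev(y)), -1)
  set.seed(2)
  for (i in 1:20) {
    a <- sample(1:5, 12, replace = TRUE)  # heavy ties
    b <- sample(1:5, 12, replace = TRUE)
    if (min(a) == max(a) || min(b) == max(b)) next
    expect_equal(spearman_rho(a, b), rank_pearson(a, b))
  }
  expect_error(spearman_rho(rep(1, 5), x[1:5]), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("extremum criterion recognizes tracer maxima and minima", {
  rise <- function(treatment, time_h) {  # accumulation under both tracers
    if (treatment == "control") 900 else 500 + 100 * time_h
  }
  dip <- function(treatment, time_h) {   # transient dip at 9 h
    if (treatment == "control") 3000
    else if (time_h == 9) 600 else 2500
  }
  ctrl <- function(treatment, time_h) {  # extremes both in control
    if (treatment == "control") ifelse(time_h == 3, 9000, 200) else 2000
  }
  tab <- make_table(mz = c(100, 200, 300), rt = 1:3,
                    ion_mode = rep("negative", 3),
                    profiles = list(rise, dip, ctrl))
  ext <- criterion_extremum(floor_noise(tab))
  expect_true(ext$pass[1]); expect_equal(ext$direction[1], "max_in_tracer")
  expect_true(ext$pass[2]); expect_equal(ext$direction[2], "min_in_tracer")
  expect_false(ext$pass[3])
})

test_that("screen equals a direct per-feature loop and recovers planted truth", {
  sim <- simulate_feature_table(small_sim_config(seed = 21))
  fl <- normalize_internal_standard(floor_noise(sim$table))
  got <- screen_cobehavior(fl)
  expect_setequal(got$feature_id, sim$truth$cobehaving$feature_id)
  expect_setequal(got$feature_id, brute_force_cobehavior(fl))
  # directions match the planted profile shapes
  m <- merge(got, sim$truth$cobehaving, by = "feature_id")
  expect_equal(m$direction.x, m$direction.y)
  # output is a subset of criterion-1 passers with honored thresholds
  p1 <- criterion_intensity(fl)
  expect_true(all(p1[got$feature_id]))
  expect_true(all(got$rho_tracers > 0.4))
  expect_true(all(got$rho_control_unlabeled <= 0.2))
  expect_true(all(got$rho_control_labeled <= 0.2))
})

test_that("group-mean vector mode still recovers the planted features", {
  sim <- simulate_feature_table(small_sim_config(seed = 33))
  fl <- floor_noise(sim$table)
  got <- screen_cobehavior(fl, vector_mode = "group_mean")
  # planted profiles are strong enough to survive 4-point vectors;
  # precision is not guaranteed in this mode (a 4-point rank
  # correlation takes only coarse values)
  expect_true(all(sim$truth$cobehaving$feature_id %in% got$feature_id))
})

test_that("incomplete designs are refused for vector pairing", {
  tab <- make_table(mz = 100, rt = 1, ion_mode = "positive",
                    profiles = list(flat_profile(2000)))
  short <- tab$design[-1, ]  # drop one control replicate
  tab2 <- feature_table(tab$features, short,
                        tab$intensities[, short$sample_id, drop = FALSE])
  expect_error(screen_cobehavior(floor_noise(tab2)), "incomplete design")
})

test_that("an empty table yields an empty record list", {
  tab <- make_table(mz = 100, rt = 1, ion_mode = "positive",
                    profiles = list(flat_profile(400)))
  expect_equal(nrow(screen_cobehavior(floor_noise(tab))), 0)
})
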