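# The four pair-screen criteria and the full screen against the
# brute-force enumeration.

test_that("intensity criterion is a strict threshold on group means", {
  tab <- make_table(mz = c(100, 110, 120), rt = c(1, 2, 3),
                    ion_mode = rep("positive", 3),
                    profiles = list(
                      flat_profile(400),                       # floors to 500
                      peak_profile("unlabeled_tracer", 1000),  # mean exactly 1000
                      peak_profile("unlabeled_tracer", 1001)))
  fl <- floor_noise(tab)
  p <- criterion_intensity(fl)
  expect_false(p[["F01"]])  # all at floor
  expect_false(p[["F02"]])  # "more than" is strict
  expect_true(p[["F03"]])
  expect_error(criterion_intensity(tab), "floored")
})

test_that("mass-shift criterion matches the printed shifts within 20 ppm of the query", {
  # the worked conjugate pair: delta 5.0310 vs printed 5.0314 at query 485
  ms <- criterion_mass_shift(485.1184, 490.1494)
  expect_true(ms$pass)
  expect_equal(ms$n_label, 5L)
  # far off: no count matches
  expect_false(criterion_mass_shift(300, 304.9)$pass)
  # randomized pairs against a direct loop over (count, tolerance)
  set.seed(1)
  cfg <- screen_config()
  deltas <- vapply(c(2L, 3L, 5L, 10L), function(n)
    label_delta(cfg$shift_spec, n), numeric(1))
  mz_a <- runif(300, 100, 900)
  mz_b <- mz_a + sample(c(deltas, 2.5, 5.2), 300, replace = TRUE) +
    runif(300, -1, 1) * 30e-6 * mz_a
  got <- criterion_mass_shift(mz_a, mz_b, cfg)
  for (i in seq_len(300)) {
    hits <- which(abs((mz_b[i] - mz_a[i]) - deltas) <= 20e-6 * mz_a[i])
    expect_equal(got$pass[i], length(hits) > 0)
    if (length(hits) > 0) expect_equal(got$n_label[i], c(2L, 3L, 5L, 10L)[hits[1]])
  }
})

test_that("co-elution tolerance is boundary inclusive", {
  expect_true(criterion_coelution(2.741, 2.741))
  expect_true(criterion_coelution(1.00, 1.05))
  expect_false(criterion_coelution(1.00, 1.051))
})

test_that("treatment-maximum criterion requires a unique argmax per member", {
  mk <- function(prof_a, prof_b) {
    tab <- make_table(mz = c(100, 105.0314), rt = c(1, 1),
                      ion_mode = c("positive", "positive"),
                      profiles = list(prof_a, prof_b))
    floor_noise(tab)
  }
  peak_at <- function(tr, t, level = 5000) function(treatment, time_h) {
    if (treatment == tr && time_h == t) level else 500
  }
  # textbook pattern: A peaks under 4MSB, B under the labeled tracer
  fl <- mk(peak_at("unlabeled_tracer", 24), peak_at("labeled_tracer", 24))
  expect_true(criterion_treatment_max(fl, "F01", "F02"))
  # labeled member peaking in control disqualifies
  fl2 <- mk(peak_at("unlabeled_tracer", 24), peak_at("control", 24))
  expect_false(criterion_treatment_max(fl2, "F01", "F02"))
  # an exact tie between a tracer group and control disqualifies
  tie <- function(treatment, time_h) {
    if (time_h == 24 && treatment %in% c("unlabeled_tracer", "control"))
      5000 else 500
  }
  fl3 <- mk(tie, peak_at("labeled_tracer", 24))
  expect_false(criterion_treatment_max(fl3, "F01", "F02"))
})

test_that("screen equals the brute-force enumeration and honors ground truth", {
  sim <- simulate_feature_table(small_sim_config(seed = 5))
  fl <- normalize_internal_standard(floor_noise(sim$table))
  pairs <- screen_pairs(fl)
  expect_setequal(pair_key(pairs), pair_key(sim$truth$pairs))
  expect_setequal(pair_key(pairs), pair_key(brute_force_pairs(fl)))
  # no decoy pair survives
  expect_length(intersect(pair_key(pairs), pair_key(sim$truth$decoys)), 0)
  # reported n_label agrees with truth
  m <- merge(pairs, sim$truth$pairs, by = c("unlabeled_id", "labeled_id"))
  expect_equal(m$n_label.x, m$n_label.y)
  # every reported candidate re-passes all four criteria individually
  p1 <- criterion_intensity(fl)
  for (i in seq_len(nrow(pairs))) {
    expect_true(p1[[pairs$unlabeled_id[i]]] && p1[[pairs$labeled_id[i]]])
    expect_true(criterion_mass_shift(pairs$unlabeled_mz[i],
                                     pairs$labeled_mz[i])$pass)
    expect_true(criterion_coelution(0, pairs$rt_diff[i]))
    expect_true(criterion_treatment_max(fl, pairs$unlabeled_id[i],
                                        pairs$labeled_id[i]))
  }
})

test_that("screen output is invariant under feature-row permutation", {
  sim <- simulate_feature_table(small_sim_config(seed = 9))
  fl <- floor_noise(sim$table)
  pairs <- screen_pairs(fl)
  set.seed(1)
  perm <- sample(nrow(fl$features))
  tab2 <- feature_table(fl$features[perm, ], fl$design,
                        fl$intensities[perm, , drop = FALSE])
  pairs2 <- screen_pairs(floor_noise(tab2))
  expect_identical(pairs2[, names(pairs2) != "rt"],
                   pairs[, names(pairs) != "rt"])
})

test_that("relaxing tolerances never removes a pair", {
  sim <- simulate_feature_table(small_sim_config(seed = 13))
  fl <- floor_noise(sim$table)
  strict <- screen_pairs(fl, screen_config())
  loose <- screen_pairs(fl, screen_config(delta_ppm_tol = 40,
                                          rt_tol_min = 0.1))
  expect_true(all(pair_key(strict) %in% pair_key(loose)))
})

test_that("an empty table yields an empty pair list", {
  tab <- make_table(mz = 100, rt = 1, ion_mode = "positive",
                    profiles = list(flat_profile(400)))
  expect_equal(nrow(screen_pairs(floor_noise(tab))), 0)
})
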