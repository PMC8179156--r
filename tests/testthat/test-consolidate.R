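# Neutral-mass hypotheses and cross-mode consolidation.

test_that("neutral hypotheses invert the three adduct forms", {
  h <- neutral_hypotheses(485.1193, "positive")
  expect_setequal(h$adduct, c("[M+H]+", "[2M+H]+"))
  expect_equal(h$neutral_mass[h$adduct == "[M+H]+"], 484.1120,
               tolerance = 1e-4)
  h2 <- neutral_hypotheses(969.2313, "positive")
  expect_equal(h2$neutral_mass[h2$adduct == "[2M+H]+"], 484.1120,
               tolerance = 1e-4)
  h3 <- neutral_hypotheses(483.1047, "negative")
  expect_equal(h3$adduct, "[M-H]-")
  expect_equal(h3$neutral_mass, 484.1120, tolerance = 1e-4)
})

# one metabolite observed as [M+H]+, [2M+H]+ and [M-H]- plus an
# unrelated singleton
adduct_trio_entries <- function(rt = 2.7) {
  M <- monoisotopic_mass("C16H28N4O7S3")
  data.frame(
    id = c("pos1", "pos2", "neg1", "lone"),
    mz = c(adduct_mz("C16H28N4O7S3", "[M+H]+"),
           adduct_mz("C16H28N4O7S3", "[2M+H]+"),
           adduct_mz("C16H28N4O7S3", "[M-H]-"),
           333.3),
    rt = c(rt, rt + 0.01, rt - 0.02, rt),
    ion_mode = c("positive", "positive", "negative", "positive"),
    max_intensity = c(9000, 2000, 5000, 800),
    stringsAsFactors = FALSE)
}

test_that("adduct forms of one metabolite merge; the representative is the most intense", {
  out <- consolidate_records(adduct_trio_entries())
  expect_equal(nrow(out), 2)
  trio <- out[out$n_members == 3, ]
  expect_equal(nrow(trio), 1)
  expect_setequal(trio$members[[1]], c("pos1", "pos2", "neg1"))
  expect_equal(trio$representative_id, "pos1")
  lone <- out[out$n_members == 1, ]
  expect_equal(lone$representative_id, "lone")
})

test_that("RT gating blocks mass-compatible merges", {
  e <- adduct_trio_entries()
  e$rt[3] <- e$rt[1] + 3  # same neutral mass, far in RT
  out <- consolidate_records(e)
  expect_equal(sort(out$n_members), c(1, 1, 2))
})

test_that("disjoint entries map to one record each", {
  e <- data.frame(id = c("a", "b", "c"), mz = c(101.1, 202.2, 303.3),
                  rt = c(1, 2, 3), ion_mode = "positive",
                  max_intensity = c(1, 2, 3), stringsAsFactors = FALSE)
  out <- consolidate_records(e)
  expect_equal(nrow(out), 3)
  expect_true(all(out$n_members == 1))
})

test_that("consolidation is idempotent and conserves members", {
  e <- adduct_trio_entries()
  out1 <- consolidate_records(e)
  expect_equal(sum(out1$n_members), nrow(e))
  # re-consolidating the representatives changes nothing structurally
  reps <- data.frame(id = out1$representative_id, mz = out1$mz, rt = out1$rt,
                     ion_mode = out1$ion_mode,
                     max_intensity = out1$max_intensity,
                     stringsAsFactors = FALSE)
  out2 <- consolidate_records(reps)
  expect_equal(nrow(out2), nrow(out1))
  expect_equal(sort(out2$representative_id), sort(out1$representative_id))
})

test_that("input order does not change the consolidation", {
  e <- adduct_trio_entries()
  out1 <- consolidate_records(e)
  set.seed(4)
  e2 <- e[sample(nrow(e)), ]
  out2 <- consolidate_records(e2)
  expect_equal(out2$representative_id, out1$representative_id)
  expect_equal(lapply(out2$members, sort), lapply(out1$members, sort))
})

test_that("pair consolidation keeps the most intense pair per metabolite", {
  pairs <- data.frame(
    unlabeled_id = c("u1", "u2"), labeled_id = c("l1", "l2"),
    n_label = 5L, observed_delta = 5.0314, delta_ppm_error = 1,
    rt_diff = 0, ion_mode = c("positive", "negative"),
    unlabeled_mz = c(adduct_mz("C16H28N4O7S3", "[M+H]+"),
                     adduct_mz("C16H28N4O7S3", "[M-H]-")),
    labeled_mz = c(adduct_mz("C16H28N4O7S3", "[M+H]+") + 5.0314,
                   adduct_mz("C16H28N4O7S3", "[M-H]-") + 5.0314),
    rt = c(2.74, 2.75),
    unlabeled_max_intensity = c(9000, 3000),
    labeled_max_intensity = c(8000, 2500), stringsAsFactors = FALSE)
  out <- consolidate_pairs(pairs)
  expect_equal(nrow(out), 1)
  expect_equal(out$representative_id, "u1")
  expect_equal(out$labeled_id, "l1")
  expect_setequal(out$members[[1]], c("u1", "u2"))
})
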