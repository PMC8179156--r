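# Data model, CSV round trip, group means.

test_that("feature_table validates its invariants", {
  d <- make_design()
  f <- data.frame(id = c("a", "b"), mz = c(100, 200), rt = c(1, 2),
                  ion_mode = "positive", stringsAsFactors = FALSE)
  m <- matrix(1000, 2, nrow(d))
  expect_s3_class(feature_table(f, d, m), "feature_table")
  expect_error(feature_table(f, d, m[, 1:10]), "dimensions")
  expect_error(feature_table(f, d, -m), "negative")
  f2 <- f; f2$id <- c("a", "a")
  expect_error(feature_table(f2, d, m), "duplicate feature ids")
  f3 <- f; f3$ion_mode <- "both"
  expect_error(feature_table(f3, d, m), "ion_mode")
  d2 <- d; d2$replicate[2] <- d2$replicate[1]; d2$time_h[2] <- d2$time_h[1]
  expect_error(feature_table(f, d2, m), "unique")
})

test_that("read/write round trip preserves the table including missing cells", {
  tab <- make_table(mz = c(100.1, 205.2), rt = c(1.0, 2.0),
                    ion_mode = c("positive", "positive"),
                    profiles = list(flat_profile(1200), flat_profile(800)))
  tab$intensities[2, 5] <- NA
  mp <- tempfile(fileext = ".csv"); dp <- tempfile(fileext = ".csv")
  write_feature_table(tab, mp, dp)
  back <- read_feature_table(mp, dp)
  expect_equal(back$features, tab$features)
  expect_equal(back$design, tab$design)
  expect_identical(back$intensities, tab$intensities)
})

test_that("reader errors name the offending sample column and cell", {
  tab <- make_table(mz = 100, rt = 1, ion_mode = "positive",
                    profiles = list(flat_profile(1000)))
  mp <- tempfile(fileext = ".csv"); dp <- tempfile(fileext = ".csv")
  write_feature_table(tab, mp, dp)
  # drop one sample from the design file
  design <- utils::read.csv(dp)
  utils::write.csv(design[design$sample_id != "S13", ], dp, row.names = FALSE)
  expect_error(read_feature_table(mp, dp), "S13")
  # corrupt one intensity cell
  write_feature_table(tab, mp, dp)
  mat <- utils::read.csv(mp, check.names = FALSE)
  mat[1, "S03"] <- "oops"
  utils::write.csv(mat, mp, row.names = FALSE)
  expect_error(read_feature_table(mp, dp), "S03")
})

test_that("reader supports a configurable column mapping", {
  tab <- make_table(mz = 100, rt = 1, ion_mode = "positive",
                    profiles = list(flat_profile(1000)))
  mp <- tempfile(fileext = ".csv"); dp <- tempfile(fileext = ".csv")
  write_feature_table(tab, mp, dp)
  mat <- utils::read.csv(mp, check.names = FALSE)
  names(mat)[1:4] <- c("peak", "m.z", "RT_min", "polarity")
  utils::write.csv(mat, mp, row.names = FALSE)
  back <- read_feature_table(mp, dp,
                             col_map = c(id = "peak", mz = "m.z",
                                         rt = "RT_min", ion_mode = "polarity"))
  expect_equal(back$features, tab$features)
  expect_error(read_feature_table(mp, dp), "lacks column")
})

test_that("group means average replicates and ignore replicate order", {
  d <- make_design()
  prof <- function(treatment, time_h) {
    if (treatment == "control" && time_h == 3) 0 else 500
  }
  tab <- make_table(mz = 100, rt = 1, ion_mode = "positive",
                    profiles = list(prof), design = d)
  # hand-set distinct replicate values in one group
  sel <- which(d$treatment == "control" & d$time_h == 3)
  tab$intensities[1, sel] <- c(1000, 2000, 3000)
  gm <- group_means(tab)
  expect_equal(unname(gm[1, "control@3h"]), 2000)
  expect_equal(unname(gm[1, "unlabeled_tracer@9h"]), 500)
  # independent per-cell loop oracle
  groups <- attr(gm, "groups")
  for (g in seq_len(nrow(groups))) {
    cols <- which(d$treatment == groups$treatment[g] &
                    d$time_h == groups$time_h[g])
    acc <- 0
    for (s in cols) acc <- acc + tab$intensities[1, s]
    expect_equal(unname(gm[1, groups$key[g]]), acc / length(cols))
  }
  # permutation invariance over samples
  perm <- sample(nrow(d))
  tab2 <- feature_table(tab$features, d[perm, ],
                        tab$intensities[, perm, drop = FALSE])
  gm2 <- group_means(tab2)
  expect_equal(gm2[, colnames(gm), drop = FALSE], gm, ignore_attr = TRUE)
})
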