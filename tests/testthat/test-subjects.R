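make_subject_table <- function(defects, subjects = NULL) {
  n <- length(defects)
  subjects <- subjects %||% sprintf("s%02d", seq_len(n))
  df <- data.frame(subject = subjects, session = "T0",
                   age = 10, sex = "female", site = "site1",
                   defect_count = defects,
                   p1 = 2.5, p2 = 2.4, stringsAsFactors = FALSE)
  attr(df, "parcel_labels") <- c("p1", "p2")
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC threshold is Q3 + 1.5 IQR with linear-interpolation quantiles", {
  qc <- qc_filter(make_subject_table(c(1, 2, 3, 4)))
  expect_equal(qc$q3, 3.25)
  expect_equal(qc$iqr, 1.5)
  expect_equal(qc$threshold, 5.5)
  expect_identical(qc$n_excluded, 0L)
  # a flagrant outlier is excluded
  qc2 <- qc_filter(make_subject_table(c(1, 2, 3, 4, 100)))
  expect_false(qc2$keep_mask["s05"])
  expect_identical(qc2$n_excluded, 1L)
  # manual fail wins regardless of defect counts
  qc3 <- qc_filter(make_subject_table(c(0, 2, 3, 4)), manual_fail = "s01")
  expect_false(qc3$keep_mask["s01"])
  expect_error(qc_filter(make_subject_table(c(1, 2, 3))), ">= 4")
})

test_that("subject-level QC can exclude whole subjects or single sessions", {
  df <- rbind(make_subject_table(c(1, 2, 3, 4)),
              make_subject_table(100, subjects = "s01"))
  df$session[5] <- "T2"
  attr(df, "parcel_labels") <- c("p1", "p2")
  qc_sub <- qc_filter(df)  # any bad session drops the subject
  expect_false(qc_sub$keep_mask["s01"])
  qc_ses <- qc_filter(df, level = "session")
  expect_true(qc_ses$keep_mask["s01"])
  expect_identical(sum(!qc_ses$keep_rows), 1L)
})

test_that("per-subject change maps are relative to the first session", {
  sim <- fix_grid(40)
  g <- fix_geom(40)
  subs <- simulate_subjects(sim$grid, g, 6, sessions = c(T0 = 10, T2 = 12),
                            seed = 5)
  ch <- subject_changes(subs)
  expect_identical(nrow(ch), 6L)
  # identical sessions give zero change; global 5% scaling gives 0.05
  s2 <- subs
  parcels <- attr(subs, "parcel_labels")
  for (s in unique(s2$subject)) {
    i <- which(s2$subject == s & s2$session == "T0")
    j <- which(s2$subject == s & s2$session == "T2")
    s2[j, parcels] <- s2[i, parcels] * 1.05
  }
  ch2 <- subject_changes(s2)
  expect_equal(unname(as.matrix(ch2[, parcels])),
               matrix(0.05, 6, length(parcels)), tolerance = 1e-12)
  # missing session pairs are skipped with a message
  s3 <- subs[-2, ]
  attr(s3, "parcel_labels") <- parcels
  expect_message(ch3 <- subject_changes(s3), "skipped")
  expect_identical(nrow(ch3), 5L)
  # averaging order matters: mean of subject-wise deltas is the contract
  two <- subs[subs$subject %in% c("sub0001", "sub0002"), ]
  attr(two, "parcel_labels") <- parcels
  ch4 <- subject_changes(two)
  mean_of_delta <- colMeans(as.matrix(ch4[, parcels]))
  ct0 <- as.matrix(two[two$session == "T0", parcels])
  ct2 <- as.matrix(two[two$session == "T2", parcels])
  delta_of_mean <- (colMeans(ct2) - colMeans(ct0)) / colMeans(ct0)
  expect_false(isTRUE(all.equal(unname(mean_of_delta),
                                unname(delta_of_mean), tolerance = 1e-12)))
})

test_that("per-subject dominance inherits the sum identity", {
  sim <- fix_grid(40)
  g <- fix_geom(40)
  mk <- fix_markers(40)$markers
  subs <- simulate_subjects(sim$grid, g, 12, seed = 6)
  ch <- subject_changes(subs)
  tab <- subject_dominance_scan(ch, mk)
  for (s in unique(tab$subject)) {
    rows <- tab[tab$subject == s, ]
    expect_equal(sum(rows$r2[rows$marker != "full_model"]),
                 rows$r2[rows$marker == "full_model"], tolerance = 1e-10)
  }
  # all-identical subjects reproduce the cohort-average R2 exactly
  same <- ch
  parcels <- attr(ch, "parcel_labels")
  for (i in seq_len(nrow(same))) same[i, parcels] <- as.numeric(ch[1, parcels])
  attr(same, "parcel_labels") <- parcels
  tab2 <- subject_dominance_scan(same, mk)
  coh <- subject_dominance_scan(same, mk, cohort_average = TRUE)
  expect_equal(unique(tab2$r2[tab2$marker == "full_model"]), coh$full_r2,
               tolerance = 1e-10)
})

test_that("group null test counts exceedances and ignores subject order", {
  sim <- fix_grid(40, p = 6, n_active = 3, target_r2 = 0.5)
  g <- fix_geom(40)
  mk <- fix_markers(40)$markers
  ens <- fix_ensembles(40, 6, n = 50)
  subs <- simulate_subjects(sim$grid, g, 15, sessions = c(T0 = 10, T2 = 12),
                            subject_noise_sd = 0.02,
                            session_noise_sd = 0.002, seed = 7)
  ch <- subject_changes(subs)
  gt <- group_null_test(ch, mk, ens, n_null = 50)
  expect_true(gt$p_full >= 1 / 51 && gt$p_full <= 1)
  expect_length(gt$null_mean_full_r2, 50)
  expect_named(gt$p_markers, mk$marker_names)
  # planted colocalization beats every unstructured null
  expect_equal(gt$p_full, 1 / 51, tolerance = 1e-12)
  # subject order must not matter
  ch_rev <- ch[rev(seq_len(nrow(ch))), ]
  attr(ch_rev, "parcel_labels") <- attr(ch, "parcel_labels")
  gt2 <- group_null_test(ch_rev, mk, ens, n_null = 50)
  expect_equal(gt2$p_full, gt$p_full, tolerance = 1e-12)
  expect_equal(gt2$observed_mean_full_r2, gt$observed_mean_full_r2,
               tolerance = 1e-12)
  # the fast full-model-only path agrees with the subset path
  gt3 <- group_null_test(ch, mk, ens, n_null = 50, include_markers = FALSE)
  expect_equal(gt3$observed_mean_full_r2, gt$observed_mean_full_r2,
               tolerance = 1e-10)
  expect_equal(gt3$null_mean_full_r2, gt$null_mean_full_r2,
               tolerance = 1e-10)
  expect_error(group_null_test(ch, mk, ens, n_null = 500), "shorter")
  expect_error(group_null_test(ch[1, ], mk, ens, n_null = 10),
               ">= 2 subjects")
})
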