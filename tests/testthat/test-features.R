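test_that("features of a constant segment are (c, 0)", {
  rec <- fsr_recording(matrix(rep(c(0.2, 0.5, 0.8), each = 100), 100, 3),
                       200)
  segs <- data.frame(start_sample = 10L, end_sample = 90L, channel = 1L,
                     label = "rest")
  db <- extract_features(rec, segs)
  expect_equal(unname(unlist(db[1, 1:3])), c(0.2, 0.5, 0.8))
  expect_equal(unname(unlist(db[1, 4:6])), c(0, 0, 0))
  expect_equal(db$label, "rest")
})

test_that("segment features agree with an independent two-pass oracle", {
  rec <- generate_trial(tiny_profile(), tiny_acq(), 3, "wrist_abduction",
                        seed = 21)
  segs <- segment_recording(rec, tiny_seg_cfg())
  segs$label <- "wrist_abduction"
  db <- extract_features(rec, segs)
  for (i in seq_len(nrow(segs))) {
    rows <- (segs$start_sample[i] + 1):segs$end_sample[i]
    for (ch in 1:3) {
      x <- rec$forces[rows, ch]
      # two-pass mean / SD, written out longhand
      m <- sum(x) / length(x)
      s <- sqrt(sum((x - m)^2) / (length(x) - 1))
      expect_equal(db[[paste0("fsr", ch, "_mean")]][i], m,
                   tolerance = 1e-12)
      expect_equal(db[[paste0("fsr", ch, "_sd")]][i], s, tolerance = 1e-12)
    }
  }
})

test_that("feature extraction is affine-equivariant per channel", {
  rec <- generate_trial(tiny_profile(), tiny_acq(), 2, "clenched_fist",
                        seed = 22)
  segs <- segment_recording(rec, tiny_seg_cfg())
  segs$label <- "clenched_fist"
  db <- extract_features(rec, segs)
  a <- c(2, -1.5, 0.5); b <- c(0.1, 0.2, -0.3)
  rec2 <- fsr_recording(sweep(sweep(rec$forces, 2, a, `*`), 2, b, `+`),
                        rec$sampling_rate)
  db2 <- extract_features(rec2, segs)
  for (ch in 1:3) {
    expect_equal(db2[[paste0("fsr", ch, "_mean")]],
                 a[ch] * db[[paste0("fsr", ch, "_mean")]] + b[ch],
                 tolerance = 1e-12)
    expect_equal(db2[[paste0("fsr", ch, "_sd")]],
                 abs(a[ch]) * db[[paste0("fsr", ch, "_sd")]],
                 tolerance = 1e-12)
  }
})

test_that("mean-median deviation is small for symmetric noise, large for skew", {
  p <- tiny_profile(noise_sd = 0.001)
  p$rise_time <- 0; p$fall_time <- 0  # rectangular bursts: pure plateau
  rec <- generate_trial(p, tiny_acq(), 3, "clenched_fist", seed = 30)
  segs <- segment_recording(rec, tiny_seg_cfg())
  dev <- median_check(rec, segs)
  expect_true(all(dev < 2))
  # an injected heavily skewed artifact pushes the deviation past 2%
  skewed <- rec
  rows <- (segs$start_sample[1] + 1):segs$end_sample[1]
  spike <- rows[seq_len(floor(length(rows) / 4))]
  skewed$forces[spike, select_segmentation_channel(rec)] <- 5
  dev2 <- median_check(skewed, segs)
  expect_gt(dev2[1], 2)
  # zero-mean segments are flagged, not divided by zero
  zero <- fsr_recording(matrix(0, 100, 3), 200)
  zseg <- data.frame(start_sample = 0L, end_sample = 50L, channel = 1L,
                     label = "rest")
  expect_true(is.na(median_check(zero, zseg, channel = 1)))
})

test_that("combining databases concatenates rows and keeps provenance", {
  dbs <- lapply(1:3, function(i) {
    tiny_database(seed = i, repetitions = 2, subject_id = paste0("S", i))
  })
  all <- combine_databases(dbs)
  expect_equal(nrow(all), 3 * 16)
  expect_equal(unique(all$subject_id), c("S1", "S2", "S3"))
  counts <- table(all$label)
  expect_true(all(counts == 6))  # sums of per-subject class counts
  expect_equal(nrow(combine_databases(list())), 0)
})

test_that("sensor projection keeps the masked mean/SD columns", {
  db <- tiny_database(seed = 4, repetitions = 2)
  pair <- project_sensors(db, c(1, 2))
  expect_identical(setdiff(names(pair), c("label", "subject_id")),
                   c("fsr1_mean", "fsr2_mean", "fsr1_sd", "fsr2_sd"))
  single <- project_sensors(db, 3)
  expect_identical(setdiff(names(single), c("label", "subject_id")),
                   c("fsr3_mean", "fsr3_sd"))
  full <- project_sensors(db, 1:3)
  expect_equal(db_features(full), db_features(db))
  # row count conservation
  expect_equal(nrow(pair), nrow(db))
  expect_error(project_sensors(single, 1), "subset")
})

test_that("the full default protocol yields the 80 x 7 gesture database", {
  db <- cached_default_database()
  expect_equal(nrow(db), 80)
  expect_equal(ncol(db_features(db)), 6)
  expect_equal(unname(table(db$label)), rep(10L, 8), ignore_attr = TRUE)
  expect_false(anyNA(db$label))
})
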