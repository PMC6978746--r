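test_that("preprocessing zeroes rest offsets and normalizes to 1", {
  p <- tiny_profile()
  rest <- generate_trial(p, tiny_acq(), 3, "rest", seed = 1)
  rec <- generate_trial(p, tiny_acq(), 3, "clenched_fist", seed = 2)
  pre <- preprocess(rec, rest)
  expect_equal(max(abs(pre$forces)), 1)
  # a rest-only recording preprocessed against itself: per-channel min is 0
  pre_rest <- preprocess(rest, rest)
  expect_equal(unname(apply(pre_rest$forces, 2, min)), c(0, 0, 0))
  # adding a constant per-channel offset to both recording and reference
  # leaves the result unchanged
  shift <- c(0.3, 0.1, 0.2)
  rec2 <- fsr_recording(sweep(rec$forces, 2, shift, `+`), rec$sampling_rate)
  rest2 <- fsr_recording(sweep(rest$forces, 2, shift, `+`),
                         rest$sampling_rate)
  pre2 <- preprocess(rec2, rest2)
  expect_equal(pre2$forces, pre$forces, tolerance = 1e-12)
})

test_that("degenerate all-zero recordings are rejected", {
  flat <- fsr_recording(matrix(0.1, 100, 3), 200)
  expect_error(preprocess(flat, flat), "degenerate")
  expect_error(preprocess(flat, c(5, 5)), "half-open")
})

test_that("segmentation channel is the peak-to-peak argmax with low-index ties", {
  mk <- function(p2p) {
    fsr_recording(sapply(p2p, function(a) c(0, a, 0, a / 2)), 200)
  }
  expect_equal(select_segmentation_channel(mk(c(0.2, 0.9, 0.4))), 2)
  expect_equal(select_segmentation_channel(mk(c(0.5, 0.2, 0.5))), 1)
  # on a clenched-fist trial the selected channel carries the largest
  # plateau of the activation profile
  p <- tiny_profile()
  rec <- generate_trial(p, tiny_acq(), 3, "clenched_fist", seed = 3)
  expect_equal(select_segmentation_channel(rec),
               unname(which.max(p$plateau_force[, "clenched_fist"])))
})

test_that("rectangular bursts segment one-to-one", {
  x <- rep(0, 600)
  for (s in c(100, 250, 400)) x[s:(s + 59)] <- 1
  rec <- fsr_recording(cbind(x, 0, 0), 200)
  segs <- segment_recording(rec, segmentation_config(0.4, 0.1, 0.05),
                            channel = 1)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start_sample, c(99, 249, 399))
  expect_equal(segs$end_sample - segs$start_sample, rep(60, 3))
})

test_that("the 40% threshold crosses a linear ramp where theory says", {
  fs <- 1000
  r <- 200  # rise samples
  ramp <- c(rep(0, 100), seq_len(r) / r, rep(1, 500),
            rev(seq_len(r) / r), rep(0, 100))
  rec <- fsr_recording(cbind(ramp, 0, 0), fs)
  segs <- segment_recording(rec, segmentation_config(0.4, 0.1, 0.05),
                            channel = 1)
  expect_equal(nrow(segs), 1)
  # burst onset at sample 100; the 0.4 crossing of a linear ramp of r
  # samples sits 0.4 * r after onset
  expect_equal(segs$start_sample, 100 + ceiling(0.4 * r) - 1, tolerance = 2)
  expect_equal(segs$end_sample, 100 + r + 500 + floor(0.6 * r) + 1,
               tolerance = 2)
})

test_that("flat signals yield no segments, short blips are dropped, gaps merge", {
  flat <- fsr_recording(matrix(0.2, 300, 3), 200)
  expect_equal(nrow(segment_recording(flat)), 0)
  x <- rep(0, 700)
  x[100:104] <- 1          # 5-sample blip: below min duration
  x[300:359] <- 1          # burst
  x[365:424] <- 1          # 5-sample dip to the burst above: merged
  rec <- fsr_recording(cbind(x, 0, 0), 200)
  segs <- segment_recording(rec, segmentation_config(0.4, 0.1, 0.05),
                            channel = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_sample, 299)
  expect_equal(segs$end_sample, 424)
})

test_that("segmentation is invariant under positive affine transforms", {
  rec <- generate_trial(tiny_profile(), tiny_acq(), 4, "wrist_flexion",
                        seed = 9)
  segs <- segment_recording(rec, tiny_seg_cfg())
  scaled <- fsr_recording(rec$forces * 3.7 + 0.42, rec$sampling_rate)
  segs2 <- segment_recording(scaled, tiny_seg_cfg())
  expect_identical(segs, segs2)
})

test_that("segment counts match the protocol across many seeds", {
  p <- tiny_profile()
  for (seed in 1:20) {
    rec <- generate_trial(p, tiny_acq(), 3, "wrist_extension", seed = seed)
    segs <- segment_recording(rec, tiny_seg_cfg())
    expect_equal(nrow(segs), 3)
    # disjoint and sorted
    if (nrow(segs) > 1) {
      expect_true(all(segs$start_sample[-1] >= segs$end_sample[-3]))
    }
  }
})

test_that("segments inherit the label of their maximal-overlap interval", {
  timeline <- data.frame(start_sample = c(100L, 400L),
                         end_sample = c(200L, 500L),
                         label = c("clenched_fist", "wrist_flexion"))
  segs <- data.frame(start_sample = c(110L, 150L, 600L),
                     end_sample = c(190L, 420L, 650L),
                     channel = 1L, label = NA_character_)
  out <- label_segments(segs, timeline)
  expect_equal(out$label, c("clenched_fist", "clenched_fist", NA))
})

test_that("a full labelled protocol session recovers every gesture instance", {
  db <- tiny_database(seed = 1, repetitions = 3)
  expect_equal(nrow(db), 24)
  expect_equal(unname(table(db$label)), rep(3L, 8), ignore_attr = TRUE)
  expect_false(anyNA(db$label))
})

test_that("rest windows tile a segment-free recording and fill gaps otherwise", {
  rec <- fsr_recording(matrix(0.1, 2000, 3), 200)
  w <- rest_windows(rec, segment_recording(rec)[0, ], n = 4,
                    window_seconds = 1)
  expect_equal(nrow(w), 4)
  expect_true(all(w$end_sample - w$start_sample == 200))
  expect_true(all(w$start_sample >= 0 & w$end_sample <= 2000))
  expect_true(all(diff(w$start_sample) >= 200))  # non-overlapping
  segs <- data.frame(start_sample = 500L, end_sample = 900L, channel = 1L,
                     label = "clenched_fist")
  w2 <- rest_windows(rec, segs, n = 2, window_seconds = 1)
  expect_equal(nrow(w2), 2)
  # windows avoid the detected segment
  expect_true(all(w2$end_sample <= 500 | w2$start_sample >= 900))
  expect_error(rest_windows(rec, segs, n = 5, window_seconds = 1), "gaps")
})
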