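# Baseline candidate intervals, the stability criterion, and extraction.

test_that("candidate interval counts and spans follow the guard arithmetic", {
  des <- list(block_design("airflow"), block_design("touch"))
  sch <- make_schedule(des)
  seg <- isi_segments(sch)
  # n - 1 consecutive pairs per block of n events
  expect_equal(sum(seg$block_type == "airflow"), 109L)
  expect_equal(sum(seg$block_type == "touch"), 99L)
  # 1 s stimuli, 4 s gaps, 200 ms guards: every candidate spans 3.6 s
  expect_true(all(abs(seg$duration - 3.6) < 1e-9))
  # no candidate precedes the first stimulus of its block
  for (b in unique(sch$block_id))
    expect_gte(min(seg$start[seg$block_id == b]),
               min(sch$onset[sch$block_id == b]))
  # single-stimulus block contributes no candidates
  seg1 <- isi_segments(make_schedule(block_design("touch", 1, 1)))
  expect_equal(nrow(seg1), 0L)
  # short gaps are skipped with a message, not an error
  tight <- data.frame(onset = c(0, 1.3), offset = c(1, 2.3),
                      block_id = 1L, block_type = "airflow")
  expect_message(seg2 <- isi_segments(tight, min_length = 0.5), "skipping")
  expect_equal(nrow(seg2), 0L)
})

test_that("stability criterion avoids a repeated early burst; exhaustive scan oracle", {
  s <- small_session(seed = 21, effect = null_effect_spec(),
                     channels = c("B", "B"))
  seg <- isi_segments(s)
  # plant a strong variable-amplitude burst in the first second of every ISI
  fs <- s$fs
  set.seed(9)
  for (i in seq_len(nrow(seg))) {
    i0 <- round(seg$start[i] * fs) + 1
    idx <- i0:(i0 + fs - 1)
    tt <- seq_along(idx) / fs
    s$lfp[, idx] <- s$lfp[, idx] +
      rep(runif(1, 200, 600), each = nrow(s$lfp)) *
        matrix(sin(2 * pi * 30 * tt), nrow(s$lfp), length(idx), byrow = TRUE)
  }
  sel <- select_stable_window(s, seg, window_length = 0.5)
  # window clear of the burst region (boundary sample tolerance)
  expect_gte(sel$offset, 1.0 - 2 / fs)

  # oracle: brute-force mean-SD over every admissible offset
  n_win <- round(0.5 * fs)
  n_common <- floor(min(seg$duration) * fs)
  starts <- round(seg$start * fs) + 1
  sd_prof <- rowMeans(vapply(1:2, function(ch) {
    trials <- t(vapply(starts, function(i0)
      s$lfp[ch, i0:(i0 + n_common - 1)], numeric(n_common)))
    apply(trials, 2, sd)
  }, numeric(n_common)))
  scores <- vapply(seq_len(n_common - n_win + 1), function(o)
    mean(sd_prof[o:(o + n_win - 1)]), numeric(1))
  expect_equal(sel$offset, (which.min(scores) - 1) / fs)
  expect_equal(sel$score, min(scores))
})

test_that("stability scan breaks ties toward the earliest offset and validates length", {
  s <- small_session(seed = 22, effect = null_effect_spec())
  # constant LFP: SD profile identically zero, all offsets tie
  s$lfp[] <- 5
  sel <- select_stable_window(s, window_length = 0.5)
  expect_equal(sel$offset, 0)
  expect_error(select_stable_window(s, window_length = 10),
               "exceeds the shortest")
})

test_that("extraction yields the product count with pure labels and guard clearance", {
  s <- small_session(seed = 23, n_per_sequence = 5, n_repeats = 2,
                     channels = c("B", "L", "AB"))
  seg <- isi_segments(s)
  b <- extract_baselines(s, offset = 0.25, window_length = 0.5)
  expect_equal(nrow(b$signals), nrow(seg) * 3L)
  expect_equal(ncol(b$signals), 500L)
  expect_true(all(table(b$index$channel) == nrow(seg)))
  # label purity: each window labelled by its block's type
  for (i in seq_len(nrow(b$index))) {
    blk <- s$schedule[s$schedule$block_id == b$index$block_id[i], ]
    expect_equal(b$index$label[i], blk$block_type[1])
  }
  # no window intrudes into any stimulus +/- 200 ms guard
  for (i in seq_len(nrow(b$index))) {
    bad <- s$schedule$onset - 0.2 < b$index$t_end[i] &
      s$schedule$offset + 0.2 > b$index$t_start[i]
    expect_false(any(bad))
  }
  # deterministic offset choice for a fixed session
  expect_equal(select_stable_window(s)$offset, select_stable_window(s)$offset)
  # nucleus bookkeeping matches the channel map
  expect_equal(unique(b$index$nucleus[b$index$channel == 2]), "L")
})

test_that("extraction handles empty input", {
  s <- small_session(seed = 24, n_per_sequence = 1, n_repeats = 1)
  b <- extract_baselines(s)
  expect_equal(nrow(b$signals), 0L)
})
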