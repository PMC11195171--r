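# Session generator: schedule arithmetic, determinism, injected band
# effects, heartbeat statistics, spike statistics.

test_that("schedule expands designs into the exact presentation counts", {
  sch <- make_schedule(default_designs(1))
  counts <- table(sch$block_type)
  expect_equal(unname(counts[["airflow"]]), 110L)
  expect_equal(unname(counts[["touch"]]), 100L)

  # degenerate design: a single 1 s event
  one <- make_schedule(block_design("airflow", n_per_sequence = 1,
                                    n_repeats = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$offset - one$onset, 1.0)

  # conservation for arbitrary designs
  d <- list(block_design("airflow", 7, 3), block_design("touch", 5, 4))
  sch2 <- make_schedule(d)
  expect_equal(as.integer(table(sch2$block_id)), c(21L, 20L))
  expect_true(all(diff(sch2$onset) > 0))
  expect_true(all(sch2$onset[-1] >= sch2$offset[-nrow(sch2)]))
})

test_that("schedule rejects invalid parameters", {
  expect_error(make_schedule(list()), "non-empty")
  expect_error(block_design("airflow", stim_duration = -1), "positive")
  expect_error(block_design("airflow", n_per_sequence = 0), "positive")
  expect_error(make_schedule(default_designs(1), inter_block_gap = 0),
               "positive")
})

test_that("effect_spec enforces its physiological invariants", {
  expect_error(effect_spec(hr_airflow = 110, hr_touch = 130), "hr_touch")
  expect_error(effect_spec(rsa_depth_airflow = 0.3, rsa_depth_touch = 0.1),
               "rsa_depth")
  expect_error(effect_spec(resp_freq = 0.6), "resp_freq")
  expect_error(effect_spec(touch_band_gain = 0.5), "gains")
  expect_error(effect_spec(hr_airflow = 300, hr_touch = 100), "BPM")
  # the null world is a valid configuration
  e <- null_effect_spec()
  expect_equal(e$touch_band_gain, 1)
  expect_equal(e$hr_airflow, e$hr_touch)
})

test_that("identical seed and parameters give bit-identical LFP", {
  s1 <- small_session(seed = 7)
  s2 <- small_session(seed = 7)
  expect_identical(s1$lfp, s2$lfp)
  s3 <- small_session(seed = 8)
  expect_false(identical(s1$lfp, s3$lfp))
  expect_true(all(is.finite(s1$lfp)))
})

test_that("injected touch-band gain raises 10-17 Hz baseline power, null world does not", {
  # oracle: independent periodogram band power on extracted baseline windows
  band_powers <- function(session) {
    b <- extract_baselines(session, offset = 0.5)
    pw <- apply(b$signals, 1, oracle_band_power, fs = session$fs,
                lo = 10, hi = 17)
    split(pw, b$index$label)
  }
  # signal world: gain 2.0 in 10-17 Hz during touch
  sig <- small_session(seed = 42, n_per_sequence = 9, n_repeats = 4,
                       channels = rep("B", 3))
  p_sig <- band_powers(sig)
  expect_gt(length(p_sig$touch), 90)
  tt <- t.test(p_sig$touch, p_sig$airflow, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # mean ratio should approach the injected gain for the band component;
  # diluted by the 1/f background, so only direction is asserted
  expect_gt(mean(p_sig$touch), mean(p_sig$airflow))

  # null world: both classes drawn from the same distribution
  nul <- small_session(seed = 42, effect = null_effect_spec(),
                       n_per_sequence = 9, n_repeats = 4,
                       channels = rep("B", 3))
  p_nul <- band_powers(nul)
  se <- sqrt(stats::var(p_nul$touch) / length(p_nul$touch) +
               stats::var(p_nul$airflow) / length(p_nul$airflow))
  expect_lt(abs(mean(p_nul$touch) - mean(p_nul$airflow)), 3 * se)
})

test_that("heartbeat generator matches its target rates", {
  # constant-rate limit: all IBIs exactly one second
  sch <- make_schedule(block_design("airflow", 6, 2), t_start = 5)
  hb <- simulate_heartbeats(sch, null_effect_spec(hr = 60, rsa_depth = 0),
                            tail = 10)
  expect_true(all(abs(diff(hb) - 1.0) < 1e-9))

  # block-mean heart rates recovered within +/- 3 BPM
  e <- effect_spec(hr_airflow = 130, hr_touch = 110)
  sch2 <- make_schedule(list(block_design("airflow", 11, 4),
                             block_design("touch", 20, 2)),
                        inter_block_gap = 30)
  hb2 <- simulate_heartbeats(sch2, e)
  ext <- lfpcontext:::block_extents(sch2)
  for (b in seq_len(nrow(ext))) {
    n_beats <- sum(hb2 >= ext$start[b] & hb2 <= ext$end[b])
    bpm <- 60 * n_beats / (ext$end[b] - ext$start[b])
    target <- if (ext$block_type[b] == "touch") 110 else 130
    expect_lt(abs(bpm - target), 3)
  }

  # injected artifact beats create sub-250 ms IBIs that cleaning flags
  hb3 <- simulate_heartbeats(sch, effect_spec(), n_artifacts = 3, seed = 2)
  expect_true(any(diff(hb3) < 0.25))
  cleaned <- clean_heartbeats(hb3)
  expect_gte(length(cleaned$removed), 1)
  expect_true(all(cleaned$ibi_ms[cleaned$ibi_ms <= 1500] >= 250))
})

test_that("spike trains have Poisson counts and obey the coupling switch", {
  sch <- make_schedule(block_design("airflow", 24, 5), t_start = 2,
                       inter_block_gap = 10)
  e <- null_effect_spec()
  s <- simulate_lfp(sch, c("B"), e, seed = 5, stim_amp = 0, tail = 2)
  # rate 5 Hz over the session: count within 3 sqrt(mean) of the mean
  s <- simulate_spikes(s, rate = 5, lfp_coupling = 0, seed = 9)
  expected <- 5 * s$duration
  expect_lt(abs(length(s$spikes[[1]]$times) - expected), 3 * sqrt(expected))
  expect_true(all(s$spikes[[1]]$times >= 0 & s$spikes[[1]]$times <= s$duration))
  # determinism
  s2 <- simulate_spikes(s, rate = 5, lfp_coupling = 0, seed = 9)
  expect_identical(s$spikes[[1]]$times, s2$spikes[[1]]$times)
})

test_that("simulate_lfp validates inputs", {
  sch <- make_schedule(block_design("airflow", 2, 1))
  expect_error(simulate_lfp(sch[0, ], "B"), "empty")
  expect_error(simulate_lfp(sch, "B", fs = 100), "fs")
})
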