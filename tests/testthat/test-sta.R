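# Spike-triggered averages, their spectra, and per-nucleus means.

# Session whose spikes are phase-locked to a planted oscillation.
locked_session <- function(freq = 12.5, seed = 31) {
  s <- small_session(seed = seed, effect = null_effect_spec(),
                     channels = c("B", "B"), n_per_sequence = 8,
                     n_repeats = 2, stim_amp = 0)
  t <- (seq_len(ncol(s$lfp)) - 1) / s$fs
  osc <- 40 * cos(2 * pi * freq * t)
  s$lfp[1, ] <- s$lfp[1, ] + osc
  # spikes exactly at oscillation peaks
  peaks <- which(diff(sign(diff(osc))) < 0) / s$fs
  s$spikes <- list(list(unit = 1L, channel = 1L, times = peaks))
  s
}

test_that("STA of phase-locked spikes recovers the generating oscillation", {
  s <- locked_session(freq = 12.5)
  b <- extract_baselines(s, offset = 0.5)
  sta <- spike_triggered_average(s, b, 1)
  expect_equal(sta$lags, seq(-80, 80) / 1000)
  tr <- sta$sta$airflow
  expect_gt(sta$n_spikes[["airflow"]], 20)
  # period 80 ms: peak near lag 0 (background noise can tip the flat
  # cosine top by a few ms), troughs at +/- 40 ms
  expect_lte(abs(40L + which.max(tr[41:121]) - 81L), 8L)
  expect_lt(tr[41], 0)
  expect_lt(tr[121], 0)
  # correlation with the ideal cosine at 12.5 Hz
  ideal <- cos(2 * pi * 12.5 * sta$lags)
  expect_gt(cor(tr, ideal), 0.95)
  # spectrum of the snippets peaks at the grid frequency nearest 12.5 Hz
  spec <- sta$spectrum$airflow
  band <- spec[spec$freq >= 1 & spec$freq <= 50, ]
  expect_lt(abs(band$freq[which.max(band$power)] - 12.5), 3.2)
})

test_that("uncoupled Poisson spikes give a flat STA within the CLT bound", {
  # rate low enough that +/-80 ms snippets rarely overlap (snippet
  # correlation would inflate the standard error)
  s <- small_session(seed = 33, effect = null_effect_spec(),
                     channels = c("B"), n_per_sequence = 12, n_repeats = 4,
                     stim_amp = 0)
  s <- simulate_spikes(s, rate = 3, lfp_coupling = 0, seed = 7)
  b <- extract_baselines(s, offset = 0.5)
  sta <- spike_triggered_average(s, b, 1)
  expect_gt(sum(sta$n_spikes), 40)
  for (lab in c("airflow", "touch"))
    if (!is.null(sta$sta[[lab]])) {
      se_hat <- apply(sta$snippets[[lab]], 2, sd) /
        sqrt(sta$n_spikes[[lab]])
      expect_true(all(abs(sta$sta[[lab]]) < 5 * se_hat))
    }
})

test_that("coupled spikes concentrate STA spectral power in the coupling band", {
  e <- null_effect_spec()
  s <- small_session(seed = 35, effect = e, channels = c("B"),
                     n_per_sequence = 10, n_repeats = 3, stim_amp = 0)
  s <- simulate_spikes(s, rate = 15, lfp_coupling = 3,
                       coupling_band = c(10, 17), seed = 8)
  b <- extract_baselines(s, offset = 0.5)
  sta <- spike_triggered_average(s, b, 1)
  spec <- sta$spectrum$airflow
  band <- spec[spec$freq >= 2 & spec$freq <= 50, ]
  pk <- band$freq[which.max(band$power)]
  expect_gte(pk, 10 - 3.2)
  expect_lte(pk, 17 + 3.2)
})

test_that("single spike yields its snippet; none yields the empty marker", {
  s <- small_session(seed = 36, effect = null_effect_spec(),
                     channels = c("B"), stim_amp = 0)
  b <- extract_baselines(s, offset = 0.5)
  iv <- b$index[b$index$label == "airflow", ][1, ]
  t_spk <- (iv$t_start + iv$t_end) / 2
  s$spikes <- list(list(unit = 1L, channel = 1L, times = t_spk))
  sta <- spike_triggered_average(s, b, 1)
  ci <- round(t_spk * s$fs) + 1
  expect_equal(sta$sta$airflow, s$lfp[1, (ci - 80):(ci + 80)])
  expect_equal(sta$n_spikes[["airflow"]], 1L)
  expect_null(sta$sta$touch)
  expect_equal(sta$n_spikes[["touch"]], 0L)
})

test_that("time reversal of snippets reverses the STA lag axis exactly", {
  s <- locked_session(seed = 37)
  b <- extract_baselines(s, offset = 0.5)
  sta <- spike_triggered_average(s, b, 1)
  snip <- sta$snippets$airflow
  rev_sta <- colMeans(snip[, ncol(snip):1])
  expect_equal(rev_sta, rev(sta$sta$airflow), tolerance = 1e-12)
})

test_that("STA spectra are calibrated and flat for white noise", {
  set.seed(41)
  fs <- 1000
  snip <- matrix(rnorm(200 * 161), 200)
  spec <- sta_spectrum(snip, fs)
  expect_true(all(spec$power >= 0))
  band <- spec$power[spec$freq >= 1 & spec$freq <= 50]
  se <- sd(band) / sqrt(length(band))
  expect_lt(max(abs(band - mean(band))), 3 * sd(band) + 3 * se)
  # Parseval on a tone: integrated PSD of unit amplitude ~ 1/2
  tone <- matrix(sin(2 * pi * 25 * (0:160) / fs), 1)
  sp_t <- sta_spectrum(tone, fs)
  expect_equal(sum(sp_t$power) * diff(sp_t$freq)[1], 0.5, tolerance = 0.05)
  expect_error(sta_spectrum(snip, fs, segment_length = 500), "exceeds")
})

test_that("mean STA averages units within a nucleus and skips empty nuclei", {
  s <- locked_session(seed = 38)
  b <- extract_baselines(s, offset = 0.5)
  sta1 <- spike_triggered_average(s, b, 1)
  # two identical units: mSTA equals either
  m <- mean_sta(list(sta1, sta1), "B")
  expect_equal(m$msta$airflow, sta1$sta$airflow)
  expect_equal(m$n_units[["airflow"]], 2L)
  # opposite-sign STAs cancel
  sta_neg <- sta1
  sta_neg$sta$airflow <- -sta1$sta$airflow
  m0 <- mean_sta(list(sta1, sta_neg), "B")
  expect_true(all(abs(m0$msta$airflow) < 1e-9))
  # empty nucleus: skipped with a message, returns NULL
  expect_message(out <- mean_sta(list(sta1), "Pl"), "skipped")
  expect_null(out)
})
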