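# Heartbeat cleaning, heart-rate interpolation, multitaper RSA strength,
# and block-level autonomic comparisons.

test_that("IBI cleaning removes out-of-range intervals with inclusive bounds", {
  # 800, 800, 200, 800 ms: the 200 ms interval is rejected
  beats <- c(0, 0.8, 1.6, 1.8, 2.6, 3.4)
  hbs <- clean_heartbeats(beats)
  expect_true(1.8 %in% hbs$removed)
  expect_false(1.8 %in% hbs$beat_times)
  # cutoff arithmetic: 250 ms <-> 240 BPM, 1500 ms <-> 40 BPM
  expect_equal(60000 / 250, 240)
  expect_equal(60000 / 1500, 40)
  # an exactly-250 ms interval is retained (boundary inclusive), HR 240
  b2 <- c(0, 0.5, 1.0, 1.25, 1.75)
  h2 <- clean_heartbeats(b2)
  expect_equal(length(h2$removed), 0L)
  expect_equal(max(h2$hr_bpm), 240)
})

test_that("constant 1000 ms IBIs give hr_instant identically 60 BPM", {
  hbs <- clean_heartbeats(0:20)
  expect_equal(range(hbs$hr_instant), c(60, 60))
  expect_equal(hbs$grid_dt, 0.001)
  expect_equal(diff(hbs$hr_time)[1], 0.001)
})

test_that("cleaning is idempotent and errors on unusable series", {
  set.seed(3)
  beats <- cumsum(runif(60, 0.2, 1.7))
  h1 <- clean_heartbeats(beats)
  h2 <- clean_heartbeats(h1)
  expect_identical(h1$beat_times, h2$beat_times)
  expect_identical(h1$hr_instant, h2$hr_instant)
  expect_error(clean_heartbeats(c(0, 1)), "at least 3")
  expect_error(clean_heartbeats(c(0, 0.1, 0.2, 0.21)), "valid")
  expect_error(clean_heartbeats(c(3, 2, 1, 0.5)), "sorted")
})

fake_hr_series <- function(hr_fun, duration = 200, dt = 0.001) {
  t <- seq(0, duration, by = dt)
  structure(list(beat_times = NULL, hr_time = t, hr_instant = hr_fun(t),
                 grid_dt = dt, hr_bpm = mean(hr_fun(t))),
            class = "heartbeat_series")
}

test_that("RSA spectra have unit band area and locate a pure respiratory tone", {
  hbs <- fake_hr_series(function(t) 70 + 5 * sin(2 * pi * 0.3 * t))
  r <- rsa_strength(hbs)
  df <- diff(r$band_freqs)[1]
  areas <- rowSums(r$band_spectra) * df
  expect_true(all(abs(areas - 1) < 1e-6))
  peaks <- apply(r$band_spectra, 1, function(p) r$band_freqs[which.max(p)])
  expect_true(all(abs(peaks - 0.3) <= 0.02))
  # Eq-style normalization: (P - mu)/mu with mu the median across windows
  expect_equal(r$mu, median(r$windows$p_raw))
  expect_equal(r$windows$p_rsa, (r$windows$p_raw - r$mu) / r$mu)
})

test_that("flat heart rate takes the no-peak branch in every window", {
  hbs <- fake_hr_series(function(t) rep(75, length(t)))
  r <- rsa_strength(hbs)
  # no interior spectral peak: strength equals the band mean of a unit-area
  # spectrum, i.e. 1/bandwidth, in every window
  expect_true(all(abs(r$windows$p_raw - mean(r$band_spectra[1, ])) < 1e-9))
  expect_error(rsa_strength(fake_hr_series(function(t) 70 + 0 * t,
                                           duration = 30)),
               "shorter")
})

test_that("sum-normalization mode satisfies the mean-centering identity", {
  hbs <- fake_hr_series(function(t) 72 + 4 * sin(2 * pi * 0.35 * t) +
                          1.5 * sin(2 * pi * 0.07 * t))
  r <- rsa_strength(hbs, mu_mode = "sum")
  expect_equal(r$mu, sum(r$windows$p_raw))
  # per window (P_rsa + 1) * mu recovers the raw strength, so their sum
  # recovers the total raw power
  expect_equal((r$windows$p_rsa + 1) * r$mu, r$windows$p_raw,
               tolerance = 1e-12)
  expect_equal(sum((r$windows$p_rsa + 1) * r$mu), r$mu, tolerance = 1e-9)
})

test_that("window hop convention: 3 s hop yields ~ (T - 60)/3 windows", {
  hbs <- fake_hr_series(function(t) 70 + 3 * sin(2 * pi * 0.3 * t),
                        duration = 120)
  r <- rsa_strength(hbs, window = 60, hop = 3)
  expect_equal(nrow(r$windows), floor((120 - 60) / 3) + 1)
  expect_equal(diff(r$windows$center)[1], 3)
})

test_that("block comparison recovers injected autonomic contrasts", {
  # 4 simulated sessions with the default effect (lower HR, stronger RSA
  # in touch); paired one-sided tests should be clearly significant
  results <- lapply(1:4, function(i) {
    sch <- make_schedule(list(block_design("airflow", 11, 2),
                              block_design("touch", 20, 1)),
                         inter_block_gap = 30, t_start = 5)
    hb <- simulate_heartbeats(sch, effect_spec(), seed = i)
    rsa_strength(clean_heartbeats(hb), schedule = sch)
  })
  cmp <- compare_blocks(results)
  expect_equal(cmp$n_sessions, 4L)
  expect_lt(cmp$rsa$p, 0.01)
  expect_lt(cmp$hr$p, 0.01)
  expect_true(all(cmp$hr$diffs > 0))   # airflow HR above touch HR

  # degenerate: identical block means give t = 0, p = 0.5
  flat <- results
  for (i in seq_along(flat)) {
    bs <- flat[[i]]$block_summary
    bs$mean_p_rsa <- c(0.1, 0.1)
    bs$mean_hr <- c(120, 120)
    flat[[i]]$block_summary <- bs
  }
  cmp0 <- compare_blocks(flat)
  expect_equal(cmp0$rsa$p, 0.5)
  expect_equal(cmp0$rsa$t, 0)

  expect_error(compare_blocks(results[[1]]), "at least 2")
})
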