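# Shared fixtures: small synthetic sessions built in code. Sizes are kept
# modest so the whole suite runs on one core; the block structure and all
# effect parameters keep their defaults.

# A short two-block session (one airflow, one touch) with few channels.
small_session <- function(seed = 101, effect = effect_spec(),
                          n_per_sequence = 6L, n_repeats = 2L,
                          channels = c("B", "B", "L"), fs = 1000,
                          inter_block_gap = 20, spikes = FALSE,
                          heartbeats = FALSE, ...) {
  designs <- list(
    block_design("airflow", n_per_sequence = n_per_sequence,
                 n_repeats = n_repeats),
    block_design("touch", n_per_sequence = n_per_sequence,
                 n_repeats = n_repeats))
  simulate_session(designs, channel_nuclei = channels, effect = effect,
                   fs = fs, seed = seed, inter_block_gap = inter_block_gap,
                   spikes = spikes, heartbeats = heartbeats, ...)
}

# Independent periodogram band power (oracle; no package Welch machinery):
# mean one-sided periodogram power density in [lo, hi] Hz.
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)[seq_len(n %/% 2 + 1)]
  p <- (Mod(X)^2) / (n * fs)
  p[-1] <- 2 * p[-1]
  f <- (seq_along(p) - 1) * fs / n
  mean(p[f >= lo & f <= hi])
}

# Toy two-class spectrogram stack: class-dependent mean added to noise in a
# block of pixels. Linearly separable for strong shift.
toy_stack <- function(n_per_class = 40, h = 12, w = 10, shift = 1,
                      seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  power <- array(abs(rnorm(h * w * n, 1, 0.3)), c(h, w, n))
  labels <- rep(c("airflow", "touch"), each = n_per_class)
  sel <- which(labels == "touch")
  power[3:6, 3:6, sel] <- power[3:6, 3:6, sel] + shift
  structure(list(power = power, freq_grid = seq_len(h),
                 time_grid = seq_len(w) / 100,
                 index = data.frame(window = seq_len(n), channel = 1L,
                                    nucleus = "B", label = labels,
                                    block_id = rep(1:2, each = n_per_class),
                                    t_start = seq_len(n),
                                    t_end = seq_len(n) + 0.5),
                 fs = 1000), class = "spectrogram_stack")
}
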