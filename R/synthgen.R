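# Synthetic session generator: block-structured stimulus schedules,
# multichannel LFP with context-dependent band-power modulation, heartbeat
# series with block-dependent rate and respiratory modulation, and
# LFP-coupled spike trains.

#' Stimulus block design
#'
#' One block of tactile stimulation: a sequence of `n_per_sequence` stimuli
#' repeated `n_repeats` times. Defaults follow the experimental paradigm:
#' airflow blocks deliver 11 presentations x 10 repeats (110 total), touch
#' (grooming) blocks 20 stimuli x 5 repeats (100 total); stimuli last 1 s
#' and are separated by ~4 s.
#'
#' @param block_type `"airflow"` or `"touch"`.
#' @param n_per_sequence stimuli per sequence; defaults 11 (airflow) or 20
#'   (touch).
#' @param n_repeats sequence repeats; defaults 10 (airflow) or 5 (touch).
#' @param stim_duration stimulus duration (s).
#' @param inter_stim_gap gap between stimulus offset and next onset (s).
#' @return object of class `block_design`.
#' @export
block_design <- function(block_type = c("airflow", "touch"),
                         n_per_sequence = NULL, n_repeats = NULL,
                         stim_duration = 1.0, inter_stim_gap = 4.0) {
  block_type <- match.arg(block_type)
  if (is.null(n_per_sequence))
    n_per_sequence <- if (block_type == "airflow") 11L else 20L
  if (is.null(n_repeats))
    n_repeats <- if (block_type == "airflow") 10L else 5L
  if (n_per_sequence < 1 || n_repeats < 1)
    stop("n_per_sequence and n_repeats must be positive counts")
  if (stim_duration <= 0 || inter_stim_gap <= 0)
    stop("stim_duration and inter_stim_gap must be positive")
  structure(list(block_type = block_type,
                 n_per_sequence = as.integer(n_per_sequence),
                 n_repeats = as.integer(n_repeats),
                 stim_duration = stim_duration,
                 inter_stim_gap = inter_stim_gap),
            class = "block_design")
}

#' Default alternating block sequence
#'
#' @param n_per_type number of blocks of each type; blocks alternate
#'   airflow, touch, airflow, ...
#' @return list of `block_design` objects.
#' @export
default_designs <- function(n_per_type = 3L) {
  designs <- list()
  for (i in seq_len(n_per_type)) {
    designs[[2L * i - 1L]] <- block_design("airflow")
    designs[[2L * i]] <- block_design("touch")
  }
  designs
}

#' Build the stimulus event schedule for a session
#'
#' Lays out the blocks in order, separated by `inter_block_gap`, and expands
#' each block into its individual stimulus events. Each block contributes
#' exactly `n_per_sequence * n_repeats` events.
#'
#' @param designs non-empty list of [block_design()] objects, in session
#'   order.
#' @param inter_block_gap seconds between the last offset of one block and
#'   the first onset of the next ("a few minutes" in the paradigm; default
#'   120 s).
#' @param t_start onset of the first stimulus (s).
#' @return data frame with columns `onset`, `offset`, `block_id`,
#'   `block_type`, strictly increasing and non-overlapping.
#' @export
make_schedule <- function(designs, inter_block_gap = 120, t_start = 10) {
  if (inherits(designs, "block_design")) designs <- list(designs)
  if (length(designs) == 0L) stop("designs must be a non-empty list")
  if (inter_block_gap <= 0) stop("inter_block_gap must be positive")
  out <- vector("list", length(designs))
  t0 <- t_start
  for (b in seq_along(designs)) {
    d <- designs[[b]]
    if (!inherits(d, "block_design")) stop("designs[[", b, "]] is not a block_design")
    n_ev <- d$n_per_sequence * d$n_repeats
    period <- d$stim_duration + d$inter_stim_gap
    onsets <- t0 + (seq_len(n_ev) - 1L) * period
    out[[b]] <- data.frame(onset = onsets,
                           offset = onsets + d$stim_duration,
                           block_id = b,
                           block_type = d$block_type,
                           stringsAsFactors = FALSE)
    t0 <- max(onsets) + d$stim_duration + inter_block_gap
  }
  sched <- do.call(rbind, out)
  stopifnot(all(diff(sched$onset) > 0), all(sched$offset > sched$onset))
  sched
}

#' Context effect specification
#'
#' The injected differences between social (touch/grooming) and non-social
#' (airflow) blocks. Band gains are power multipliers (>= 1) applied to
#' band-limited LFP components within blocks of the favoured type; heart
#' rate and respiratory-sinus-arrhythmia depth differ by block. Setting
#' both gains to 1 and equal HR/RSA parameters yields a context-free "null
#' world".
#'
#' @param touch_band,airflow_band frequency band(s) favoured in touch resp.
#'   airflow blocks: a 2-vector `c(lo, hi)` in Hz or a list of such bands.
#'   Defaults 10-17 Hz (touch) and 17-25 Hz (airflow).
#' @param touch_band_gain,airflow_band_gain power gain factors >= 1.
#' @param burst_rate rate of transient oscillatory bursts (events/s).
#' @param burst_duration burst envelope SD-scale duration (s).
#' @param background_exponent slope of the 1/f^a background.
#' @param hr_airflow,hr_touch block heart rates (BPM); grooming lowers heart
#'   rate so `hr_touch <= hr_airflow`.
#' @param rsa_depth_airflow,rsa_depth_touch fractional modulation of the
#'   instantaneous rate at `resp_freq`; grooming raises RSA so
#'   `rsa_depth_touch >= rsa_depth_airflow`.
#' @param resp_freq respiratory frequency, in `[0.25, 0.5]` Hz.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(touch_band = c(10, 17), touch_band_gain = 2.0,
                        airflow_band = c(17, 25), airflow_band_gain = 2.0,
                        burst_rate = 0.5, burst_duration = 0.1,
                        background_exponent = 1.0,
                        hr_airflow = 130, hr_touch = 110,
                        rsa_depth_airflow = 0.05, rsa_depth_touch = 0.15,
                        resp_freq = 0.35) {
  as_bands <- function(b) if (is.list(b)) b else list(b)
  touch_band <- as_bands(touch_band)
  airflow_band <- as_bands(airflow_band)
  for (b in c(touch_band, airflow_band))
    if (length(b) != 2L || b[1L] >= b[2L] || b[1L] <= 0)
      stop("each band must be c(lo, hi) with 0 < lo < hi")
  if (touch_band_gain < 1 || airflow_band_gain < 1)
    stop("band power gains must be >= 1")
  if (hr_airflow <= 40 || hr_airflow >= 240 || hr_touch <= 40 || hr_touch >= 240)
    stop("heart rates must lie in (40, 240) BPM")
  if (hr_touch > hr_airflow)
    stop("hr_touch must not exceed hr_airflow (grooming lowers heart rate)")
  if (rsa_depth_touch < rsa_depth_airflow)
    stop("rsa_depth_touch must be >= rsa_depth_airflow (grooming raises RSA)")
  if (rsa_depth_airflow < 0 || rsa_depth_touch >= 1)
    stop("rsa depths must lie in [0, 1)")
  if (resp_freq < 0.25 || resp_freq > 0.5)
    stop("resp_freq must lie in [0.25, 0.5] Hz")
  if (burst_rate < 0 || burst_duration <= 0)
    stop("burst_rate must be >= 0 and burst_duration positive")
  structure(list(touch_band = touch_band, touch_band_gain = touch_band_gain,
                 airflow_band = airflow_band, airflow_band_gain = airflow_band_gain,
                 burst_rate = burst_rate, burst_duration = burst_duration,
                 background_exponent = background_exponent,
                 hr_airflow = hr_airflow, hr_touch = hr_touch,
                 rsa_depth_airflow = rsa_depth_airflow,
                 rsa_depth_touch = rsa_depth_touch,
                 resp_freq = resp_freq),
            class = "effect_spec")
}

#' Context-free effect specification (null world)
#'
#' Both band gains 1 and identical autonomic parameters in the two block
#' types; downstream decoders should perform at chance on such sessions.
#'
#' @param hr common heart rate (BPM).
#' @param rsa_depth common RSA modulation depth.
#' @param ... further arguments passed to [effect_spec()].
#' @export
null_effect_spec <- function(hr = 120, rsa_depth = 0.1, ...) {
  effect_spec(touch_band_gain = 1, airflow_band_gain = 1,
              hr_airflow = hr, hr_touch = hr,
              rsa_depth_airflow = rsa_depth, rsa_depth_touch = rsa_depth, ...)
}

#' Default V-probe channel-to-nucleus map
#'
#' Mimics a 32-contact linear probe spanning the dorso-ventral extent of the
#' amygdala: central (C), lateral (L), basal (B), accessory basal (AB) and
#' paralaminar (Pl) nuclei in dorsal-to-ventral order.
#'
#' @param n_channels number of contacts (default 32).
#' @return character vector of nucleus labels, one per channel.
#' @export
default_channel_map <- function(n_channels = 32L) {
  proportions <- c(C = 4, L = 10, B = 10, AB = 6, Pl = 2) / 32
  counts <- round(proportions * n_channels)
  while (sum(counts) > n_channels) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_channels) counts[which.max(counts)] <- counts[which.max(counts)] + 1L
  rep(names(counts), counts)
}

# Block extents: one row per block with [start, end] = first onset to last
# offset. Context modulation applies over the whole block extent.
block_extents <- function(schedule) {
  ids <- unique(schedule$block_id)
  data.frame(
    block_id = ids,
    block_type = vapply(ids, function(b)
      schedule$block_type[schedule$block_id == b][1L], character(1)),
    start = vapply(ids, function(b) min(schedule$onset[schedule$block_id == b]), numeric(1)),
    end = vapply(ids, function(b) max(schedule$offset[schedule$block_id == b]), numeric(1)),
    stringsAsFactors = FALSE)
}

# FFT-filtered noise: white Gaussian noise shaped by `shape(f)` on the folded
# frequency axis. DC is removed.
shaped_noise <- function(n, fs, shape) {
  x <- rnorm(n)
  f <- (seq_len(n) - 1L) * fs / n
  f_fold <- pmin(f, fs - f)
  h <- shape(f_fold)
  h[1L] <- 0
  Re(fft(fft(x) * h, inverse = TRUE)) / n
}

one_over_f_noise <- function(n, fs, exponent, sd_target) {
  x <- shaped_noise(n, fs, function(f) ifelse(f > 0, f^(-exponent / 2), 0))
  x * (sd_target / sd(x))
}

bandpass_noise <- function(n, fs, lo, hi, sd_target) {
  x <- shaped_noise(n, fs, function(f) as.numeric(f >= lo & f <= hi))
  x * (sd_target / sd(x))
}

#' Simulate multichannel baseline LFP for a session
#'
#' Each channel is the sum of (i) 1/f^a background noise, (ii) band-limited
#' components in the context bands whose power is multiplied by the block's
#' gain inside blocks of the favoured type, (iii) Poisson-timed transient
#' oscillatory bursts, and (iv) brief broadband transients during stimulus
#' presentations (never analysed downstream). Identical `(parameters, seed)`
#' give bit-identical output.
#'
#' @param schedule stimulus schedule from [make_schedule()].
#' @param channel_nuclei per-channel nucleus labels.
#' @param effect an [effect_spec()].
#' @param fs sampling rate (Hz), at least 200.
#' @param seed integer seed.
#' @param noise_sd background noise SD (uV).
#' @param band_sd base SD of each context band component (uV).
#' @param burst_amp burst peak amplitude (uV).
#' @param stim_amp stimulus-transient SD (uV).
#' @param tail seconds of recording appended after the last stimulus.
#' @return object of class `lfp_session` with elements `lfp` (channels x
#'   samples, uV), `fs`, `channel_nuclei`, `schedule`, `duration`, `effect`,
#'   `seed`, and empty `spikes`/`heartbeats` slots.
#' @export
simulate_lfp <- function(schedule, channel_nuclei, effect = effect_spec(),
                         fs = 1000, seed = 1, noise_sd = 50, band_sd = 15,
                         burst_amp = 30, stim_amp = 20, tail = 5) {
  if (is.null(schedule) || nrow(schedule) == 0L) stop("schedule is empty")
  if (fs < 200) stop("fs must be >= 200 Hz to cover the 1-50 Hz band with margin")
  stopifnot(inherits(effect, "effect_spec"))
  n_ch <- length(channel_nuclei)
  duration <- max(schedule$offset) + tail
  n <- as.integer(round(duration * fs))
  tvec <- (seq_len(n) - 1L) / fs
  ext <- block_extents(schedule)

  # sqrt-power envelopes for the two context band groups
  env_for <- function(favoured_type, gain) {
    e <- rep(1, n)
    if (gain != 1) {
      for (b in which(ext$block_type == favoured_type)) {
        i0 <- max(1L, as.integer(floor(ext$start[b] * fs)) + 1L)
        i1 <- min(n, as.integer(ceiling(ext$end[b] * fs)) + 1L)
        e[i0:i1] <- sqrt(gain)
      }
    }
    e
  }
  env_touch <- env_for("touch", effect$touch_band_gain)
  env_airflow <- env_for("airflow", effect$airflow_band_gain)

  seeds <- substream_seeds(seed, n_ch)
  lfp <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    lfp[ch, ] <- with_seed(seeds[ch], {
      bg <- one_over_f_noise(n, fs, effect$background_exponent, noise_sd)
      x <- bg
      # the gain scales the session's whole in-band power during favoured
      # blocks: the background's in-band part and the rhythmic component
      for (band in effect$touch_band) {
        x <- x + env_touch * bandpass_noise(n, fs, band[1L], band[2L], band_sd)
        if (effect$touch_band_gain != 1)
          x <- x + (env_touch - 1) * bandpass_filter(bg, fs, band[1L], band[2L])
      }
      for (band in effect$airflow_band) {
        x <- x + env_airflow * bandpass_noise(n, fs, band[1L], band[2L], band_sd)
        if (effect$airflow_band_gain != 1)
          x <- x + (env_airflow - 1) * bandpass_filter(bg, fs, band[1L], band[2L])
      }
      # transient oscillatory bursts
      n_burst <- rpois(1L, effect$burst_rate * duration)
      if (n_burst > 0) {
        t0s <- runif(n_burst, 0, duration)
        f0s <- runif(n_burst, 5, 45)
        phis <- runif(n_burst, 0, 2 * pi)
        half <- 3 * effect$burst_duration
        for (k in seq_len(n_burst)) {
          i0 <- max(1L, as.integer(floor((t0s[k] - half) * fs)))
          i1 <- min(n, as.integer(ceiling((t0s[k] + half) * fs)))
          tt <- tvec[i0:i1] - t0s[k]
          x[i0:i1] <- x[i0:i1] + burst_amp *
            exp(-tt^2 / (2 * (effect$burst_duration / 2)^2)) *
            cos(2 * pi * f0s[k] * tt + phis[k])
        }
      }
      # stimulus-evoked broadband transients (illustrative, never analysed)
      if (stim_amp > 0) {
        for (ev in seq_len(nrow(schedule))) {
          i0 <- as.integer(floor(schedule$onset[ev] * fs)) + 1L
          i1 <- min(n, as.integer(ceiling(schedule$offset[ev] * fs)))
          m <- i1 - i0 + 1L
          if (m > 4L)
            x[i0:i1] <- x[i0:i1] + stim_amp * hann_window(m) * rnorm(m)
        }
      }
      x
    })
  }
  stopifnot(all(is.finite(lfp)))
  structure(list(lfp = lfp, fs = fs, channel_nuclei = channel_nuclei,
                 schedule = schedule, duration = duration, effect = effect,
                 seed = seed, spikes = NULL, heartbeats = NULL),
            class = "lfp_session")
}

#' Simulate a heartbeat (beat time) series
#'
#' Integrate-and-fire beat generator: the instantaneous rate is the block's
#' base heart rate modulated sinusoidally at the respiratory frequency with
#' the block's RSA depth; between blocks the two base rates are averaged.
#' With `rsa_depth = 0` the series is strictly periodic.
#'
#' @param schedule stimulus schedule (defines block extents).
#' @param effect an [effect_spec()] (heart-rate and RSA fields are used).
#' @param seed integer seed (used only when `n_artifacts > 0`).
#' @param dt integration step (s).
#' @param tail seconds after the last stimulus.
#' @param n_artifacts number of spurious short-interval beats to inject
#'   (for exercising the cleaning filter); default 0.
#' @return sorted numeric vector of beat times (s).
#' @export
simulate_heartbeats <- function(schedule, effect = effect_spec(), seed = 1,
                                dt = 0.001, tail = 5, n_artifacts = 0L) {
  stopifnot(inherits(effect, "effect_spec"))
  duration <- max(schedule$offset) + tail
  n <- as.integer(round(duration / dt))
  tvec <- (seq_len(n) - 1L) * dt
  ext <- block_extents(schedule)
  hr <- rep((effect$hr_airflow + effect$hr_touch) / 2, n)
  depth <- rep((effect$rsa_depth_airflow + effect$rsa_depth_touch) / 2, n)
  for (b in seq_len(nrow(ext))) {
    idx <- tvec >= ext$start[b] & tvec <= ext$end[b]
    if (ext$block_type[b] == "touch") {
      hr[idx] <- effect$hr_touch
      depth[idx] <- effect$rsa_depth_touch
    } else {
      hr[idx] <- effect$hr_airflow
      depth[idx] <- effect$rsa_depth_airflow
    }
  }
  rate <- hr / 60 * (1 + depth * sin(2 * pi * effect$resp_freq * tvec))
  phase <- cumsum(rate * dt)
  beats <- tvec[c(FALSE, diff(floor(phase)) >= 1)]
  if (n_artifacts > 0L && length(beats) > 2L) {
    extra <- with_seed(seed, sample(seq_along(beats)[-1L], n_artifacts))
    beats <- sort(c(beats, beats[extra] - 0.1))   # 100 ms artifact intervals
  }
  beats
}

#' Simulate LFP-coupled spike trains
#'
#' Inhomogeneous Poisson (Bernoulli thinning on the sample grid) spike
#' trains on a subset of channels. With `lfp_coupling > 0` the firing rate
#' is modulated by the channel's band-passed, z-scored LFP, so the
#' spike-triggered average is non-flat and its spectrum peaks inside the
#' coupling band.
#'
#' @param session an `lfp_session`.
#' @param rate mean firing rate (Hz), positive.
#' @param lfp_coupling modulation gain; 0 gives homogeneous Poisson trains.
#' @param coupling_band band (Hz) of the LFP component driving the rate.
#' @param n_units number of units; default one per channel up to 8.
#' @param seed integer seed.
#' @return the session with a `spikes` element: list with one entry per
#'   unit, each `list(unit, channel, times)`.
#' @export
simulate_spikes <- function(session, rate = 5, lfp_coupling = 1,
                            coupling_band = c(10, 17), n_units = NULL,
                            seed = 1) {
  stopifnot(inherits(session, "lfp_session"))
  if (rate <= 0) stop("rate must be positive")
  n_ch <- nrow(session$lfp)
  if (is.null(n_units)) n_units <- min(8L, n_ch)
  channels <- rep_len(seq_len(n_ch), n_units)
  fs <- session$fs
  n <- ncol(session$lfp)
  seeds <- substream_seeds(seed, n_units)
  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    ch <- channels[u]
    lam <- rep(rate, n)
    if (lfp_coupling > 0) {
      drive <- bandpass_filter(session$lfp[ch, ], fs,
                               coupling_band[1L], coupling_band[2L])
      z <- drive / sd(drive)
      lam <- rate * pmax(0, 1 + lfp_coupling * z)
      lam <- lam * (rate / mean(lam))          # keep the mean rate fixed
    }
    p <- pmin(1, lam / fs)
    times <- with_seed(seeds[u], {
      u01 <- runif(n)
      (which(u01 < p) - 1L) / fs
    })
    spikes[[u]] <- list(unit = u, channel = ch, times = times)
  }
  session$spikes <- spikes
  session
}

# Zero-phase FFT brickwall bandpass (synthetic-data plumbing).
bandpass_filter <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f_fold <- pmin(f, fs - f)
  h <- as.numeric(f_fold >= lo & f_fold <= hi)
  Re(fft(fft(x) * h, inverse = TRUE)) / n
}

#' Simulate a complete session
#'
#' Convenience wrapper chaining [make_schedule()], [simulate_lfp()],
#' [simulate_heartbeats()] and [simulate_spikes()] under one master seed
#' that fans out to per-component substreams.
#'
#' @param designs list of [block_design()]s (default 3 airflow + 3 touch,
#'   alternating).
#' @param channel_nuclei channel-to-nucleus map.
#' @param effect an [effect_spec()].
#' @param fs sampling rate (Hz).
#' @param seed master integer seed.
#' @param inter_block_gap,t_start schedule layout (s).
#' @param spikes,heartbeats logical: simulate these components?
#' @param spike_rate,lfp_coupling passed to [simulate_spikes()].
#' @param ... further arguments to [simulate_lfp()].
#' @return an `lfp_session` with `lfp`, `spikes` and `heartbeats` filled in.
#' @export
simulate_session <- function(designs = default_designs(),
                             channel_nuclei = default_channel_map(),
                             effect = effect_spec(), fs = 1000, seed = 1,
                             inter_block_gap = 120, t_start = 10,
                             spikes = TRUE, heartbeats = TRUE,
                             spike_rate = 5, lfp_coupling = 1, ...) {
  seeds <- substream_seeds(seed, 3L)
  schedule <- make_schedule(designs, inter_block_gap, t_start)
  session <- simulate_lfp(schedule, channel_nuclei, effect, fs,
                          seed = seeds[1L], ...)
  if (heartbeats)
    session$heartbeats <- simulate_heartbeats(schedule, effect, seed = seeds[2L])
  if (spikes)
    session <- simulate_spikes(session, rate = spike_rate,
                               lfp_coupling = lfp_coupling, seed = seeds[3L])
  session$seed <- seed
  session
}

#' @export
print.lfp_session <- function(x, ...) {
  cat("<lfp_session> ", nrow(x$lfp), " channels x ", ncol(x$lfp),
      " samples @ ", x$fs, " Hz (", round(x$duration, 1), " s)\n", sep = "")
  cat("  blocks:", paste(block_extents(x$schedule)$block_type, collapse = ", "), "\n")
  cat("  nuclei:", paste(sprintf("%s=%d", names(table(x$channel_nuclei)),
                                 table(x$channel_nuclei)), collapse = " "), "\n")
  if (!is.null(x$spikes)) cat("  units:", length(x$spikes), "\n")
  if (!is.null(x$heartbeats)) cat("  heartbeats:", length(x$heartbeats), "\n")
  invisible(x)
}
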