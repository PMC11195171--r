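# Heart-rate and respiratory-sinus-arrhythmia analysis: inter-beat-interval
# cleaning, modified-Akima interpolation of instantaneous heart rate to a
# 1 ms grid, multitaper RSA-strength estimation in sliding windows, and
# block-level autonomic-state comparisons.

#' Clean a heartbeat series and interpolate instantaneous heart rate
#'
#' Beats producing physiologically impossible inter-beat intervals are
#' removed: an interval is retained iff it lies in `ibi_range_ms`
#' (boundaries inclusive), i.e. heart rate in \[40, 240\] BPM for the
#' default cutoffs. Instantaneous heart rate (60000 / IBI_ms, assigned at
#' the closing beat of each interval) is then interpolated to a 1 ms grid
#' with a modified Akima cubic Hermite interpolant.
#'
#' @param beat_times sorted beat times (s), length >= 3; or a
#'   `heartbeat_series` (cleaning is idempotent).
#' @param ibi_range_ms retained IBI range (ms), default `c(250, 1500)`.
#' @param grid_dt interpolation grid step (s), default 1 ms.
#' @return object of class `heartbeat_series`: `beat_times` (kept beats),
#'   `ibi_ms`, `hr_bpm` (per kept interval), `hr_time`/`hr_instant` (grid),
#'   `removed` (rejected beat times), `grid_dt`.
#' @export
clean_heartbeats <- function(beat_times, ibi_range_ms = c(250, 1500),
                             grid_dt = 0.001) {
  if (inherits(beat_times, "heartbeat_series")) beat_times <- beat_times$beat_times
  beat_times <- as.numeric(beat_times)
  if (is.unsorted(beat_times)) stop("beat_times must be sorted")
  if (length(beat_times) < 3L) stop("need at least 3 beats")
  lo <- ibi_range_ms[1L] / 1000
  hi <- ibi_range_ms[2L] / 1000
  kept <- beat_times[1L]
  removed <- numeric(0)
  last <- beat_times[1L]
  for (b in beat_times[-1L]) {
    ibi <- b - last
    if (ibi >= lo && ibi <= hi) {
      kept <- c(kept, b)
      last <- b
    } else if (ibi > hi) {
      # long gap (dropout): keep the beat, restart intervals from it
      kept <- c(kept, b)
      last <- b
      removed <- c(removed, NA_real_)  # marks a skipped interval
    } else {
      removed <- c(removed, b)
    }
  }
  removed <- removed[!is.na(removed)]
  if (length(kept) < 3L) stop("fewer than 3 valid beats after cleaning")
  ibi <- diff(kept)
  valid <- ibi >= lo & ibi <= hi
  hr_bpm <- 60 / ibi[valid]
  hr_at <- kept[-1L][valid]
  if (length(hr_at) < 2L) stop("fewer than 2 valid intervals after cleaning")
  grid <- seq(hr_at[1L], hr_at[length(hr_at)], by = grid_dt)
  hr_instant <- makima(hr_at, hr_bpm, grid)
  structure(list(beat_times = kept, ibi_ms = ibi * 1000, hr_bpm = hr_bpm,
                 hr_time = grid, hr_instant = hr_instant,
                 removed = removed, grid_dt = grid_dt,
                 ibi_range_ms = ibi_range_ms),
            class = "heartbeat_series")
}

#' @export
print.heartbeat_series <- function(x, ...) {
  cat("<heartbeat_series> ", length(x$beat_times), " beats, ",
      length(x$removed), " removed; mean HR ",
      round(mean(x$hr_bpm), 1), " BPM\n", sep = "")
  invisible(x)
}

# Decimate a uniformly sampled series to target_fs by boxcar (block mean).
decimate_mean <- function(x, fs, target_fs) {
  k <- as.integer(round(fs / target_fs))
  if (k <= 1L) return(list(x = x, fs = fs))
  m <- (length(x) %/% k) * k
  list(x = colMeans(matrix(x[seq_len(m)], nrow = k)), fs = fs / k)
}

# Highest interior local maximum of p; returns index, prominence, and the
# contiguous half-prominence region, or NULL when no interior peak exists.
find_band_peak <- function(p) {
  n <- length(p)
  if (n < 3L) return(NULL)
  cand <- which(diff(sign(diff(p))) < 0) + 1L
  cand <- cand[p[cand] > p[cand - 1L] & p[cand] > p[cand + 1L]]
  if (length(cand) == 0L) return(NULL)
  peak <- cand[which.max(p[cand])]
  prom <- p[peak] - max(min(p[1:peak]), min(p[peak:n]))
  level <- p[peak] - prom / 2
  left <- peak
  while (left > 1L && p[left - 1L] >= level) left <- left - 1L
  right <- peak
  while (right < n && p[right + 1L] >= level) right <- right + 1L
  list(peak = peak, prominence = prom, region = left:right)
}

#' Respiratory-sinus-arrhythmia strength in sliding windows
#'
#' In each 60 s window (hop `hop` seconds) the instantaneous-heart-rate
#' series is decimated and its power spectral density estimated with
#' `tapers` Slepian tapers (time-bandwidth `nw`). Each spectrum is
#' normalized to unit area on the respiratory band, RSA strength is the
#' average power over the highest band-interior peak +/- its half-width at
#' half prominence (band mean when no peak exists), and the per-window
#' strengths are finally centred and scaled as `(P - mu) / mu` where `mu`
#' is the median strength across windows (`mu_mode = "sum"` uses the sum
#' instead).
#'
#' @param hbs a `heartbeat_series` from [clean_heartbeats()].
#' @param window window length (s), default 60.
#' @param hop window hop (s), default 3 (consecutive windows share 57 s).
#' @param tapers number of Slepian tapers, default 7.
#' @param nw time-bandwidth product, default 4 (supports 7 tapers).
#' @param band respiratory band (Hz), default `c(0.25, 0.5)` (15-30
#'   breaths/min).
#' @param analysis_fs sampling rate (Hz) of the decimated heart-rate series
#'   used for spectral estimation.
#' @param mu_mode normalization constant across windows: `"median"`
#'   (default) or `"sum"`.
#' @param schedule optional stimulus schedule; when given, windows are
#'   labelled by the block containing their centre and block-level
#'   summaries are attached.
#' @return object of class `rsa_result`: `windows` data frame
#'   (`center`, `p_raw`, `p_rsa`, `block_type`), `mu`, parameters, and
#'   (with a schedule) `block_summary` with per-block-type mean RSA
#'   strength and mean heart rate.
#' @export
rsa_strength <- function(hbs, window = 60, hop = 3, tapers = 7, nw = 4,
                         band = c(0.25, 0.5), analysis_fs = 10,
                         mu_mode = c("median", "sum"), schedule = NULL) {
  stopifnot(inherits(hbs, "heartbeat_series"))
  mu_mode <- match.arg(mu_mode)
  dec <- decimate_mean(hbs$hr_instant, 1 / hbs$grid_dt, analysis_fs)
  x <- dec$x
  fs <- dec$fs
  t0 <- hbs$hr_time[1L]
  n_win <- as.integer(round(window * fs))
  if (n_win > length(x)) stop("series shorter than one analysis window")
  hop_n <- max(1L, as.integer(round(hop * fs)))
  starts <- seq(1L, length(x) - n_win + 1L, by = hop_n)
  tap <- dpss_tapers(n_win, nw = nw, k = tapers)
  freqs <- (seq_len(n_win %/% 2L + 1L) - 1L) * fs / n_win
  in_band <- freqs >= band[1L] & freqs <= band[2L]
  if (sum(in_band) < 3L) stop("analysis window too short to resolve the respiratory band")
  df <- fs / n_win
  p_raw <- numeric(length(starts))
  centers <- numeric(length(starts))
  spectra <- matrix(NA_real_, length(starts), sum(in_band))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + n_win - 1L)]
    seg <- seg - mean(seg)
    eig <- vapply(seq_len(tapers), function(k) {
      X <- fft(seg * tap[, k])[seq_len(n_win %/% 2L + 1L)]
      Re(X * Conj(X))
    }, numeric(n_win %/% 2L + 1L))
    psd <- rowMeans(eig) / fs
    band_psd <- psd[in_band]
    area <- sum(band_psd) * df
    band_psd <- if (area > 0) band_psd / area else band_psd
    pk <- find_band_peak(band_psd)
    p_raw[i] <- if (is.null(pk)) mean(band_psd) else mean(band_psd[pk$region])
    centers[i] <- t0 + (starts[i] - 1L) / fs + window / 2
    spectra[i, ] <- band_psd
  }
  mu <- if (mu_mode == "median") median(p_raw) else sum(p_raw)
  p_rsa <- (p_raw - mu) / mu
  wins <- data.frame(center = centers, p_raw = p_raw, p_rsa = p_rsa,
                     block_type = NA_character_, stringsAsFactors = FALSE)
  block_summary <- NULL
  if (!is.null(schedule)) {
    ext <- block_extents(schedule)
    for (b in seq_len(nrow(ext))) {
      idx <- wins$center >= ext$start[b] & wins$center <= ext$end[b]
      wins$block_type[idx] <- ext$block_type[b]
    }
    hr_block <- function(type) {
      keep <- rep(FALSE, length(hbs$hr_time))
      for (b in which(ext$block_type == type))
        keep <- keep | (hbs$hr_time >= ext$start[b] & hbs$hr_time <= ext$end[b])
      if (!any(keep)) NA_real_ else mean(hbs$hr_instant[keep])
    }
    block_summary <- data.frame(
      block_type = c("airflow", "touch"),
      mean_p_rsa = c(mean(wins$p_rsa[wins$block_type %in% "airflow"]),
                     mean(wins$p_rsa[wins$block_type %in% "touch"])),
      mean_hr = c(hr_block("airflow"), hr_block("touch")),
      stringsAsFactors = FALSE)
  }
  structure(list(windows = wins, mu = mu, mu_mode = mu_mode,
                 band = band, window = window, hop = hop,
                 tapers = tapers, nw = nw, analysis_fs = fs,
                 band_freqs = freqs[in_band], band_spectra = spectra,
                 block_summary = block_summary),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  cat("<rsa_result> ", nrow(x$windows), " windows of ", x$window, " s (hop ",
      x$hop, " s), ", x$tapers, " tapers, mu(", x$mu_mode, ") = ",
      signif(x$mu, 4), "\n", sep = "")
  if (!is.null(x$block_summary)) print(x$block_summary)
  invisible(x)
}

# One-sided paired t on per-session differences; the degenerate all-zero
# case is reported as t = 0, p = 0.5 (symmetric null).
paired_onesided_t <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 sessions for a paired t-test")
  if (all(diffs == 0) || sd(diffs) == 0) {
    if (all(diffs == 0)) return(list(t = 0, df = n - 1, p = 0.5))
    return(list(t = sign(mean(diffs)) * Inf, df = n - 1,
                p = if (mean(diffs) > 0) 0 else 1))
  }
  tt <- t.test(diffs, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Compare autonomic state across blocks over sessions
#'
#' Paired one-sided t-tests across sessions of the block-level summaries:
#' RSA strength greater in touch than airflow, and heart rate lower in
#' touch than airflow.
#'
#' @param results list of `rsa_result` objects (each computed with a
#'   `schedule`, so block summaries are present), one per session.
#' @return list with elements `rsa` and `hr`, each `list(t, df, p, diffs)`,
#'   plus `n_sessions` and the per-session summary table.
#' @export
compare_blocks <- function(results) {
  if (inherits(results, "rsa_result")) results <- list(results)
  if (length(results) < 2L) stop("need at least 2 sessions")
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (!inherits(r, "rsa_result") || is.null(r$block_summary))
      stop("results[[", i, "]] lacks block labels; run rsa_strength with a schedule")
    bs <- r$block_summary
    a <- bs[bs$block_type == "airflow", ]
    t_ <- bs[bs$block_type == "touch", ]
    if (nrow(a) != 1L || nrow(t_) != 1L || anyNA(c(a$mean_p_rsa, t_$mean_p_rsa)))
      stop("results[[", i, "]] is missing a block type")
    data.frame(session = i, p_rsa_airflow = a$mean_p_rsa,
               p_rsa_touch = t_$mean_p_rsa, hr_airflow = a$mean_hr,
               hr_touch = t_$mean_hr)
  })
  tab <- do.call(rbind, rows)
  rsa_diff <- tab$p_rsa_touch - tab$p_rsa_airflow
  hr_diff <- tab$hr_airflow - tab$hr_touch
  rsa_test <- paired_onesided_t(rsa_diff)
  hr_test <- paired_onesided_t(hr_diff)
  list(rsa = c(rsa_test, list(diffs = rsa_diff)),
       hr = c(hr_test, list(diffs = hr_diff)),
       n_sessions = nrow(tab), sessions = tab)
}
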