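# Time-frequency analysis: complex Morlet continuous wavelet transform of
# baseline windows, band restriction, and training-set-fit min-max
# normalization of spectrogram stacks.

#' Wavelet configuration
#'
#' Complex Morlet (Morlet2-type) CWT parameters. The scale for grid
#' frequency `f` is `a = f0 * fs / (2 * pi * f)` so that the wavelet's peak
#' response falls exactly on `f`. The time axis of the resulting power
#' image is decimated by `time_decim` samples (the CWT is heavily
#' oversampled in time at typical LFP rates).
#'
#' @param fs sampling rate of the input windows (Hz).
#' @param freqs strictly increasing frequency grid (Hz), default 1-50 Hz at
#'   1 Hz spacing.
#' @param f0 central frequency of the mother wavelet (unitless), default 5.
#' @param time_decim keep every `time_decim`-th time column, default 16.
#' @return object of class `wavelet_config`.
#' @export
wavelet_config <- function(fs, freqs = 1:50, f0 = 5, time_decim = 16L) {
  stopifnot(fs > 0, f0 > 0, time_decim >= 1)
  if (any(freqs <= 0) || any(diff(freqs) <= 0))
    stop("freqs must be a positive, strictly increasing grid")
  if (max(freqs) > fs / 2) stop("freq grid exceeds the Nyquist frequency")
  structure(list(fs = fs, freqs = as.numeric(freqs), f0 = f0,
                 time_decim = as.integer(time_decim)),
            class = "wavelet_config")
}

# Core batched CWT power: signals as windows x samples matrix; returns
# array (freq x time x window) of |CWT|^2 with an L1-normalized analytic
# Morlet, computed by FFT convolution with generous zero padding.
cwt_power_core <- function(signals, fs, freqs, f0) {
  n <- ncol(signals)
  n_w <- nrow(signals)
  scales <- f0 / (2 * pi * freqs)            # seconds
  support <- ceiling(4 * max(scales) * fs)
  n_fft <- next_pow2(n + 2L * support)
  pad_off <- support
  xp <- matrix(0, n_fft, n_w)
  xp[pad_off + seq_len(n), ] <- t(signals - rowMeans(signals))
  X <- stats::mvfft(xp)
  omega <- 2 * pi * (seq_len(n_fft) - 1L) / n_fft * fs
  pos <- seq_len(n_fft %/% 2L + 1L)          # analytic wavelet: positive freqs
  out <- array(NA_real_, c(length(freqs), n, n_w))
  for (i in seq_along(freqs)) {
    h <- numeric(n_fft)
    h[pos] <- pi^(-0.25) * sqrt(2 * pi) *
      exp(-0.5 * (scales[i] * omega[pos] - f0)^2)
    w <- stats::mvfft(X * h, inverse = TRUE) / n_fft
    wc <- w[pad_off + seq_len(n), , drop = FALSE]
    out[i, , ] <- Re(wc)^2 + Im(wc)^2
  }
  out
}

#' Continuous-wavelet spectrogram of one baseline window
#'
#' Squared modulus of the complex Morlet CWT on the configured frequency
#' grid. Input may be a numeric vector or one row of a `baseline_set`.
#'
#' @param window numeric signal vector, or a `baseline_set` together with
#'   `which` selecting one window.
#' @param cfg a [wavelet_config()]; its `fs` must match the window's.
#' @param which window row when `window` is a `baseline_set`.
#' @return object of class `spectrogram`: `power` (freq x time, >= 0),
#'   `freq_grid`, `time_grid` (s, relative to window start), `fs`, and
#'   provenance fields `label`, `channel`, `nucleus`, `block_id` when
#'   available.
#' @export
cwt_spectrogram <- function(window, cfg, which = 1L) {
  prov <- list(label = NA_character_, channel = NA_integer_,
               nucleus = NA_character_, block_id = NA_integer_)
  if (inherits(window, "baseline_set")) {
    if (!isTRUE(all.equal(window$fs, cfg$fs)))
      stop("sampling rate of baseline_set (", window$fs,
           ") does not match wavelet_config (", cfg$fs, ")")
    prov <- as.list(window$index[which, c("label", "channel", "nucleus", "block_id")])
    window <- window$signals[which, ]
  }
  stopifnot(is.numeric(window), length(window) >= 8L)
  pw <- cwt_power_core(matrix(window, 1L), cfg$fs, cfg$freqs, cfg$f0)[, , 1L]
  keep <- seq(1L, ncol(pw), by = cfg$time_decim)
  structure(c(list(power = pw[, keep, drop = FALSE],
                   freq_grid = cfg$freqs,
                   time_grid = (keep - 1L) / cfg$fs, fs = cfg$fs), prov),
            class = "spectrogram")
}

#' Spectrogram stack for a whole baseline set
#'
#' Batched CWT of every window in a `baseline_set`, sharing the index table.
#'
#' @param bset a `baseline_set`.
#' @param cfg a [wavelet_config()].
#' @return object of class `spectrogram_stack`: `power` array (freq x time
#'   x window), `freq_grid`, `time_grid`, `index` (the baseline index).
#' @export
spectrogram_stack <- function(bset, cfg) {
  stopifnot(inherits(bset, "baseline_set"))
  if (!isTRUE(all.equal(bset$fs, cfg$fs)))
    stop("sampling rate of baseline_set does not match wavelet_config")
  if (nrow(bset$signals) == 0L) stop("baseline_set is empty")
  pw <- cwt_power_core(bset$signals, cfg$fs, cfg$freqs, cfg$f0)
  keep <- seq(1L, dim(pw)[2L], by = cfg$time_decim)
  structure(list(power = pw[, keep, , drop = FALSE],
                 freq_grid = cfg$freqs,
                 time_grid = (keep - 1L) / cfg$fs,
                 index = bset$index, fs = cfg$fs),
            class = "spectrogram_stack")
}

#' Restrict a spectrogram to a frequency band
#'
#' Drops frequency rows outside `[lo, hi]` (bounds inclusive); provenance
#' and time axis are preserved.
#'
#' @param spec a `spectrogram` or `spectrogram_stack`.
#' @param lo,hi band edges (Hz).
#' @return object of the same class with the restricted frequency grid.
#' @export
restrict_band <- function(spec, lo, hi) {
  stopifnot(lo < hi)
  keep <- spec$freq_grid >= lo & spec$freq_grid <= hi
  if (!any(keep))
    stop("band [", lo, ", ", hi, "] Hz does not intersect the frequency grid")
  out <- spec
  out$freq_grid <- spec$freq_grid[keep]
  if (inherits(spec, "spectrogram_stack")) {
    out$power <- spec$power[keep, , , drop = FALSE]
  } else {
    out$power <- spec$power[keep, , drop = FALSE]
  }
  out
}

#' @export
print.spectrogram_stack <- function(x, ...) {
  d <- dim(x$power)
  cat("<spectrogram_stack> ", d[3L], " spectrograms, ", d[1L],
      " freqs (", min(x$freq_grid), "-", max(x$freq_grid), " Hz) x ",
      d[2L], " timepoints\n", sep = "")
  invisible(x)
}

#' Fit a per-pixel min-max normalizer on training spectrograms
#'
#' Estimates per-pixel extrema from the training set only; applying the
#' normalizer maps values to `[0, 1]`, clipping values outside the training
#' range. A pixel constant across the training set maps to 0.
#'
#' @param train a `spectrogram_stack` or a (freq x time x n) array of
#'   training spectrograms only (never the validation or test items).
#' @param per_image alternative mode: scale each image by its own extrema
#'   (no training statistics retained).
#' @return object of class `minmax_normalizer`.
#' @export
fit_normalizer <- function(train, per_image = FALSE) {
  x <- if (inherits(train, "spectrogram_stack")) train$power else train
  stopifnot(is.array(x), length(dim(x)) == 3L)
  structure(list(min = apply(x, c(1L, 2L), min),
                 max = apply(x, c(1L, 2L), max),
                 per_image = per_image),
            class = "minmax_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' @param normalizer a `minmax_normalizer` from [fit_normalizer()].
#' @param x a `spectrogram_stack`, a (freq x time x n) array, or a single
#'   freq x time matrix.
#' @return same shape as the input, values in `[0, 1]`.
#' @export
apply_normalizer <- function(normalizer, x) {
  if (!inherits(normalizer, "minmax_normalizer"))
    stop("fit_normalizer must be called before apply_normalizer")
  is_stack <- inherits(x, "spectrogram_stack")
  arr <- if (is_stack) x$power else x
  single <- is.matrix(arr)
  if (single) arr <- array(arr, c(dim(arr), 1L))
  if (normalizer$per_image) {
    out <- arr
    for (i in seq_len(dim(arr)[3L])) {
      m <- arr[, , i]
      rng <- range(m)
      out[, , i] <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else 0
    }
  } else {
    if (!all(dim(arr)[1:2] == dim(normalizer$min)))
      stop("spectrogram dimensions do not match the fitted normalizer")
    span <- normalizer$max - normalizer$min
    span[span == 0] <- Inf                  # constant pixel -> 0
    out <- sweep(arr, c(1L, 2L), normalizer$min)
    out <- sweep(out, c(1L, 2L), span, "/")
    out <- pmin(pmax(out, 0), 1)
  }
  if (single) out <- out[, , 1L]
  if (is_stack) {
    x$power <- out
    return(x)
  }
  out
}
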