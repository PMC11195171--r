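# Baseline-window extraction: candidate inter-stimulus intervals between
# same-type stimuli (200 ms guards), a session-wide stability criterion to
# place the window, and extraction of labelled per-channel segments.

#' Candidate inter-stimulus intervals
#'
#' One candidate per within-block pair of consecutive stimuli, spanning
#' stimulus offset + guard to next onset - guard. No candidate precedes the
#' first stimulus of a block. Pairs whose trimmed gap is shorter than
#' `min_length` are skipped (with a message), not an error.
#'
#' @param session an `lfp_session` (or a schedule data frame).
#' @param guard guard interval after offset and before onset (s), default
#'   0.2.
#' @param min_length minimum usable interval length (s), default 0.
#' @return data frame with columns `block_id`, `block_type`, `start`,
#'   `end`, `duration`.
#' @export
isi_segments <- function(session, guard = 0.2, min_length = 0) {
  schedule <- if (inherits(session, "lfp_session")) session$schedule else session
  out <- list()
  for (b in unique(schedule$block_id)) {
    ev <- schedule[schedule$block_id == b, ]
    if (nrow(ev) < 2L) next
    start <- ev$offset[-nrow(ev)] + guard
    end <- ev$onset[-1L] - guard
    keep <- end - start >= max(min_length, 0) & end > start
    if (any(!keep))
      message("isi_segments: skipping ", sum(!keep),
              " short interval(s) in block ", b)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        block_id = b, block_type = ev$block_type[1L],
        start = start[keep], end = end[keep],
        duration = (end - start)[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(block_id = integer(0), block_type = character(0),
                      start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  do.call(rbind, out)
}

#' Select the low-variability baseline window offset
#'
#' Aligns all candidate intervals at their starts, trial-averages the LFP,
#' computes the across-trial standard deviation at each timepoint (per
#' channel, then averaged over channels), and selects the contiguous
#' `window_length` stretch with the lowest mean SD. One offset is chosen
#' per session so that all extracted windows share a time base; ties break
#' toward the earliest offset.
#'
#' @param session an `lfp_session`.
#' @param segments candidate intervals from [isi_segments()]; computed with
#'   defaults when omitted.
#' @param window_length baseline window length (s), default 0.5.
#' @param channels channel indices to use (default all).
#' @return list with `offset` (s, relative to interval start),
#'   `window_length`, `sd_profile` (mean across-trial SD per timepoint) and
#'   `score` (mean SD inside the chosen window).
#' @export
select_stable_window <- function(session, segments = NULL,
                                 window_length = 0.5, channels = NULL) {
  stopifnot(inherits(session, "lfp_session"))
  if (is.null(segments)) segments <- isi_segments(session)
  if (nrow(segments) < 2L) stop("need at least 2 candidate intervals")
  fs <- session$fs
  if (is.null(channels)) channels <- seq_len(nrow(session$lfp))
  common <- min(segments$duration)
  n_win <- as.integer(round(window_length * fs))
  n_common <- as.integer(floor(common * fs))
  if (n_win > n_common)
    stop("window_length (", window_length, " s) exceeds the shortest candidate interval (",
         round(common, 3), " s)")
  starts_idx <- as.integer(round(segments$start * fs)) + 1L
  sd_sum <- numeric(n_common)
  for (ch in channels) {
    trials <- matrix(NA_real_, nrow(segments), n_common)
    for (i in seq_len(nrow(segments)))
      trials[i, ] <- session$lfp[ch, starts_idx[i]:(starts_idx[i] + n_common - 1L)]
    sd_sum <- sd_sum + apply(trials, 2L, sd)
  }
  sd_profile <- sd_sum / length(channels)
  # mean SD over every contiguous window of n_win samples
  cs <- c(0, cumsum(sd_profile))
  win_scores <- (cs[(n_win + 1L):(n_common + 1L)] - cs[1L:(n_common - n_win + 1L)]) / n_win
  best <- which.min(win_scores)              # earliest on ties
  list(offset = (best - 1L) / fs, window_length = window_length,
       sd_profile = sd_profile, score = win_scores[best])
}

#' Extract labelled baseline windows
#'
#' One window per channel per candidate interval, placed `offset` seconds
#' into the interval, labelled by the block type. All windows share the
#' same sample count.
#'
#' @param session an `lfp_session`.
#' @param offset window offset into each interval (s); chosen by
#'   [select_stable_window()] when omitted.
#' @param window_length window length (s), default 0.5.
#' @param segments candidate intervals; computed with defaults when
#'   omitted.
#' @param channels channel indices (default all).
#' @param guard guard interval passed to [isi_segments()] when `segments`
#'   is omitted.
#' @return object of class `baseline_set`: `index` data frame (`window`,
#'   `channel`, `nucleus`, `label`, `block_id`, `t_start`, `t_end`),
#'   `signals` matrix (windows x samples, uV), `fs`, `window_length`.
#' @export
extract_baselines <- function(session, offset = NULL, window_length = 0.5,
                              segments = NULL, channels = NULL, guard = 0.2) {
  stopifnot(inherits(session, "lfp_session"))
  if (is.null(segments)) segments <- isi_segments(session, guard = guard,
                                                  min_length = window_length)
  if (is.null(channels)) channels <- seq_len(nrow(session$lfp))
  fs <- session$fs
  n_win <- as.integer(round(window_length * fs))
  if (nrow(segments) == 0L)
    return(structure(list(index = data.frame(), signals = matrix(0, 0, n_win),
                          fs = fs, window_length = window_length,
                          offset = offset %||% 0),
                     class = "baseline_set"))
  if (is.null(offset))
    offset <- select_stable_window(session, segments, window_length,
                                   channels)$offset
  if (any(segments$start + offset + window_length > segments$end + 1e-9))
    stop("offset + window_length exceeds a candidate interval")
  n_seg <- nrow(segments)
  n_ch <- length(channels)
  idx0 <- as.integer(round((segments$start + offset) * fs)) + 1L
  index <- data.frame(
    window = seq_len(n_seg * n_ch),
    channel = rep(channels, each = n_seg),
    nucleus = rep(session$channel_nuclei[channels], each = n_seg),
    label = rep(segments$block_type, times = n_ch),
    block_id = rep(segments$block_id, times = n_ch),
    t_start = rep(segments$start + offset, times = n_ch),
    t_end = rep(segments$start + offset + window_length, times = n_ch),
    stringsAsFactors = FALSE)
  signals <- matrix(NA_real_, n_seg * n_ch, n_win)
  r <- 1L
  for (ch in channels) {
    for (s in seq_len(n_seg)) {
      signals[r, ] <- session$lfp[ch, idx0[s]:(idx0[s] + n_win - 1L)]
      r <- r + 1L
    }
  }
  structure(list(index = index, signals = signals, fs = fs,
                 window_length = window_length, offset = offset),
            class = "baseline_set")
}

#' @export
print.baseline_set <- function(x, ...) {
  cat("<baseline_set> ", nrow(x$signals), " windows x ", ncol(x$signals),
      " samples @ ", x$fs, " Hz (offset ", round(x$offset, 3), " s)\n", sep = "")
  if (nrow(x$index) > 0)
    print(table(label = x$index$label, nucleus = x$index$nucleus))
  invisible(x)
}
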