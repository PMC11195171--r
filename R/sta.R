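# Spike-triggered averages of baseline LFP, their Welch power spectra, and
# per-nucleus means across units.

#' Spike-triggered average of baseline LFP for one unit
#'
#' Averages +/- `lag` seconds of the unit's channel LFP around every spike
#' that falls inside an extracted baseline window (with full context inside
#' the recording), separately per block label.
#'
#' @param session an `lfp_session` with spikes.
#' @param baselines a `baseline_set` from [extract_baselines()].
#' @param unit unit index into `session$spikes`.
#' @param lag half-window around each spike (s), default 0.08 (+/- 80 ms).
#' @param keep_snippets retain the per-spike snippet matrices (needed for
#'   [sta_spectrum()]; default TRUE).
#' @return object of class `sta_result`: `lags` (s, symmetric about 0),
#'   per-label `sta` (mean LFP, uV), `n_spikes`, `spectrum` (averaged
#'   per-snippet Welch PSD), `snippets`, and provenance (`unit`, `channel`,
#'   `nucleus`). Labels with no qualifying spikes carry `NULL` entries and
#'   `n_spikes = 0` (an empty-result marker, not an error).
#' @export
spike_triggered_average <- function(session, baselines, unit, lag = 0.08,
                                    keep_snippets = TRUE) {
  stopifnot(inherits(session, "lfp_session"), inherits(baselines, "baseline_set"))
  if (is.null(session$spikes) || unit > length(session$spikes))
    stop("session has no spike train for unit ", unit)
  sp <- session$spikes[[unit]]
  fs <- session$fs
  n_lag <- as.integer(round(lag * fs))
  lags <- (-n_lag):n_lag
  n_samp <- ncol(session$lfp)
  # baseline time intervals are shared across channels
  iv <- unique(baselines$index[, c("t_start", "t_end", "label")])
  out <- list(airflow = NULL, touch = NULL)
  n_spikes <- c(airflow = 0L, touch = 0L)
  spectra <- list(airflow = NULL, touch = NULL)
  snippets <- list(airflow = NULL, touch = NULL)
  for (lab in c("airflow", "touch")) {
    ivl <- iv[iv$label == lab, ]
    if (nrow(ivl) == 0L) next
    qualify <- rep(FALSE, length(sp$times))
    for (r in seq_len(nrow(ivl)))
      qualify <- qualify | (sp$times >= ivl$t_start[r] & sp$times <= ivl$t_end[r])
    centers <- as.integer(round(sp$times[qualify] * fs)) + 1L
    centers <- centers[centers - n_lag >= 1L & centers + n_lag <= n_samp]
    if (length(centers) == 0L) next
    snip <- t(vapply(centers, function(ci)
      session$lfp[sp$channel, (ci - n_lag):(ci + n_lag)], numeric(2L * n_lag + 1L)))
    out[[lab]] <- colMeans(snip)
    n_spikes[lab] <- length(centers)
    spectra[[lab]] <- sta_spectrum(snip, fs)
    if (keep_snippets) snippets[[lab]] <- snip
  }
  structure(list(lags = lags / fs, sta = out, n_spikes = n_spikes,
                 spectrum = spectra, snippets = snippets,
                 unit = sp$unit, channel = sp$channel,
                 nucleus = session$channel_nuclei[sp$channel]),
            class = "sta_result")
}

#' Averaged power spectrum of spike-triggered snippets
#'
#' Welch PSD of each snippet, averaged across snippets: the conditional
#' expectation of the LFP power spectrum given that a spike occurred.
#' By default each snippet forms a single Hann-windowed segment (snippets
#' are short relative to the frequencies of interest).
#'
#' @param snippets matrix, one snippet per row (uV).
#' @param fs sampling rate (Hz).
#' @param segment_length Welch segment length in samples (default: snippet
#'   length).
#' @param overlap segment overlap fraction (default 0.5).
#' @return data frame with `freq` (Hz) and `power` (averaged PSD).
#' @export
sta_spectrum <- function(snippets, fs, segment_length = NULL, overlap = 0.5) {
  if (is.null(dim(snippets))) snippets <- matrix(snippets, 1L)
  if (nrow(snippets) < 1L) stop("need at least one snippet")
  if (!is.null(segment_length) && segment_length > ncol(snippets))
    stop("segment_length exceeds snippet length")
  welch_psd(snippets, fs, segment_length = segment_length, overlap = overlap)
}

#' Mean spike-triggered average over the units of one nucleus
#'
#' Pointwise mean of per-unit STAs and of their spectra, per block label,
#' across all units recorded in the same nucleus (pooled across sessions
#' when results from several sessions are supplied).
#'
#' @param sta_list list of `sta_result` objects.
#' @param nucleus nucleus label; `NULL` pools all units.
#' @return object of class `msta`: per-label `msta` trace, `spectrum`, the
#'   number of contributing units `n_units`, `lags`, `nucleus`; units with
#'   no qualifying spikes for a label are skipped.
#' @export
mean_sta <- function(sta_list, nucleus = NULL) {
  if (inherits(sta_list, "sta_result")) sta_list <- list(sta_list)
  keep <- if (is.null(nucleus)) sta_list else
    Filter(function(s) identical(s$nucleus, nucleus), sta_list)
  if (length(keep) == 0L) {
    message("mean_sta: no units in nucleus '", nucleus, "'; skipped")
    return(NULL)
  }
  lags <- keep[[1L]]$lags
  out <- list(airflow = NULL, touch = NULL)
  spec <- list(airflow = NULL, touch = NULL)
  n_units <- c(airflow = 0L, touch = 0L)
  for (lab in c("airflow", "touch")) {
    stas <- lapply(keep, function(s) s$sta[[lab]])
    specs <- lapply(keep, function(s) s$spectrum[[lab]])
    ok <- !vapply(stas, is.null, logical(1))
    if (!any(ok)) next
    out[[lab]] <- colMeans(do.call(rbind, stas[ok]))
    pw <- vapply(specs[ok], function(sdf) sdf$power, numeric(nrow(specs[ok][[1L]])))
    spec[[lab]] <- data.frame(freq = specs[ok][[1L]]$freq,
                              power = rowMeans(as.matrix(pw)))
    n_units[lab] <- sum(ok)
  }
  structure(list(lags = lags, msta = out, spectrum = spec,
                 n_units = n_units, nucleus = nucleus %||% "all"),
            class = "msta")
}

#' @export
print.sta_result <- function(x, ...) {
  cat("<sta_result> unit ", x$unit, " (channel ", x$channel, ", ",
      x$nucleus, "): ", x$n_spikes[["airflow"]], " airflow / ",
      x$n_spikes[["touch"]], " touch spikes, lags +/-",
      max(x$lags) * 1000, " ms\n", sep = "")
  invisible(x)
}
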