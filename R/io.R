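# Session-bundle reader/writer and pipeline configuration files. A bundle
# is a directory holding the LFP array (Arrow feather when available,
# full-precision CSV otherwise) plus a JSON metadata document with the
# schedule, channel map, spike and heartbeat times, effect parameters and
# seed. Round-trips are lossless. A documented import shim point is
# `read_session`'s `lfp_reader` argument (vendor formats are out of scope).

#' Write a session bundle
#'
#' @param session an `lfp_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "lfp_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lfp_df <- as.data.frame(t(session$lfp))
  names(lfp_df) <- paste0("ch", seq_len(nrow(session$lfp)))
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_feather(lfp_df, file.path(path, "lfp.feather"))
  } else {
    con <- file(file.path(path, "lfp.csv"), "w")
    writeLines(paste(names(lfp_df), collapse = ","), con)
    write.table(format(lfp_df, digits = 17, trim = TRUE, scientific = TRUE),
                con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    close(con)
  }
  meta <- list(
    schema_version = 1L,
    fs = session$fs,
    duration = session$duration,
    seed = session$seed,
    channel_nuclei = session$channel_nuclei,
    schedule = session$schedule,
    effect = if (!is.null(session$effect)) unclass(session$effect),
    heartbeats = session$heartbeats,
    spikes = if (!is.null(session$spikes))
      lapply(session$spikes, function(s)
        list(unit = s$unit, channel = s$channel, times = s$times)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(path)
}

#' Read a session bundle
#'
#' @param path bundle directory written by [write_session()].
#' @param lfp_reader optional function `(path) -> channels x samples
#'   matrix`, the shim point for importing other recording formats.
#' @return an `lfp_session`.
#' @export
read_session <- function(path, lfp_reader = NULL) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = FALSE)
  if (!is.null(lfp_reader)) {
    lfp <- lfp_reader(path)
  } else if (file.exists(file.path(path, "lfp.feather"))) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("bundle uses feather but the arrow package is unavailable")
    lfp <- t(as.matrix(arrow::read_feather(file.path(path, "lfp.feather"))))
  } else {
    lfp <- t(as.matrix(read.csv(file.path(path, "lfp.csv"))))
  }
  dimnames(lfp) <- NULL
  effect <- if (!is.null(meta$effect)) {
    e <- meta$effect
    as_bands <- function(b) {
      if (is.list(b) && is.list(b[[1L]])) lapply(b, function(x) as.numeric(unlist(x)))
      else list(as.numeric(unlist(b)))
    }
    effect_spec(touch_band = as_bands(e$touch_band),
                touch_band_gain = e$touch_band_gain,
                airflow_band = as_bands(e$airflow_band),
                airflow_band_gain = e$airflow_band_gain,
                burst_rate = e$burst_rate, burst_duration = e$burst_duration,
                background_exponent = e$background_exponent,
                hr_airflow = e$hr_airflow, hr_touch = e$hr_touch,
                rsa_depth_airflow = e$rsa_depth_airflow,
                rsa_depth_touch = e$rsa_depth_touch,
                resp_freq = e$resp_freq)
  }
  spikes <- if (!is.null(meta$spikes) && length(meta$spikes))
    lapply(meta$spikes, function(s)
      list(unit = as.integer(s$unit), channel = as.integer(s$channel),
           times = as.numeric(unlist(s$times))))
  schedule <- data.frame(
    onset = as.numeric(unlist(meta$schedule$onset)),
    offset = as.numeric(unlist(meta$schedule$offset)),
    block_id = as.integer(unlist(meta$schedule$block_id)),
    block_type = as.character(unlist(meta$schedule$block_type)),
    stringsAsFactors = FALSE)
  structure(list(lfp = lfp, fs = meta$fs,
                 channel_nuclei = as.character(unlist(meta$channel_nuclei)),
                 schedule = schedule,
                 duration = meta$duration, effect = effect,
                 seed = meta$seed, spikes = spikes,
                 heartbeats = as.numeric(unlist(meta$heartbeats))),
            class = "lfp_session")
}

#' Read / write a pipeline configuration
#'
#' Declarative YAML mirroring every tunable parameter of the pipeline
#' (block designs, effect specification, window lengths, wavelet grid,
#' training protocol, bands, seeds). Round-trips losslessly.
#'
#' @param config a config list from [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns the config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
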