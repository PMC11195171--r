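# Top-level pipeline driver: simulate -> physiology -> baseline extraction
# -> spectrograms -> decoding (real + shuffled-label null) -> optional band
# ablation -> spike-triggered averages -> report.

#' Default pipeline configuration
#'
#' One declarative document holding every tunable parameter, including all
#' defaults introduced beyond the experimental paradigm (sampling rate,
#' blocks per session, inter-block gap, channel map, spectrogram time
#' decimation, dropout, learning rate, SVM hyperparameters). Intended to be
#' serialized with [write_config()].
#'
#' @param n_sessions simulated sessions.
#' @param n_blocks_per_type blocks of each type per session.
#' @param n_channels recording contacts.
#' @param fs LFP sampling rate (Hz).
#' @param seed master seed.
#' @param effect list of [effect_spec()] arguments.
#' @param models classifiers to train, subset of `c("svm", "cnn")`.
#' @param repeats training repeats per classifier.
#' @param epochs CNN epochs.
#' @param max_per_class per-class cap on dataset size.
#' @param nuclei nuclei to analyse; `NULL` analyses every nucleus with
#'   enough trials.
#' @param run_ablation run the band-ablation stage.
#' @param run_sta run the spike-triggered-average stage.
#' @return nested configuration list (schema version 1).
#' @export
pipeline_config <- function(n_sessions = 2L, n_blocks_per_type = 3L,
                            n_channels = 32L, fs = 1000, seed = 1L,
                            effect = list(), models = "svm",
                            repeats = 20L, epochs = 40L,
                            max_per_class = 300L, nuclei = NULL,
                            run_ablation = FALSE, run_sta = TRUE) {
  list(
    schema_version = 1L,
    seed = as.integer(seed),
    session = list(n_sessions = as.integer(n_sessions),
                   n_blocks_per_type = as.integer(n_blocks_per_type),
                   n_channels = as.integer(n_channels), fs = fs,
                   inter_block_gap = 120, t_start = 10,
                   spike_rate = 5, lfp_coupling = 1,
                   airflow_design = list(), touch_design = list()),
    effect = utils::modifyList(
      list(touch_band = c(10, 17), touch_band_gain = 2.0,
           airflow_band = c(17, 25), airflow_band_gain = 2.0,
           burst_rate = 0.5, burst_duration = 0.1,
           background_exponent = 1.0, hr_airflow = 130, hr_touch = 110,
           rsa_depth_airflow = 0.05, rsa_depth_touch = 0.15,
           resp_freq = 0.35), effect),
    baseline = list(guard = 0.2, window_length = 0.5),
    wavelet = list(freqs = 1:50, f0 = 5, time_decim = 16L),
    physio = list(window = 60, hop = 3, tapers = 7, nw = 4,
                  band = c(0.25, 0.5), analysis_fs = 10,
                  mu_mode = "median"),
    decode = list(models = models, repeats = as.integer(repeats),
                  epochs = as.integer(epochs), batch_size = 20L,
                  lr = 1e-3, dropout = 0.5, pool_stride = 1L,
                  svm_cost = 1, svm_gamma = "median",
                  min_per_class = 20L, max_per_class = max_per_class,
                  nuclei = nuclei,
                  bands = list(c(10, 17), c(17, 25), c(10, 25))),
    ablation = list(run = run_ablation, repeats = 10L),
    sta = list(run = run_sta, lag = 0.08))
}

stage_log <- function(report, stage, t0, items, verbose) {
  elapsed <- as.numeric(Sys.time()) - t0
  if (verbose)
    message(sprintf("[%s] done in %.1f s (%s)", stage, elapsed, items))
  report$log <- rbind(report$log,
                      data.frame(stage = stage, seconds = elapsed,
                                 items = items, stringsAsFactors = FALSE))
  report
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Simulates `n_sessions` sessions, runs the physiology, baseline,
#' spectrogram, decoding (real and shuffled-label null), optional band
#' ablation and spike-triggered-average stages, and assembles a report.
#' Every output carries the configuration hash and seed; identical
#' `(config, seed)` give identical reports.
#'
#' @param config configuration list from [pipeline_config()].
#' @param seed overrides `config$seed` when given.
#' @param out_dir optional directory: writes `accuracy.csv` (tidy table:
#'   session, nucleus, classifier, band, repeat, accuracy, is_null),
#'   `physio.csv`, and `summary.json`.
#' @param verbose log each stage with wall time and item counts.
#' @return report list: `accuracy` (tidy data frame), `physiology`
#'   (block comparison tests), `nucleus_test`, `ablation`, `sta`,
#'   `signal_detected` (per session x nucleus x classifier),
#'   `config_hash`, `seed`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         out_dir = NULL, verbose = TRUE) {
  seed <- as.integer(seed %||% config$seed)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  report <- list(config_hash = config_hash, seed = seed,
                 log = data.frame())

  effect <- do.call(effect_spec, config$effect)
  sc <- config$session
  seeds <- substream_seeds(seed, sc$n_sessions + 2L)
  run_stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    list(res = res, t0 = t0)
  }

  # --- simulate ---------------------------------------------------------
  designs <- unlist(lapply(seq_len(sc$n_blocks_per_type), function(i) list(
    do.call(block_design, c(list("airflow"), sc$airflow_design)),
    do.call(block_design, c(list("touch"), sc$touch_design)))),
    recursive = FALSE)
  st <- run_stage("simulate", {
    lapply(seq_len(sc$n_sessions), function(i)
      simulate_session(designs = designs,
                       channel_nuclei = default_channel_map(sc$n_channels),
                       effect = effect, fs = sc$fs, seed = seeds[i],
                       inter_block_gap = sc$inter_block_gap,
                       t_start = sc$t_start, spike_rate = sc$spike_rate,
                       lfp_coupling = sc$lfp_coupling))
  })
  sessions <- st$res
  report <- stage_log(report, "simulate", st$t0,
                      paste(length(sessions), "sessions"), verbose)

  # --- physiology -------------------------------------------------------
  st <- run_stage("physio", {
    lapply(sessions, function(s) {
      hbs <- clean_heartbeats(s$heartbeats)
      rsa_strength(hbs, window = config$physio$window, hop = config$physio$hop,
                   tapers = config$physio$tapers, nw = config$physio$nw,
                   band = config$physio$band,
                   analysis_fs = config$physio$analysis_fs,
                   mu_mode = config$physio$mu_mode, schedule = s$schedule)
    })
  })
  rsa_results <- st$res
  physiology <- if (length(rsa_results) >= 2L) compare_blocks(rsa_results)
  report <- stage_log(report, "physio", st$t0,
                      paste(length(rsa_results), "sessions"), verbose)

  # --- baselines + spectrograms ----------------------------------------
  st <- run_stage("extract+spectro", {
    lapply(sessions, function(s) {
      bset <- extract_baselines(s, window_length = config$baseline$window_length,
                                guard = config$baseline$guard)
      cfg <- wavelet_config(s$fs, freqs = config$wavelet$freqs,
                            f0 = config$wavelet$f0,
                            time_decim = config$wavelet$time_decim)
      spectrogram_stack(bset, cfg)
    })
  })
  stacks <- st$res
  report <- stage_log(report, "extract+spectro", st$t0,
                      paste(sum(vapply(stacks, function(s) dim(s$power)[3L],
                                       numeric(1))), "spectrograms"), verbose)

  # --- decoding ---------------------------------------------------------
  dc <- config$decode
  protocol <- training_protocol(repeats = dc$repeats, epochs = dc$epochs,
                                batch_size = dc$batch_size, lr = dc$lr,
                                dropout = dc$dropout,
                                pool_stride = dc$pool_stride,
                                svm_cost = dc$svm_cost,
                                svm_gamma = dc$svm_gamma,
                                min_per_class = dc$min_per_class)
  st <- run_stage("train", {
    rows <- list()
    dists <- list()
    for (si in seq_along(stacks)) {
      stack <- stacks[[si]]
      nuclei <- dc$nuclei %||% unique(stack$index$nucleus)
      for (nu in nuclei) {
        ds <- tryCatch(
          with_seed(seeds[sc$n_sessions + 1L],
                    build_dataset(stack, nu, min_per_class = dc$min_per_class,
                                  max_per_class = dc$max_per_class,
                                  session = si)),
          error = function(e) {
            message("skipping session ", si, " nucleus ", nu, ": ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(ds)) next
        for (mdl in dc$models) {
          d <- accuracy_distribution(ds, mdl, protocol,
                                     seed = seeds[si] + match(mdl, dc$models))
          key <- paste(si, nu, mdl, sep = "/")
          dists[[key]] <- d
          rows[[length(rows) + 1L]] <- data.frame(
            session = si, nucleus = nu, classifier = mdl, band = "full",
            rep = seq_len(protocol$repeats),
            accuracy = c(d$accuracies, d$null_accuracies),
            is_null = rep(c(FALSE, TRUE), each = protocol$repeats))
        }
      }
    }
    list(rows = rows, dists = dists)
  })
  accuracy <- if (length(st$res$rows)) do.call(rbind, st$res$rows) else
    data.frame()
  dists <- st$res$dists
  report <- stage_log(report, "train", st$t0,
                      paste(length(dists), "classifier fits x",
                            protocol$repeats, "repeats"), verbose)

  signal_detected <- if (length(dists))
    data.frame(cell = names(dists),
               separated = vapply(dists, separates_from_null, logical(1)),
               row.names = NULL)
  nucleus_test <- NULL
  by_nucleus <- split(dists, vapply(strsplit(names(dists), "/"),
                                    `[`, character(1), 2L))
  if (length(by_nucleus) >= 2L) {
    samples <- lapply(by_nucleus, function(l)
      unlist(lapply(l, function(d) d$accuracies)))
    counts <- table(default_channel_map(sc$n_channels))
    nucleus_test <- cross_nucleus_test(samples,
                                       channel_counts = stats::setNames(
                                         as.numeric(counts), names(counts)))
  }

  # --- band ablation ----------------------------------------------------
  ablation <- NULL
  if (isTRUE(config$ablation$run)) {
    st <- run_stage("ablate", {
      nuclei <- dc$nuclei %||% unique(stacks[[1L]]$index$nucleus)
      band_ablation(stacks[[1L]], nuclei[1L], bands = dc$bands,
                    model = dc$models[1L],
                    protocol = training_protocol(
                      repeats = config$ablation$repeats, epochs = dc$epochs,
                      batch_size = dc$batch_size, lr = dc$lr,
                      dropout = dc$dropout, svm_cost = dc$svm_cost,
                      svm_gamma = dc$svm_gamma),
                    seed = seeds[sc$n_sessions + 2L],
                    max_per_class = dc$max_per_class)
    })
    ablation <- st$res
    report <- stage_log(report, "ablate", st$t0,
                        paste(nrow(ablation$summary), "bands"), verbose)
  }

  # --- spike-triggered averages ----------------------------------------
  sta <- NULL
  if (isTRUE(config$sta$run)) {
    st <- run_stage("sta", {
      s1 <- sessions[[1L]]
      bset <- extract_baselines(s1, window_length = config$baseline$window_length,
                                guard = config$baseline$guard)
      stas <- lapply(seq_along(s1$spikes), function(u)
        spike_triggered_average(s1, bset, u, lag = config$sta$lag,
                                keep_snippets = FALSE))
      nuclei <- unique(vapply(stas, function(s) s$nucleus, character(1)))
      mstas <- lapply(nuclei, function(nu) mean_sta(stas, nu))
      names(mstas) <- nuclei
      list(per_unit = stas, per_nucleus = mstas)
    })
    sta <- st$res
    report <- stage_log(report, "sta", st$t0,
                        paste(length(sta$per_unit), "units"), verbose)
  }

  report$accuracy <- accuracy
  report$physiology <- physiology
  report$distributions <- dists
  report$signal_detected <- signal_detected
  report$nucleus_test <- nucleus_test
  report$ablation <- ablation
  report$sta <- sta

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(accuracy, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    if (!is.null(physiology))
      write.csv(physiology$sessions, file.path(out_dir, "physio.csv"),
                row.names = FALSE)
    summary <- list(
      config_hash = config_hash, seed = seed,
      quantiles = lapply(dists, function(d)
        list(real = as.list(d$quantiles), null = as.list(d$null_quantiles))),
      signal_detected = signal_detected,
      physiology = if (!is.null(physiology))
        list(rsa_p = physiology$rsa$p, hr_p = physiology$hr$p),
      nucleus_test = nucleus_test,
      ablation = if (!is.null(ablation)) ablation$summary)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}
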