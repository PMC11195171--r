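# Decoding: per-(session, nucleus) datasets of labelled baseline
# spectrograms, the bootstrap-balanced 80/10/10 training protocol, CNN and
# RBF-SVM classifiers, shuffled-label null distributions, frequency-band
# ablation and cross-nucleus comparisons.

#' Training protocol
#'
#' The repeated-training protocol shared by both classifiers: bootstrap
#' balancing of the minority class to parity, a stratified 80/10/10
#' train/validation/test split with equal class representation in each
#' subset, 50 independently re-initialized and re-split repeats, minibatch
#' Adam for the CNN, and the SVM hyperparameters.
#'
#' @param repeats independent training repeats (default 50).
#' @param epochs CNN training epochs (default 40).
#' @param batch_size CNN minibatch size (default 20).
#' @param lr Adam learning rate (default 1e-3).
#' @param dropout CNN dropout rate (default 0.5).
#' @param pool_stride CNN max-pool stride (default 1).
#' @param svm_cost SVM regularization constant C (default 1).
#' @param svm_gamma RBF kernel width: `"median"` for the median heuristic
#'   (1 / median squared pairwise distance of training points) or a number.
#' @param min_per_class minimum trials per class required of a dataset.
#' @param train_frac,val_frac split fractions; the test fraction is the
#'   remainder.
#' @return object of class `training_protocol`.
#' @export
training_protocol <- function(repeats = 50L, epochs = 40L, batch_size = 20L,
                              lr = 1e-3, dropout = 0.5, pool_stride = 1L,
                              svm_cost = 1, svm_gamma = "median",
                              min_per_class = 20L, train_frac = 0.8,
                              val_frac = 0.1) {
  stopifnot(repeats >= 1, epochs >= 1, batch_size >= 2,
            train_frac > 0, val_frac >= 0, train_frac + val_frac < 1)
  structure(list(repeats = as.integer(repeats), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 dropout = dropout, pool_stride = as.integer(pool_stride),
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 min_per_class = as.integer(min_per_class),
                 train_frac = train_frac, val_frac = val_frac),
            class = "training_protocol")
}

#' Build a labelled decoding dataset for one nucleus
#'
#' Groups the baseline spectrograms of one anatomical region (nucleus) in
#' one session into a single labelled dataset.
#'
#' @param stack a `spectrogram_stack`.
#' @param nucleus nucleus label to select; `NULL` uses all windows.
#' @param min_per_class minimum windows per class (default 20).
#' @param max_per_class optional cap per class (windows subsampled without
#'   replacement, for bounded run times).
#' @param session session identifier carried as provenance.
#' @return object of class `decode_dataset`: `x` (freq x time x n array),
#'   `y` (factor airflow/touch), `freq_grid`, `time_grid`, `nucleus`,
#'   `session`, `n_channels`.
#' @export
build_dataset <- function(stack, nucleus = NULL, min_per_class = 20L,
                          max_per_class = Inf, session = NA) {
  stopifnot(inherits(stack, "spectrogram_stack"))
  idx <- stack$index
  sel <- if (is.null(nucleus)) seq_len(nrow(idx)) else which(idx$nucleus == nucleus)
  if (length(sel) == 0L)
    stop("no spectrograms for nucleus '", nucleus, "'")
  y <- idx$label[sel]
  counts <- table(factor(y, levels = c("airflow", "touch")))
  if (any(counts == 0L))
    stop("a class is absent in nucleus '", nucleus %||% "all", "': ",
         paste(names(counts), counts, collapse = ", "))
  if (any(counts < min_per_class))
    stop("fewer than ", min_per_class, " trials in a class for nucleus '",
         nucleus %||% "all", "'")
  if (is.finite(max_per_class)) {
    keep <- unlist(lapply(c("airflow", "touch"), function(cl) {
      cl_idx <- sel[y == cl]
      if (length(cl_idx) > max_per_class)
        sort(sample(cl_idx, max_per_class)) else cl_idx
    }))
    sel <- sort(keep)
    y <- idx$label[sel]
  }
  structure(list(x = stack$power[, , sel, drop = FALSE],
                 y = factor(y, levels = c("airflow", "touch")),
                 freq_grid = stack$freq_grid, time_grid = stack$time_grid,
                 nucleus = nucleus %||% "all", session = session,
                 n_channels = length(unique(idx$channel[sel]))),
            class = "decode_dataset")
}

#' @export
print.decode_dataset <- function(x, ...) {
  cat("<decode_dataset> ", x$nucleus, ": ", dim(x$x)[3L], " spectrograms (",
      paste(table(x$y), collapse = " / "), "), ",
      dim(x$x)[1L], "x", dim(x$x)[2L], " pixels, ",
      x$n_channels, " channels\n", sep = "")
  invisible(x)
}

# Bootstrap-balance to parity with a stratified 80/10/10 split. Each
# class's unique windows are first partitioned 80/10/10, then the
# minority class (ties: touch, which the paradigm under-samples) is
# resampled with replacement *within each subset* up to the majority
# class's subset sizes. Partition-first keeps balancing from ever placing
# copies of one window on both sides of the split (no test-set leakage)
# while preserving the protocol's subset arithmetic (e.g. 300 + 200
# windows -> 480/60/60). Returns index vectors into the dataset (the
# minority entries may repeat within a subset) and the training labels
# (shuffled when requested).
balance_and_split <- function(y, protocol, shuffle_labels = FALSE) {
  idx_a <- which(y == "airflow")
  idx_t <- which(y == "touch")
  m <- max(length(idx_a), length(idx_t))
  n_tr <- floor(protocol$train_frac * m)
  n_val <- floor(protocol$val_frac * m)
  n_te <- m - n_tr - n_val
  if (n_tr < 2L || n_te < 1L) stop("dataset too small to split")
  minority_touch <- length(idx_t) <= length(idx_a)
  split_class <- function(ii, resample) {
    ii <- ii[sample.int(length(ii))]     # permute, then cut by fractions
    k_tr <- floor(protocol$train_frac * length(ii))
    k_val <- floor(protocol$val_frac * length(ii))
    parts <- list(train = ii[seq_len(k_tr)],
                  val = ii[k_tr + seq_len(k_val)],
                  test = ii[(k_tr + k_val + 1L):length(ii)])
    target <- c(train = n_tr, val = n_val, test = n_te)
    for (p in names(parts)) {
      if (length(parts[[p]]) == 0L && target[[p]] > 0L)
        stop("dataset too small to split")
      if (resample || length(parts[[p]]) != target[[p]])
        parts[[p]] <- parts[[p]][sample.int(length(parts[[p]]),
                                            target[[p]], replace = TRUE)]
    }
    parts
  }
  sa <- split_class(idx_a, resample = !minority_touch)
  st <- split_class(idx_t, resample = minority_touch)
  train <- c(sa$train, st$train)
  val <- c(sa$val, st$val)
  test <- c(sa$test, st$test)
  y_train <- y[train]
  if (shuffle_labels) y_train <- sample(y_train)
  list(train = train, val = val, test = test, y_train = y_train)
}

svm_gamma_value <- function(feat, protocol) {
  if (is.numeric(protocol$svm_gamma)) return(protocol$svm_gamma)
  n <- nrow(feat)
  sub <- if (n > 150L) feat[sample.int(n, 150L), , drop = FALSE] else feat
  med <- median(dist(sub)^2)
  if (!is.finite(med) || med <= 0) 1 / ncol(feat) else 1 / med
}

#' Train one classifier instance and report its test accuracy
#'
#' One repeat of the protocol: bootstrap balancing, stratified 80/10/10
#' split, per-pixel min-max normalization fitted on the training split
#' only, classifier training (for the CNN, with epoch-wise best-validation
#' model selection), and evaluation on the held-out test set. With
#' `shuffle_labels = TRUE` the training (and validation) labels are
#' permuted while the test set keeps its true labels — one draw of the
#' null protocol.
#'
#' @param dataset a `decode_dataset`.
#' @param model `"svm"` or `"cnn"`.
#' @param protocol a [training_protocol()].
#' @param seed integer seed for this repeat (split, initialization,
#'   shuffling); `NULL` uses the ambient RNG stream.
#' @param shuffle_labels permute training labels (null protocol).
#' @param return_fit also return the fitted classifier and normalizer.
#' @return test-set accuracy (fraction in `[0, 1]`), or a list when
#'   `return_fit = TRUE`.
#' @export
train_once <- function(dataset, model = c("svm", "cnn"),
                       protocol = training_protocol(), seed = NULL,
                       shuffle_labels = FALSE, return_fit = FALSE) {
  stopifnot(inherits(dataset, "decode_dataset"))
  model <- match.arg(model)
  with_seed(seed, {
    sp <- balance_and_split(dataset$y, protocol, shuffle_labels)
    norm <- fit_normalizer(dataset$x[, , sp$train, drop = FALSE])
    x_tr <- apply_normalizer(norm, dataset$x[, , sp$train, drop = FALSE])
    x_te <- apply_normalizer(norm, dataset$x[, , sp$test, drop = FALSE])
    y_te <- dataset$y[sp$test]
    if (model == "svm") {
      feat_tr <- t(matrix(x_tr, prod(dim(x_tr)[1:2]), dim(x_tr)[3L]))
      feat_te <- t(matrix(x_te, prod(dim(x_te)[1:2]), dim(x_te)[3L]))
      gam <- svm_gamma_value(feat_tr, protocol)
      fit <- e1071::svm(x = feat_tr, y = factor(sp$y_train),
                        kernel = "radial", cost = protocol$svm_cost,
                        gamma = gam, scale = FALSE)
      pred <- predict(fit, feat_te)
      acc <- mean(as.character(pred) == as.character(y_te))
    } else {
      x_val <- apply_normalizer(norm, dataset$x[, , sp$val, drop = FALSE])
      y_val <- dataset$y[sp$val]
      if (shuffle_labels) y_val <- sample(y_val)
      net <- cnn_init(dim(x_tr)[1:2],
                      seed = sample.int(.Machine$integer.max - 1L, 1L),
                      pool_stride = protocol$pool_stride,
                      dropout = protocol$dropout)
      net <- cnn_train(net, x_tr, sp$y_train, x_val, y_val,
                       epochs = protocol$epochs,
                       batch_size = protocol$batch_size, lr = protocol$lr)
      pred <- cnn_predict(net, x_te)
      acc <- mean(pred == as.integer(y_te))
      fit <- net
    }
    if (return_fit) list(accuracy = acc, fit = fit, normalizer = norm,
                         split = sp) else acc
  })
}

#' Accuracy distribution over repeated training, with its null
#'
#' Runs [train_once()] `protocol$repeats` times with fresh splits and
#' initializations, and the same number of times under the shuffled-label
#' null protocol, then summarizes both samples by their 5th/50th/95th
#' quantiles.
#'
#' @param dataset a `decode_dataset`.
#' @param model `"svm"` or `"cnn"`.
#' @param protocol a [training_protocol()].
#' @param seed master seed; fans out one substream per repeat.
#' @param include_null also compute the shuffled-label null sample
#'   (default TRUE).
#' @return object of class `accuracy_distribution`: `accuracies`,
#'   `null_accuracies`, `quantiles`, `null_quantiles`, provenance.
#' @export
accuracy_distribution <- function(dataset, model = c("svm", "cnn"),
                                  protocol = training_protocol(), seed = 1,
                                  include_null = TRUE) {
  model <- match.arg(model)
  seeds <- substream_seeds(seed, 2L * protocol$repeats)
  acc <- vapply(seq_len(protocol$repeats), function(i)
    train_once(dataset, model, protocol, seed = seeds[i]), numeric(1))
  null_acc <- if (include_null)
    vapply(seq_len(protocol$repeats), function(i)
      train_once(dataset, model, protocol,
                 seed = seeds[protocol$repeats + i],
                 shuffle_labels = TRUE), numeric(1))
  else numeric(0)
  qs <- c(0.05, 0.5, 0.95)
  structure(list(accuracies = acc, null_accuracies = null_acc,
                 quantiles = quantile(acc, qs, names = TRUE),
                 null_quantiles = if (include_null)
                   quantile(null_acc, qs, names = TRUE) else NULL,
                 model = model, nucleus = dataset$nucleus,
                 session = dataset$session, repeats = protocol$repeats),
            class = "accuracy_distribution")
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat("<accuracy_distribution> ", x$model, " / ", x$nucleus, ": ",
      length(x$accuracies), " repeats\n  accuracy  q5/q50/q95: ",
      paste(sprintf("%.1f%%", 100 * x$quantiles), collapse = " / "), "\n",
      sep = "")
  if (length(x$null_accuracies))
    cat("  null      q5/q50/q95: ",
        paste(sprintf("%.1f%%", 100 * x$null_quantiles), collapse = " / "),
        "\n", sep = "")
  invisible(x)
}

#' Does the real accuracy distribution separate from its null?
#'
#' The separation criterion used in reporting: the 5th percentile of the
#' real accuracy sample exceeds the 95th percentile of the shuffled-label
#' null sample ("no overlap with the null distribution").
#'
#' @param dist an `accuracy_distribution` with a null sample.
#' @return logical.
#' @export
separates_from_null <- function(dist) {
  stopifnot(inherits(dist, "accuracy_distribution"),
            length(dist$null_accuracies) > 0)
  unname(quantile(dist$accuracies, 0.05) >
           quantile(dist$null_accuracies, 0.95))
}

#' Frequency-band ablation
#'
#' Re-trains the classifier on spectrograms restricted to each band and
#' compares with the full-spectrogram distribution.
#'
#' @param stack a `spectrogram_stack` (full frequency grid).
#' @param nucleus nucleus to analyse (`NULL` = all windows).
#' @param bands list of `c(lo, hi)` bands; defaults to the 10-17, 17-25 and
#'   10-25 Hz bands.
#' @param model `"cnn"` (as in the original ablation) or `"svm"`.
#' @param protocol a [training_protocol()] (reduced `repeats` are typical
#'   here).
#' @param seed master seed.
#' @param max_per_class per-class cap passed to [build_dataset()].
#' @return object of class `band_ablation`: named list `distributions`
#'   (full band first) and a `summary` data frame (band, mean, quantiles).
#' @export
band_ablation <- function(stack, nucleus = NULL,
                          bands = list(c(10, 17), c(17, 25), c(10, 25)),
                          model = c("cnn", "svm"),
                          protocol = training_protocol(repeats = 10L),
                          seed = 1, max_per_class = Inf) {
  model <- match.arg(model)
  stopifnot(inherits(stack, "spectrogram_stack"))
  for (b in bands)
    if (!any(stack$freq_grid >= b[1L] & stack$freq_grid <= b[2L]))
      stop("band [", b[1L], ", ", b[2L], "] has no frequency rows")
  labels <- c("full", vapply(bands, function(b)
    paste0(b[1L], "-", b[2L], "Hz"), character(1)))
  seeds <- substream_seeds(seed, length(labels) + 1L)
  dists <- vector("list", length(labels))
  names(dists) <- labels
  for (i in seq_along(labels)) {
    st <- if (i == 1L) stack else restrict_band(stack, bands[[i - 1L]][1L],
                                                bands[[i - 1L]][2L])
    ds <- with_seed(seeds[length(labels) + 1L],
                    build_dataset(st, nucleus, max_per_class = max_per_class))
    dists[[i]] <- accuracy_distribution(ds, model, protocol,
                                        seed = seeds[i], include_null = FALSE)
  }
  summary <- do.call(rbind, lapply(labels, function(l) {
    a <- dists[[l]]$accuracies
    data.frame(band = l, mean = mean(a), q5 = unname(quantile(a, 0.05)),
               q50 = unname(quantile(a, 0.5)),
               q95 = unname(quantile(a, 0.95)), stringsAsFactors = FALSE)
  }))
  structure(list(distributions = dists, summary = summary, model = model,
                 nucleus = nucleus %||% "all"),
            class = "band_ablation")
}

#' @export
print.band_ablation <- function(x, ...) {
  cat("<band_ablation> ", x$model, " / ", x$nucleus, "\n", sep = "")
  print(transform(x$summary, mean = sprintf("%.1f%%", 100 * mean),
                  q5 = NULL, q50 = sprintf("%.1f%%", 100 * q50),
                  q95 = NULL))
  invisible(x)
}

#' Cross-nucleus comparison of decoding accuracy
#'
#' Kruskal-Wallis H-test (one-way ANOVA on ranks) across the per-nucleus
#' accuracy samples, plus — when channel counts are supplied — the Spearman
#' rank correlation between each nucleus's median accuracy and its number
#' of recording contacts.
#'
#' @param dists named list (by nucleus) of `accuracy_distribution` objects
#'   or numeric accuracy vectors; at least 2 groups.
#' @param channel_counts optional named numeric vector of contacts per
#'   nucleus.
#' @return list with `statistic` (H), `p_value`, `medians`, and (when
#'   counts are given) `rank_correlation`.
#' @export
cross_nucleus_test <- function(dists, channel_counts = NULL) {
  if (length(dists) < 2L) stop("need accuracy samples from at least 2 nuclei")
  samples <- lapply(dists, function(d)
    if (inherits(d, "accuracy_distribution")) d$accuracies else as.numeric(d))
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  kt <- kruskal.test(samples)
  medians <- vapply(samples, median, numeric(1))
  out <- list(statistic = unname(kt$statistic), p_value = kt$p.value,
              medians = medians)
  if (!is.null(channel_counts)) {
    common <- intersect(names(medians), names(channel_counts))
    if (length(common) >= 3L)
      out$rank_correlation <- cor(medians[common], channel_counts[common],
                                  method = "spearman")
  }
  out
}
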