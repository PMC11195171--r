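# Dataset construction, the balanced split protocol, SVM decoding against
# an independent oracle, accuracy distributions, and the cross-nucleus
# statistics.

test_that("balancing and the stratified 80/10/10 split follow the stated arithmetic", {
  # 300 airflow + 200 touch -> 300 + 300; train 480, val 60, test 60
  y <- factor(rep(c("airflow", "touch"), c(300, 200)),
              levels = c("airflow", "touch"))
  pr <- training_protocol()
  set.seed(1)
  sp <- lfpcontext:::balance_and_split(y, pr)
  expect_equal(length(sp$train), 480L)
  expect_equal(length(sp$val), 60L)
  expect_equal(length(sp$test), 60L)
  # equal class representation in every subset
  for (part in list(sp$train, sp$val, sp$test))
    expect_equal(unname(table(y[part])), c(length(part) / 2, length(part) / 2),
                 ignore_attr = TRUE)
  # the bootstrap oversamples only the minority class
  expect_true(any(duplicated(c(sp$train, sp$val, sp$test)[
    y[c(sp$train, sp$val, sp$test)] == "touch"])))
  # balancing never places one window on both sides of the split
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  # balanced input still passes through the resampling step
  yb <- factor(rep(c("airflow", "touch"), each = 100),
               levels = c("airflow", "touch"))
  sp2 <- lfpcontext:::balance_and_split(yb, pr)
  expect_equal(length(sp2$train), 160L)
  expect_equal(unname(table(y[sp$train])), c(240, 240), ignore_attr = TRUE)
})

test_that("build_dataset groups by nucleus and enforces class minima", {
  st <- toy_stack(n_per_class = 30)
  ds <- build_dataset(st, "B")
  expect_s3_class(ds, "decode_dataset")
  expect_equal(dim(ds$x)[3], 60L)
  expect_equal(levels(ds$y), c("airflow", "touch"))
  expect_error(build_dataset(st, "AB"), "no spectrograms")
  expect_error(build_dataset(st, "B", min_per_class = 50), "fewer than")
  # per-class cap subsamples both classes
  set.seed(2)
  ds2 <- build_dataset(st, "B", max_per_class = 10)
  expect_equal(unname(table(ds2$y)), c(10L, 10L), ignore_attr = TRUE)
  # absent class errors
  st_bad <- st
  st_bad$index$label <- "airflow"
  expect_error(build_dataset(st_bad, "B"), "absent")
})

test_that("SVM decodes separable spectrograms at least as well as a centroid oracle", {
  st <- toy_stack(n_per_class = 60, shift = 1.2, seed = 3)
  ds <- build_dataset(st, "B")
  acc <- train_once(ds, "svm", seed = 5)
  # independent oracle: nearest class centroid on a fixed split
  set.seed(5)
  n <- dim(st$power)[3]
  feat <- t(matrix(st$power, prod(dim(st$power)[1:2]), n))
  te <- sort(sample(n, 20))
  tr <- setdiff(seq_len(n), te)
  y <- st$index$label
  mu_a <- colMeans(feat[tr[y[tr] == "airflow"], ])
  mu_t <- colMeans(feat[tr[y[tr] == "touch"], ])
  pred <- ifelse(colSums((t(feat[te, ]) - mu_a)^2) <
                   colSums((t(feat[te, ]) - mu_t)^2), "airflow", "touch")
  oracle_acc <- mean(pred == y[te])
  expect_gte(oracle_acc, 0.95)
  expect_gte(acc, 0.95)
})

test_that("indistinguishable classes decode at chance", {
  st <- toy_stack(n_per_class = 60, shift = 0, seed = 4)
  ds <- build_dataset(st, "B")
  accs <- vapply(1:6, function(i) train_once(ds, "svm", seed = i), numeric(1))
  # binomial null band around 0.5 at test n = 12 per repeat, 6 repeats
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("accuracy distributions store consistent quantiles and are deterministic", {
  st <- toy_stack(n_per_class = 40, shift = 0.8, seed = 6)
  ds <- build_dataset(st, "B")
  pr <- training_protocol(repeats = 8)
  d <- accuracy_distribution(ds, "svm", pr, seed = 3)
  expect_length(d$accuracies, 8L)
  expect_length(d$null_accuracies, 8L)
  expect_equal(unname(d$quantiles),
               unname(quantile(d$accuracies, c(0.05, 0.5, 0.95))))
  expect_equal(unname(d$null_quantiles),
               unname(quantile(d$null_accuracies, c(0.05, 0.5, 0.95))))
  d2 <- accuracy_distribution(ds, "svm", pr, seed = 3)
  expect_identical(d$accuracies, d2$accuracies)
  expect_identical(d$null_accuracies, d2$null_accuracies)
  # separable toy: every real repeat decodes essentially perfectly, while
  # a label-shuffled model cannot beat memoryless guessing on average
  # (its accuracy sample is bimodal, so only the mean is constrained)
  expect_gte(min(d$accuracies), 0.9)
  expect_lt(mean(d$null_accuracies), 0.95)
})

test_that("normalizer statistics never observe validation or test items", {
  st <- toy_stack(n_per_class = 30, shift = 0.5, seed = 7)
  ds <- build_dataset(st, "B")
  fit <- train_once(ds, "svm", seed = 11, return_fit = TRUE)
  sp <- fit$split
  tr_only <- fit_normalizer(ds$x[, , sp$train, drop = FALSE])
  expect_identical(fit$normalizer$min, tr_only$min)
  expect_identical(fit$normalizer$max, tr_only$max)
  all_fit <- fit_normalizer(ds$x)
  expect_false(identical(fit$normalizer$min, all_fit$min))
})

test_that("cross-nucleus H-test flags a shifted nucleus and respects exchangeability", {
  set.seed(21)
  base <- rbeta(50, 8, 4)
  same <- list(L = base, B = base, AB = base, C = base)
  r_same <- cross_nucleus_test(same)
  expect_gt(r_same$p_value, 0.9)            # identical samples: H near 0
  shifted <- list(L = base, B = base, AB = base,
                  C = pmin(base + 0.2, 1))
  r_shift <- cross_nucleus_test(shifted)
  expect_lt(r_shift$p_value, 0.01)
  expect_error(cross_nucleus_test(same[1]), "at least 2")
  # accuracy increasing in channel count gives positive rank correlation
  counts <- c(L = 2, B = 4, AB = 8, C = 16)
  accs <- list(L = base * 0.6, B = base * 0.7, AB = base * 0.8, C = base)
  r_cor <- cross_nucleus_test(accs, channel_counts = counts)
  expect_equal(r_cor$rank_correlation, 1)
  # oracle: exhaustive rank computation on the medians
  med <- vapply(accs, median, numeric(1))
  expect_equal(r_cor$rank_correlation,
               cor(rank(med[names(counts)]), rank(counts)))
})
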