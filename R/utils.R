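# Shared numerical helpers: seeding, windows, Welch PSD, Slepian tapers,
# modified Akima interpolation. Internal except where documented.

#' Derive independent substream seeds from one master seed
#'
#' Modules draw their randomness from per-component seeds fanned out from a
#' single session seed, so each stage can be re-run independently and the
#' whole pipeline is reproducible from `(parameters, seed)`.
#'
#' @param seed master integer seed.
#' @param n number of substream seeds to derive.
#' @return integer vector of length `n`, each below 2^31.
#' @export
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a local RNG stream
#'
#' Runs `expr` with the RNG seeded by `seed`, restoring the ambient RNG
#' state afterwards; `seed = NULL` uses the ambient stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann tapers and configurable segment
#' length and overlap. Density scaling: the integral of the one-sided PSD
#' over frequency recovers the signal variance (window power corrected), so
#' a unit-amplitude tone carries integrated power 1/2.
#'
#' @param x numeric vector (one signal) or matrix with one signal per row.
#' @param fs sampling rate (Hz).
#' @param segment_length segment length in samples; default the whole signal
#'   (a single Hann-windowed segment).
#' @param overlap fractional overlap between segments in `[0, 1)`.
#' @param demean subtract the segment mean before tapering.
#' @return data frame with columns `freq` (Hz) and `power` (units^2/Hz);
#'   for a matrix input, the PSD is averaged across rows.
#' @export
welch_psd <- function(x, fs, segment_length = NULL, overlap = 0.5,
                      demean = TRUE) {
  if (is.matrix(x)) {
    ps <- apply(x, 1L, function(r)
      welch_psd(r, fs, segment_length, overlap, demean)$power)
    f <- welch_psd(x[1L, ], fs, segment_length, overlap, demean)$freq
    return(data.frame(freq = f, power = rowMeans(as.matrix(ps))))
  }
  n <- length(x)
  if (is.null(segment_length)) segment_length <- n
  segment_length <- as.integer(segment_length)
  if (segment_length > n)
    stop("segment_length (", segment_length, ") exceeds signal length (", n, ")")
  if (segment_length < 4L)
    stop("segment_length must be at least 4 samples")
  hop <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, n - segment_length + 1L, by = hop)
  w <- hann_window(segment_length)
  u <- sum(w^2)                       # window power normalisation
  nf <- segment_length %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)[seq_len(nf)]
    acc <- acc + Re(X * Conj(X))
  }
  p <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when n even)
  scale2 <- rep(2, nf)
  scale2[1L] <- 1
  if (segment_length %% 2L == 0L) scale2[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1L) * fs / segment_length,
             power = p * scale2)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product; `2*nw - 1` tapers are well concentrated.
#' @param k number of tapers to return.
#' @return `n x k` matrix, columns unit-energy tapers ordered by
#'   concentration.
#' @export
dpss_tapers <- function(n, nw = 4, k = 7) {
  stopifnot(n >= 8, k >= 1, nw > 0, k <= n)
  t_idx <- 0:(n - 1)
  w <- nw / n
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_idx[-1] * (n - t_idx[-1]) / 2
  m <- matrix(0, n, n)
  m[cbind(1:n, 1:n)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- diag_off
  m[cbind(2:n, 1:(n - 1))] <- diag_off
  e <- eigen(m, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tj <- tapers[, j]
    tj <- tj / sqrt(sum(tj^2))
    # sign convention: symmetric tapers positive mean, antisymmetric positive
    # initial slope
    if (abs(sum(tj)) > 1e-8) {
      if (sum(tj) < 0) tj <- -tj
    } else if (tj[2L] - tj[1L] < 0) tj <- -tj
    tapers[, j] <- tj
  }
  tapers
}

#' Modified Akima cubic Hermite interpolation
#'
#' Piecewise-cubic Hermite interpolant whose slopes are the Akima weighted
#' average with the modified weights `|d2 - d1| + |d2 + d1|/2`, which damps
#' the overshoot of the classic Akima scheme near flat regions.
#'
#' @param x,y data points, `x` strictly increasing.
#' @param xout abscissae at which to evaluate; values outside `range(x)` are
#'   clamped to the boundary values.
#' @return numeric vector of interpolated values at `xout`.
#' @export
makima <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2, all(diff(x) > 0))
  if (n == 2L) {
    out <- y[1L] + (y[2L] - y[1L]) * (xout - x[1L]) / (x[2L] - x[1L])
    out[xout <= x[1L]] <- y[1L]
    out[xout >= x[n]] <- y[n]
    return(out)
  }
  d <- diff(y) / diff(x)                       # n-1 secant slopes
  dd <- c(2 * d[1L] - d[2L], d, 2 * d[n - 1L] - d[n - 2L])
  dd <- c(2 * dd[1L] - dd[2L], dd, 2 * dd[length(dd)] - dd[length(dd) - 1L])
  # dd has n+3 entries; slopes at knot i use dd[i..i+3]
  s <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- dd[i]; d2 <- dd[i + 1L]; d3 <- dd[i + 2L]; d4 <- dd[i + 3L]
    w1 <- abs(d4 - d3) + abs(d4 + d3) / 2
    w2 <- abs(d2 - d1) + abs(d2 + d1) / 2
    s[i] <- if (w1 + w2 > 0) (w1 * d2 + w2 * d3) / (w1 + w2) else 0
  }
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= n] <- n - 1L
  h <- x[idx + 1L] - x[idx]
  t_ <- (xout - x[idx]) / h
  t_ <- pmin(pmax(t_, 0), 1)
  h00 <- (1 + 2 * t_) * (1 - t_)^2
  h10 <- t_ * (1 - t_)^2
  h01 <- t_^2 * (3 - 2 * t_)
  h11 <- t_^2 * (t_ - 1)
  h00 * y[idx] + h10 * h * s[idx] + h01 * y[idx + 1L] + h11 * h * s[idx + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
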