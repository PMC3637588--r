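#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft qbeta rnorm runif rpois rexp sd var t.test
#'   approx kmeans cov convolve median pt nextn
#' @importFrom utils head tail
NULL

## numerically stable log(sum(exp(x))) along rows of a matrix
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

## pairwise log(exp(a) + exp(b)), vectorised
logaddexp <- function(a, b) {
  mx <- pmax(a, b)
  out <- mx + log1p(exp(pmin(a, b) - mx))
  i <- !is.finite(mx)
  out[i] <- mx[i]
  out
}

#' Type-II discrete cosine transform
#'
#' Unnormalised DCT-II, `X_k = sum_n x_n cos(pi*(2n+1)*k/(2N))`,
#' computed via an even-symmetric FFT. Coefficient `k` (0-based)
#' corresponds to frequency `k * fs / (2N)`.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @seealso [idct2()] for the inverse.
#' @export
dct2 <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  y <- c(x, rev(x))
  k <- 0:(n - 1L)
  Re(fft(y)[1:n] * exp(-1i * pi * k / (2 * n))) / 2
}

#' Inverse of the type-II discrete cosine transform
#'
#' @param X coefficients as returned by [dct2()].
#' @return reconstructed signal, `idct2(dct2(x)) == x` to machine precision.
#' @export
idct2 <- function(X) {
  n <- length(X)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(Re(X))
  k <- 1:(n - 1L)
  ## rebuild the length-2n spectrum of the even extension:
  ## Y_k = 2 X_k exp(i pi k / 2n), Y_n = 0, Y_{2n-k} = Conj(Y_k)
  Y <- complex(length.out = 2 * n)
  Y[1L] <- 2 * X[1L]
  Y[k + 1L] <- 2 * X[k + 1L] * exp(1i * pi * k / (2 * n))
  Y[2 * n - k + 1L] <- Conj(Y[k + 1L])
  Re(fft(Y, inverse = TRUE))[1:n] / (2 * n)
}

#' Low-pass and decimate a uniformly sampled signal
#'
#' Anti-aliasing (8th-order Butterworth, zero-phase) followed by
#' point decimation. Large rate ratios are handled as a cascade of
#' stages with per-stage factor at most 13 so that the normalised
#' cutoff stays in a numerically comfortable range.
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param fs_in,fs_out input/output sampling rates in Hz; their ratio must
#'   be a whole number.
#' @param cutoff anti-alias cutoff in Hz; default `0.8 * fs_out / 2`.
#' @param order filter order (default 8).
#' @return the decimated signal (vector or matrix as supplied).
#' @export
downsample_signal <- function(x, fs_in, fs_out, cutoff = NULL, order = 8L) {
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("fs_in must be an integer multiple of fs_out")
  }
  ratio <- as.integer(round(ratio))
  was_vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) < ratio) stop("signal shorter than one decimation step")
  factors <- integer(0)
  r <- ratio
  while (r > 13L) {
    f <- max(which(r %% (2:13) == 0L)) + 1L  # largest factor <= 13
    factors <- c(factors, f)
    r <- r %/% f
  }
  factors <- c(factors, r)
  fs <- fs_in
  for (i in seq_along(factors)) {
    f <- factors[i]
    if (f == 1L) next
    fs_next <- fs / f
    wc <- if (i == length(factors) && !is.null(cutoff)) cutoff else 0.8 * fs_next / 2
    bf <- signal::butter(order, wc / (fs / 2), type = "low")
    x <- apply(x, 2L, function(col) zero_phase(bf, col))
    x <- x[seq(1L, nrow(x), by = f), , drop = FALSE]
    fs <- fs_next
  }
  if (was_vec) drop(x) else x
}

## deterministic sub-seed derivation from a master seed (kept < 2^31)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(s)
}

## zero-phase application of an ARMA filter with odd-reflection padding
## (suppresses the edge transients of plain forward-backward filtering on
## signals with a large offset)
zero_phase <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 5000L)
  if (pad > 0L) {
    pre <- 2 * x[1] - x[(pad + 1L):2]
    post <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1L):(pad + n)]
}
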