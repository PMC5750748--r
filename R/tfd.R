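#' Analytic signal via the frequency-domain construction
#'
#' Builds the complex analytic signal whose spectrum is zero at negative
#' frequencies: negative FFT bins are zeroed, strictly positive bins doubled,
#' and the DC bin (plus the Nyquist bin for even length) kept unchanged. The
#' real part of the result equals the input to machine precision.
#'
#' @param x Real numeric vector, length >= 8, all values finite.
#' @param fs Sampling rate in Hz.
#' @return An object of class `analytic_signal` with fields `z` (complex
#'   vector) and `fs`.
#' @export
analytic_signal <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("signal must have at least 8 samples")
  if (!all(is.finite(x))) stop("non-finite values in input")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  structure(list(z = z, fs = fs), class = "analytic_signal")
}

#' Instantaneous frequency and amplitude of an analytic signal
#'
#' IF is the unwrapped-phase derivative scaled by `fs / (2 * pi)`, using
#' central differences in the interior and one-sided differences at the
#' endpoints; IA is the modulus of the analytic signal.
#'
#' @param z An [analytic_signal()].
#' @return List with `if_hz` and `ia`, both the length of the signal.
#' @export
instantaneous_freq_amp <- function(z) {
  stopifnot(inherits(z, "analytic_signal"))
  ph <- unwrap_phase(Arg(z$z))
  n <- length(ph)
  d <- numeric(n)
  d[1] <- ph[2] - ph[1]
  d[n] <- ph[n] - ph[n - 1]
  if (n > 2) d[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
  list(if_hz = d * z$fs / (2 * pi), ia = Mod(z$z))
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Specify a Cohen's-class time-frequency kernel
#'
#' The six supported distributions: `wvd` (Wigner-Ville, no smoothing),
#' `swvd` (time-smoothed WVD, lag-independent window), `spec` (spectrogram),
#' `gkd` (Gaussian product kernel, Choi-Williams type, parameter `sigma`),
#' `mbd` (modified B, lag-independent `cosh^(-2*beta)` smoothing), and
#' `sepk` (separable time window x lag window).
#'
#' @param kind One of `"wvd"`, `"swvd"`, `"spec"`, `"gkd"`, `"mbd"`, `"sepk"`.
#' @param sigma Gaussian kernel parameter (> 0), default 0.8.
#' @param mbd_beta Modified-B parameter in (0, 1), default 0.02.
#' @param window_kind `"hanning"` or `"hamming"` smoothing window.
#' @param window_len Window length in samples; `NULL` means `floor(fs / 4)`
#'   at computation time. Always adjusted to the next odd value so the window
#'   is symmetric.
#' @return An object of class `tfd_kernel`.
#' @export
tfd_kernel <- function(kind = c("wvd", "swvd", "spec", "gkd", "mbd", "sepk"),
                       sigma = 0.8, mbd_beta = 0.02,
                       window_kind = c("hanning", "hamming"),
                       window_len = NULL) {
  kind <- match.arg(kind)
  window_kind <- match.arg(window_kind)
  if (sigma <= 0) stop("sigma must be positive")
  if (mbd_beta <= 0 || mbd_beta >= 1) stop("mbd_beta must lie in (0, 1)")
  structure(list(kind = kind, sigma = sigma, mbd_beta = mbd_beta,
                 window_kind = window_kind, window_len = window_len),
            class = "tfd_kernel")
}

# Symmetric (odd-length) unit-sum smoothing window.
smoothing_window <- function(kind, len) {
  if (len %% 2 == 0) len <- len + 1
  w <- if (kind == "hanning") as.numeric(signal::hanning(len))
       else as.numeric(signal::hamming(len))
  w / sum(w)
}

resolve_window_len <- function(spec, fs) {
  len <- spec$window_len %||% floor(fs / 4)
  if (len %% 2 == 0) len <- len + 1
  len
}

# Circular convolution of each row of `m` with window `w` (centered),
# via FFT along the time (column) axis.
smooth_time <- function(m, w) {
  n <- ncol(m)
  wk <- numeric(n)
  half <- (length(w) - 1) / 2
  idx <- ((-half:half) %% n) + 1
  for (i in seq_along(w)) wk[idx[i]] <- wk[idx[i]] + w[i]
  W <- fft(wk)
  Y <- mvfft(t(m)) * W            # FFT over time for each lag row
  t(mvfft(Y, inverse = TRUE)) / n
}

#' Compute a quadratic time-frequency distribution of a segment
#'
#' Forms the instantaneous autocorrelation `K(n, l) = z(n+l) * Conj(z(n-l))`
#' of the analytic signal, applies the chosen time-lag kernel (time smoothing
#' over `n` and/or lag windowing over `l`), and Fourier-transforms over lag.
#' The output is real by the Hermitian lag symmetry; the imaginary residue is
#' checked and discarded. The grid is one frequency bin per segment sample
#' covering 0 to `fs/2`, one time column per sample. Columns sum to the
#' instantaneous power `|z(t)|^2` for the Wigner-Ville kernel.
#'
#' @param seg An [eeg_segment()] or numeric vector (then `fs` is required).
#' @param spec A [tfd_kernel()].
#' @param fs Sampling rate when `seg` is a bare vector.
#' @return An object of class `tf_image`: fields `values`
#'   (`n_freq x n_time` real matrix), `fs`, `freq_axis` (Hz), `time_axis`
#'   (s), and `kernel`.
#' @export
compute_tfd <- function(seg, spec = tfd_kernel("swvd"), fs = NULL) {
  if (inherits(seg, "eeg_segment")) {
    x <- seg$samples; fs <- seg$fs
  } else {
    x <- as.numeric(seg)
    if (is.null(fs)) stop("fs required when seg is a numeric vector")
  }
  n <- length(x)
  wlen <- resolve_window_len(spec, fs)
  if (spec$kind %in% c("swvd", "spec", "sepk") && n < 2 * wlen)
    stop("segment shorter than twice the smoothing window")
  z <- analytic_signal(x, fs)$z

  if (spec$kind == "spec") {
    vals <- spectrogram_values(z, n, wlen, spec$window_kind)
  } else {
    K <- iaf_matrix(z)                       # n x n, rows = wrapped lag
    K <- apply_kernel(K, spec, fs, wlen)
    Fz <- mvfft(K)
    resid <- max(abs(Im(Fz))) / max(abs(Fz), .Machine$double.eps)
    if (resid > 1e-8)
      warning(sprintf("imaginary residue %.2e exceeds tolerance", resid))
    vals <- Re(Fz) / n
  }
  structure(list(values = vals, fs = fs,
                 freq_axis = (0:(n - 1)) * fs / (2 * n),
                 time_axis = (0:(n - 1)) / fs,
                 kernel = spec),
            class = "tf_image")
}

# Instantaneous autocorrelation K[l, n] = z(n+l) Conj(z(n-l)), lag wrapped
# into rows 1..n (row 1 = lag 0), truncated at the segment edges.
iaf_matrix <- function(z) {
  n <- length(z)
  K <- matrix(0+0i, n, n)
  K[1, ] <- z * Conj(z)
  for (tau in 1:(floor(n / 2) - 1)) {
    idx <- (tau + 1):(n - tau)               # valid time samples (1-based)
    v <- z[idx + tau] * Conj(z[idx - tau])
    K[tau + 1, idx] <- v
    K[n - tau + 1, idx] <- Conj(v)
  }
  K
}

apply_kernel <- function(K, spec, fs, wlen) {
  n <- ncol(K)
  switch(spec$kind,
    wvd = K,
    swvd = smooth_time(K, smoothing_window(spec$window_kind, wlen)),
    sepk = {
      Ks <- smooth_time(K, smoothing_window("hanning", wlen))
      lag_window(Ks, smoothing_window_raw("hamming", wlen))
    },
    mbd = {
      g <- cosh(seq(-floor(n / 2), floor(n / 2)))^(-2 * spec$mbd_beta)
      smooth_time(K, g / sum(g))
    },
    gkd = gkd_smooth(K, spec$sigma),
    stop("unknown kernel kind: ", spec$kind)
  )
}

# Raw (non-normalized) symmetric window used as a lag window.
smoothing_window_raw <- function(kind, len) {
  if (len %% 2 == 0) len <- len + 1
  if (kind == "hanning") as.numeric(signal::hanning(len))
  else as.numeric(signal::hamming(len))
}

# Multiply wrapped-lag rows by a centered lag window (zero outside support).
lag_window <- function(K, w) {
  n <- nrow(K)
  half <- (length(w) - 1) / 2
  g <- numeric(n)
  g[1] <- w[half + 1]
  for (tau in 1:half) {
    if (tau + 1 <= n) g[tau + 1] <- w[half + 1 + tau]
    g[n - tau + 1] <- w[half + 1 - tau]
  }
  K * g
}

# Choi-Williams-type Gaussian product kernel: in the Doppler-lag domain
# Phi(theta, tau) = exp(-theta^2 tau^2 / sigma), applied as lag-dependent
# time smoothing via the FFT along time. Lag zero is untouched, so the time
# marginal is preserved.
gkd_smooth <- function(K, sigma) {
  n <- ncol(K)
  Ft <- t(mvfft(t(K)))                       # FFT over time per lag row
  theta <- 2 * pi * fft_freq_index(n) / n
  taus <- fft_freq_index(n)                  # wrapped lag per row
  for (r in seq_len(n)) {
    tau <- 2 * taus[r]                       # physical lag of z(n+l)z*(n-l)
    if (tau != 0) Ft[r, ] <- Ft[r, ] * exp(-(theta^2 * tau^2) / sigma)
  }
  t(mvfft(t(Ft), inverse = TRUE)) / n
}

# Spectrogram on the shared grid: |STFT|^2 with a centered sliding window,
# zero-padded FFT of length 2n so bins match k * fs / (2n).
spectrogram_values <- function(z, n, wlen, window_kind) {
  w <- smoothing_window_raw(window_kind, wlen)
  half <- (length(w) - 1) / 2
  frames <- matrix(0+0i, 2 * n, n)
  zp <- c(rep(0+0i, half), z, rep(0+0i, half))
  for (t in seq_len(n)) frames[seq_along(w), t] <- zp[t:(t + 2 * half)] * w
  S <- mvfft(frames)
  Mod(S[1:n, , drop = FALSE])^2 / sum(w^2)
}

#' Quantize a time-frequency image to integer gray levels
#'
#' Min-max normalizes to `[0, n_gray_levels - 1]` and rounds half up.
#' A constant input maps to all zeros.
#'
#' @param tf A `tf_image` or numeric matrix.
#' @param n_gray_levels Number of gray levels (>= 2), default 8.
#' @return Integer matrix with values in `0:(n_gray_levels - 1)`.
#' @export
tf_to_image <- function(tf, n_gray_levels = 8) {
  v <- if (inherits(tf, "tf_image")) tf$values else tf
  stopifnot(n_gray_levels >= 2)
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1))
    return(matrix(0L, nrow(v), ncol(v)))
  q <- (v - rng[1]) / diff(rng) * (n_gray_levels - 1)
  matrix(as.integer(floor(q + 0.5)), nrow(v), ncol(v))
}

#' Extract connected time-frequency components and their IF tracks
#'
#' Keeps pixels that are both above `rel_threshold * max` and local maxima
#' along the frequency axis (ridge points), groups them into connected
#' components under 4- or 8-connectivity, and returns each component's
#' per-time ridge as an instantaneous-frequency polyline.
#'
#' @param tf A `tf_image`.
#' @param rel_threshold Relative amplitude threshold in (0, 1), default 0.1.
#' @param connectivity 4 or 8 (default 8).
#' @return List of components; each has `pixels` (two-column matrix of
#'   time/frequency indices), `if_track` (data frame `time_s`, `freq_hz`),
#'   and `peak_energy`.
#' @export
extract_components <- function(tf, rel_threshold = 0.1, connectivity = 8) {
  stopifnot(inherits(tf, "tf_image"), rel_threshold > 0, rel_threshold < 1,
            connectivity %in% c(4, 8))
  v <- tf$values
  nf <- nrow(v); nt <- ncol(v)
  thr <- rel_threshold * max(v)
  up <- rbind(v[-1, , drop = FALSE], -Inf)
  dn <- rbind(-Inf, v[-nf, , drop = FALSE])
  mask <- (v >= thr) & (v >= up) & (v >= dn)
  labels <- label_components(mask, connectivity)
  n_comp <- max(labels)
  if (n_comp == 0) return(list())
  out <- vector("list", n_comp)
  for (cmp in seq_len(n_comp)) {
    w <- which(labels == cmp, arr.ind = TRUE)     # rows: (freq, time)
    times <- sort(unique(w[, 2]))
    ridge <- vapply(times, function(t) {
      rows <- w[w[, 2] == t, 1]
      rows[which.max(v[cbind(rows, t)])]
    }, integer(1))
    out[[cmp]] <- list(
      pixels = cbind(time_index = w[, 2], freq_index = w[, 1]),
      if_track = data.frame(time_s = tf$time_axis[times],
                            freq_hz = tf$freq_axis[ridge]),
      peak_energy = max(v[w])
    )
  }
  out[order(vapply(out, `[[`, 0, "peak_energy"), decreasing = TRUE)]
}

# Two-pass connected-component labeling with union-find.
label_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc]) next
      nb <- integer(0)
      if (rr > 1 && labels[rr - 1, cc]) nb <- c(nb, labels[rr - 1, cc])
      if (cc > 1 && labels[rr, cc - 1]) nb <- c(nb, labels[rr, cc - 1])
      if (connectivity == 8 && cc > 1) {
        if (rr > 1 && labels[rr - 1, cc - 1]) nb <- c(nb, labels[rr - 1, cc - 1])
        if (rr < nr && labels[rr + 1, cc - 1]) nb <- c(nb, labels[rr + 1, cc - 1])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[rr, cc] <- nxt
      } else {
        roots <- vapply(nb, find, integer(1))
        m <- min(roots)
        labels[rr, cc] <- m
        for (r2 in roots) parent[r2] <- m
      }
    }
  }
  if (nxt == 0L) return(labels)
  remap <- integer(nxt)
  roots <- vapply(seq_len(nxt), find, integer(1))
  uniq <- sort(unique(roots))
  remap[uniq] <- seq_along(uniq)
  idx <- labels > 0
  labels[idx] <- remap[roots[labels[idx]]]
  labels
}
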