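#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft mvfft rnorm runif predict prcomp sd t.test var pnorm setNames
#' @importFrom utils read.csv write.csv write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic sub-stream seed derived from a base seed and an index.
# Kept within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

#' Resize a matrix by bilinear interpolation
#'
#' Maps the input matrix onto a regular grid of the requested size using
#' bilinear interpolation of cell-centre coordinates. Used to bring
#' time-frequency images to a fixed resolution before 2D multi-resolution
#' analysis so decomposition shapes do not depend on segment length.
#'
#' @param m Numeric matrix.
#' @param nrow_out,ncol_out Output dimensions.
#' @return Numeric matrix of size `nrow_out` by `ncol_out`.
#' @export
resize_image <- function(m, nrow_out, ncol_out) {
  stopifnot(is.matrix(m), nrow_out >= 2, ncol_out >= 2)
  if (nrow(m) == nrow_out && ncol(m) == ncol_out) return(m)
  interp_weights(nrow(m), nrow_out) %*% m %*% t(interp_weights(ncol(m), ncol_out))
}

# n_out x n_in linear-interpolation weight matrix for the uniform grid map
# seq(1, n_in, length.out = n_out); each row has at most two nonzeros.
interp_weights <- function(n_in, n_out) {
  xi <- seq(1, n_in, length.out = n_out)
  i0 <- pmin(floor(xi), n_in - 1)
  fr <- xi - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0)] <- 1 - fr
  W[cbind(seq_len(n_out), i0 + 1)] <- W[cbind(seq_len(n_out), i0 + 1)] + fr
  W
}

# Centered frequency index for an FFT axis of length n:
# bins 0..n-1 mapped to 0..n/2-1, -n/2..-1 (n even) or symmetric (n odd).
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k < ceiling(n / 2), k, k - n)
}

# Reorder an FFT-layout matrix so frequency zero sits at the centre
# (circular shift by floor(n/2) per axis), and its inverse.
shift_index <- function(n, inverse = FALSE) {
  s <- if (inverse) floor(n / 2) else -floor(n / 2)
  ((0:(n - 1) + s) %% n) + 1
}

fftshift2 <- function(m) {
  m[shift_index(nrow(m)), shift_index(ncol(m)), drop = FALSE]
}

ifftshift2 <- function(m) {
  m[shift_index(nrow(m), inverse = TRUE), shift_index(ncol(m), inverse = TRUE), drop = FALSE]
}
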