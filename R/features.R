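# Texture and moment features extracted from coefficient matrices.
#
# Each sub-band matrix is summarized by eight numbers: four second-order
# texture statistics from a gray-level co-occurrence matrix (contrast,
# correlation, energy, homogeneity) and four moments (mean, variance,
# skewness, Pearson kurtosis).

#' Gray-level co-occurrence matrix of a quantized matrix
#'
#' Quantizes the input with the same min-max rule as [tf_to_image()], then
#' accumulates co-occurrence counts of gray-level pairs over the given pixel
#' offsets (symmetric accumulation by default) and normalizes to sum one.
#'
#' @param m Real matrix.
#' @param n_gray_levels Number of gray levels G (default 8).
#' @param offsets List of integer `c(dy, dx)` offsets; default the four
#'   standard directions `(0,1), (1,0), (1,1), (1,-1)`.
#' @param symmetric Count each pair in both directions (default TRUE).
#' @return List of G x G probability matrices, one per offset.
#' @export
glcm <- function(m, n_gray_levels = 8,
                 offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                 symmetric = TRUE) {
  stopifnot(is.matrix(m), n_gray_levels >= 2)
  q <- tf_to_image(m, n_gray_levels)
  nr <- nrow(q); nc <- ncol(q)
  lapply(offsets, function(off) {
    dy <- off[1]; dx <- off[2]
    rows <- seq_len(nr - abs(dy))
    if (dy < 0) rows <- rows + abs(dy)
    cols <- seq_len(nc - abs(dx))
    if (dx < 0) cols <- cols + abs(dx)
    a <- as.integer(q[rows, cols, drop = FALSE])
    b <- as.integer(q[rows + dy, cols + dx, drop = FALSE])
    counts <- matrix(tabulate(a + b * n_gray_levels + 1L,
                              nbins = n_gray_levels^2),
                     n_gray_levels, n_gray_levels)
    if (symmetric) counts <- counts + t(counts)
    if (sum(counts) > 0) counts <- counts / sum(counts)
    counts
  })
}

glcm_props_one <- function(p) {
  G <- nrow(p)
  k <- matrix(0:(G - 1), G, G)
  l <- t(k)
  contrast <- sum(abs(k - l)^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(k - l)))
  mu_k <- sum(k * p); mu_l <- sum(l * p)
  var_k <- sum((k - mu_k)^2 * p); var_l <- sum((l - mu_l)^2 * p)
  correlation <- if (var_k < 1e-14 || var_l < 1e-14) 1
                 else sum((k - mu_k) * (l - mu_l) * p) / sqrt(var_k * var_l)
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

#' GLCM texture features of a matrix
#'
#' The four co-occurrence properties (contrast, correlation, energy,
#' homogeneity), averaged over the offsets. A constant matrix yields the
#' degenerate single-cell co-occurrence matrix, for which the convention
#' `(0, 1, 1, 1)` is returned (correlation defined as 1).
#'
#' @inheritParams glcm
#' @return Named numeric vector of the four properties.
#' @export
glcm_features <- function(m, n_gray_levels = 8,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                          symmetric = TRUE) {
  mats <- glcm(m, n_gray_levels, offsets, symmetric)
  props <- vapply(mats, glcm_props_one, numeric(4))
  rowMeans(props)
}

#' Moment features of a matrix
#'
#' Sample mean, sample variance, skewness, and Pearson (non-excess)
#' kurtosis of the flattened values. A zero-variance input returns skewness
#' and kurtosis of 0 by convention, keeping all features finite.
#'
#' @param m Numeric matrix or vector (complex input uses the real part).
#' @return Named vector `(mean, variance, skewness, kurtosis)`.
#' @export
moment_features <- function(m) {
  x <- as.vector(m)
  if (is.complex(x)) x <- Re(x)
  stopifnot(length(x) >= 2)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  v <- var(x)
  if (m2 < .Machine$double.eps * max(mu^2, 1)) {
    return(c(mean = mu, variance = 0, skewness = 0, kurtosis = 0))
  }
  c(mean = mu,
    variance = v,
    skewness = mean((x - mu)^3) / m2^1.5,
    kurtosis = mean((x - mu)^4) / m2^2)
}

FEATURE_BLOCK <- c("contrast", "correlation", "energy", "homogeneity",
                   "mean", "variance", "skewness", "kurtosis")

# Eight-feature block for one coefficient matrix: GLCM properties on the
# magnitudes (texture energy of complex coefficients), moments on the real
# parts.
matrix_feature_block <- function(m, n_gray_levels = 8) {
  mag <- if (is.complex(m)) Mod(m) else abs(m)
  c(glcm_features(mag, n_gray_levels), moment_features(m))
}

#' Curvelet feature vector (176 features)
#'
#' Eight features per selected sub-band matrix (four GLCM properties of the
#' coefficient magnitudes, four moments of the real parts), concatenated
#' coarse to fine over the 22 matrices kept by [select_subbands()].
#'
#' @param selected List of 22 coefficient matrices from [select_subbands()].
#' @param n_gray_levels Gray levels for the GLCM quantization (default 8).
#' @return Named numeric vector of length 176, names
#'   `"s<scale>_w<wedge>_<feature>"`.
#' @export
curvelet_feature_vector <- function(selected, n_gray_levels = 8) {
  if (length(selected) != 22)
    stop("expected exactly 22 selected sub-band matrices")
  blocks <- lapply(selected, matrix_feature_block, n_gray_levels = n_gray_levels)
  nm <- names(selected) %||% sprintf("m%d", seq_along(selected))
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- as.vector(t(outer(nm, FEATURE_BLOCK, paste, sep = "_")))
  out
}

#' 2D wavelet feature vector (104 features)
#'
#' The same eight-feature block applied to the 13 sub-bands of a 4-level 2D
#' Haar decomposition, ordered approximation first, then details from the
#' coarsest level to the finest (horizontal, vertical, diagonal within each
#' level).
#'
#' @param dec A `wavelet2d` decomposition with 4 levels.
#' @param n_gray_levels Gray levels for the GLCM quantization (default 8).
#' @return Named numeric vector of length `8 * (3 * levels + 1)`.
#' @export
wavelet_feature_vector <- function(dec, n_gray_levels = 8) {
  stopifnot(inherits(dec, "wavelet2d"))
  if (dec$levels != 4)
    stop("the 2D wavelet feature vector is defined for 4 levels")
  bands <- wavelet_subbands(dec)
  blocks <- lapply(bands, matrix_feature_block, n_gray_levels = n_gray_levels)
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- as.vector(t(outer(names(bands), FEATURE_BLOCK, paste, sep = "_")))
  out
}

#' Baseline 1D DWT features (18 features)
#'
#' Five-level Daubechies-4 decomposition of the raw segment; each of the six
#' sub-bands (approximation plus five details, coarse to fine) contributes
#' its average power (mean of squared coefficients), mean, and standard
#' deviation.
#'
#' @param seg An [eeg_segment()] or numeric vector.
#' @param levels Decomposition depth (default 5).
#' @return Named numeric vector of length `3 * (levels + 1)`.
#' @export
dwt1d_baseline_features <- function(seg, levels = 5) {
  x <- if (inherits(seg, "eeg_segment")) seg$samples else as.numeric(seg)
  if (length(x) < 2^levels) stop("segment too short for the requested depth")
  dec <- dwt1d(x, levels)
  bands <- c(list(approximation = dec$approximation),
             stats::setNames(rev(dec$details),
                             paste0("detail", seq(levels, 1))))
  out <- unlist(lapply(bands, function(b) {
    c(avg_power = mean(b^2), mean = mean(b), sd = if (length(b) > 1) sd(b) else 0)
  }))
  names(out) <- as.vector(t(outer(names(bands), c("avg_power", "mean", "sd"),
                                  paste, sep = "_")))
  out
}
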