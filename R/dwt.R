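# Orthonormal discrete wavelet transforms with periodized boundaries.
#
# Haar analysis pair: a = (x0 + x1)/sqrt(2), d = (x0 - x1)/sqrt(2); the 2D
# transform applies the pair along rows then columns at each level and
# recurses on the approximation (LL) quadrant. Periodization keeps every
# level-k sub-band exactly dim/2^k, so N levels yield 3N + 1 sub-bands.

SQRT2 <- sqrt(2)

haar_step_rows <- function(m) {
  odd <- m[seq(1, nrow(m), 2), , drop = FALSE]
  evn <- m[seq(2, nrow(m), 2), , drop = FALSE]
  rbind((odd + evn) / SQRT2, (odd - evn) / SQRT2)
}

haar_unstep_rows <- function(m) {
  h <- nrow(m) / 2
  a <- m[1:h, , drop = FALSE]
  d <- m[(h + 1):(2 * h), , drop = FALSE]
  out <- matrix(0, 2 * h, ncol(m))
  out[seq(1, 2 * h, 2), ] <- (a + d) / SQRT2
  out[seq(2, 2 * h, 2), ] <- (a - d) / SQRT2
  out
}

#' Multilevel 2D Haar wavelet decomposition
#'
#' Separable orthonormal 2D DWT: each level splits the current approximation
#' into LL (approximation), LH (horizontal detail), HL (vertical detail), and
#' HH (diagonal detail) quadrants and recurses on LL. `levels = N` produces
#' `3 * N + 1` coefficient matrices.
#'
#' @param image Real matrix; both dimensions must be divisible by
#'   `2^levels`.
#' @param levels Decomposition depth (default 4).
#' @param wavelet Mother wavelet; only `"haar"` is implemented for 2D.
#' @return Object of class `wavelet2d`: `approximation` (LL at the deepest
#'   level), `details` (list with `level`, `orientation`, `coefficients`),
#'   `levels`, `wavelet`.
#' @export
dwt2 <- function(image, levels = 4, wavelet = "haar") {
  stopifnot(is.matrix(image), levels >= 1)
  if (wavelet != "haar") stop("only the Haar wavelet is supported in 2D")
  if (nrow(image) %% 2^levels != 0 || ncol(image) %% 2^levels != 0)
    stop("image dimensions must be divisible by 2^levels")
  details <- list()
  cur <- image
  for (k in seq_len(levels)) {
    s <- t(haar_step_rows(t(haar_step_rows(cur))))
    h <- nrow(s) / 2; w <- ncol(s) / 2
    ll <- s[1:h, 1:w, drop = FALSE]
    lh <- s[1:h, (w + 1):(2 * w), drop = FALSE]      # horizontal detail
    hl <- s[(h + 1):(2 * h), 1:w, drop = FALSE]      # vertical detail
    hh <- s[(h + 1):(2 * h), (w + 1):(2 * w), drop = FALSE]
    details[[length(details) + 1]] <- list(level = k, orientation = "horizontal", coefficients = lh)
    details[[length(details) + 1]] <- list(level = k, orientation = "vertical", coefficients = hl)
    details[[length(details) + 1]] <- list(level = k, orientation = "diagonal", coefficients = hh)
    cur <- ll
  }
  structure(list(approximation = cur, details = details, levels = levels,
                 wavelet = wavelet, input_shape = dim(image)),
            class = "wavelet2d")
}

#' Inverse multilevel 2D Haar wavelet transform
#'
#' Exact synthesis inverse of [dwt2()].
#'
#' @param dec A `wavelet2d` decomposition.
#' @return The reconstructed real matrix.
#' @export
idwt2 <- function(dec) {
  stopifnot(inherits(dec, "wavelet2d"))
  cur <- dec$approximation
  for (k in seq(dec$levels, 1)) {
    lv <- Filter(function(d) d$level == k, dec$details)
    get_or <- function(o) Filter(function(d) d$orientation == o, lv)[[1]]$coefficients
    lh <- get_or("horizontal"); hl <- get_or("vertical"); hh <- get_or("diagonal")
    if (!all(dim(cur) == dim(lh)))
      stop("sub-band shape mismatch at level ", k)
    s <- rbind(cbind(cur, lh), cbind(hl, hh))
    cur <- t(haar_unstep_rows(t(haar_unstep_rows(s))))
  }
  cur
}

#' List the coefficient matrices of a 2D wavelet decomposition
#'
#' Ordered coarse to fine: the approximation first, then details from the
#' deepest level down to level 1, orientations horizontal, vertical,
#' diagonal within a level. Used as the feature-extraction ordering.
#'
#' @param dec A `wavelet2d` decomposition.
#' @return Named list of `3 * levels + 1` matrices.
#' @export
wavelet_subbands <- function(dec) {
  stopifnot(inherits(dec, "wavelet2d"))
  out <- list(approximation = dec$approximation)
  for (k in seq(dec$levels, 1)) {
    for (o in c("horizontal", "vertical", "diagonal")) {
      d <- Filter(function(x) x$level == k && x$orientation == o, dec$details)[[1]]
      out[[paste0("level", k, "_", o)]] <- d$coefficients
    }
  }
  out
}

# Daubechies-4 (four vanishing moments, 8 taps) scaling filter.
DB4_LO <- c( 0.230377813308855230, 0.714846570552541500,
             0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
             0.032883011666982945, -0.010597401784997278)

# Periodized single-level analysis with an orthonormal filter pair.
dwt1_step <- function(x, lo) {
  n <- length(x)
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)   # quadrature mirror
  L <- length(lo)
  a <- d <- numeric(n / 2)
  for (i in seq_len(n / 2)) {
    idx <- ((2 * (i - 1)) + seq_len(L) - 1) %% n + 1
    a[i] <- sum(lo * x[idx])
    d[i] <- sum(hi * x[idx])
  }
  list(a = a, d = d)
}

#' Multilevel 1D discrete wavelet transform (Daubechies-4, periodized)
#'
#' Baseline decomposition of a raw segment into `levels` detail bands plus
#' one approximation band. Signal length must be divisible by `2^levels`.
#'
#' @param x Numeric vector.
#' @param levels Depth (default 5).
#' @return List with `approximation` and `details` (list, level 1 = finest).
#' @export
dwt1d <- function(x, levels = 5) {
  x <- as.numeric(x)
  if (length(x) %% 2^levels != 0) stop("length must be divisible by 2^levels")
  details <- vector("list", levels)
  cur <- x
  for (k in seq_len(levels)) {
    s <- dwt1_step(cur, DB4_LO)
    details[[k]] <- s$d
    cur <- s$a
  }
  list(approximation = cur, details = details, levels = levels, wavelet = "db4")
}
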