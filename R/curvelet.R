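# Fast discrete curvelet transform via wedge wrapping.
#
# The transform is a tight frame built in the 2D frequency plane. Scales
# partition frequency into concentric-square annuli (pseudo-radius
# r = max(|w1|, |w2|) normalized to 1 at Nyquist) whose widths halve toward
# DC; scales 2..(n-1) are further split into angular wedges whose count
# doubles every other scale (parabolic scaling), while the coarsest and
# finest scales stay isotropic. All windows are Meyer-type smooth profiles
# chosen so the squared windows sum to exactly one at every frequency, which
# makes the frame tight: Parseval holds and the adjoint is the inverse.
# Each wedge is "wrapped" by cropping its frequency bounding box and taking
# a unitary inverse FFT of the windowed patch, giving a small complex
# coefficient matrix per wedge.

.curvelet_cache <- new.env(parent = emptyenv())

# Meyer-type smooth step: fall(0) = 1, fall(1) = 0, rise = reversed,
# rise^2 + fall^2 = 1 (used for all radial and angular transitions).
meyer_fall_raw <- function(t) {
  out <- numeric(length(t))
  out[t <= 0] <- 1
  mid <- t > 0 & t < 1
  tm <- t[mid]
  out[mid] <- exp(1 - 1 / (1 - exp(1 - 1 / tm)))
  out
}

meyer_pair <- function(t) {
  f <- meyer_fall_raw(t)
  r <- meyer_fall_raw(1 - t)
  nrm <- sqrt(f^2 + r^2)
  list(rise = r / nrm, fall = f / nrm)
}

#' Wedge counts per curvelet scale
#'
#' One isotropic wedge at the coarsest and finest scales; at scale 2 the
#' requested count, doubling every other scale toward finer detail.
#'
#' @param n_scales Number of scales.
#' @param n_angles_scale2 Wedges at scale 2 (multiple of 4).
#' @return Integer vector of length `n_scales`.
#' @export
curvelet_wedge_counts <- function(n_scales, n_angles_scale2) {
  stopifnot(n_scales >= 3, n_angles_scale2 %% 4 == 0, n_angles_scale2 >= 4)
  counts <- integer(n_scales)
  counts[1] <- 1L
  mid <- 2:(n_scales - 1)
  counts[mid] <- as.integer(n_angles_scale2 * 2^floor((mid - 1) / 2))
  counts[n_scales] <- 1L
  counts
}

# Build (and cache) the window system for a grid size / scale layout.
curvelet_system <- function(n1, n2, n_scales, n_angles_scale2) {
  key <- paste(n1, n2, n_scales, n_angles_scale2, sep = "_")
  if (!is.null(.curvelet_cache[[key]])) return(.curvelet_cache[[key]])
  stopifnot(n1 >= 32, n2 >= 32)
  m1 <- (-floor(n1 / 2)):(ceiling(n1 / 2) - 1)   # centered row frequencies
  m2 <- (-floor(n2 / 2)):(ceiling(n2 / 2) - 1)
  R1 <- matrix(m1, n1, n2)
  R2 <- matrix(m2, n1, n2, byrow = TRUE)
  r <- pmax(abs(R1) / (n1 / 2), abs(R2) / (n2 / 2))
  theta <- atan2(R1, R2) %% (2 * pi)

  counts <- curvelet_wedge_counts(n_scales, n_angles_scale2)
  # Radial lowpass per internal boundary b_j = 2^-(n_scales - j).
  lows <- lapply(seq_len(n_scales - 1), function(j) {
    b <- 2^(-(n_scales - j))
    lp <- matrix(0, n1, n2)
    lp[r <= b / 2] <- 1
    tr <- r > b / 2 & r < b
    lp[tr] <- meyer_pair((r[tr] - b / 2) / (b / 2))$fall
    lp
  })
  radial <- vector("list", n_scales)
  radial[[1]] <- lows[[1]]
  if (n_scales > 2) {
    for (j in 2:(n_scales - 1))
      radial[[j]] <- sqrt(pmax(lows[[j]]^2 - lows[[j - 1]]^2, 0))
  }
  radial[[n_scales]] <- sqrt(pmax(1 - lows[[n_scales - 1]]^2, 0))

  wedges <- list()
  for (j in seq_len(n_scales)) {
    nw <- counts[j]
    for (w in seq_len(nw)) {
      U <- if (nw == 1) radial[[j]] else {
        delta <- 2 * pi / nw
        half_tr <- delta / 3          # transition half-width
        a <- (theta - (w - 1) * delta + half_tr) %% (2 * pi)
        V <- numeric(length(a))
        rising <- a < 2 * half_tr
        flat <- a >= 2 * half_tr & a < delta
        falling <- a >= delta & a < delta + 2 * half_tr
        V[rising] <- meyer_pair(a[rising] / (2 * half_tr))$rise
        V[flat] <- 1
        V[falling] <- meyer_pair((a[falling] - delta) / (2 * half_tr))$fall
        radial[[j]] * matrix(V, n1, n2)
      }
      sup <- which(U > 1e-14, arr.ind = TRUE)
      rr <- range(sup[, 1]); cc <- range(sup[, 2])
      win <- U[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      # Wrap the patch so the wedge's peak frequency sits at the FFT origin:
      # coefficients then vary slowly in space (demodulated envelope).
      pk <- which(win == max(win), arr.ind = TRUE)[1, ]
      wedges[[length(wedges) + 1]] <- list(
        scale = j, wedge = w,
        rows = rr[1]:rr[2], cols = cc[1]:cc[2],
        win = win,
        roll_r = ((seq_len(nrow(win)) + pk[1] - 2) %% nrow(win)) + 1,
        roll_c = ((seq_len(ncol(win)) + pk[2] - 2) %% ncol(win)) + 1,
        unroll_r = order(((seq_len(nrow(win)) + pk[1] - 2) %% nrow(win)) + 1),
        unroll_c = order(((seq_len(ncol(win)) + pk[2] - 2) %% ncol(win)) + 1)
      )
    }
  }
  # Squared windows already telescope to one; renormalize pointwise to
  # remove any floating-point residue so the frame is numerically tight.
  total <- matrix(0, n1, n2)
  for (wd in wedges) total[wd$rows, wd$cols] <- total[wd$rows, wd$cols] + wd$win^2
  scl <- 1 / sqrt(total)
  for (i in seq_along(wedges)) {
    wd <- wedges[[i]]
    wedges[[i]]$win <- wd$win * scl[wd$rows, wd$cols]
  }
  sys <- list(n1 = n1, n2 = n2, n_scales = n_scales,
              n_angles_scale2 = n_angles_scale2, counts = counts,
              wedges = wedges)
  .curvelet_cache[[key]] <- sys
  sys
}

#' Forward fast discrete curvelet transform (wrapping)
#'
#' Decomposes an image into complex curvelet coefficients over `n_scales`
#' scales with `n_angles_scale2` orientations at scale 2, doubling every
#' other scale: for the default 5 scales / 8 angles the per-scale wedge
#' counts are 1, 8, 16, 16, 1. The frame is tight, so total coefficient
#' energy equals image energy and [ifdct_wrapping()] reconstructs exactly
#' (machine precision). For a real image the wedge at orientation
#' `theta + pi` carries the same coefficient magnitudes as its partner at
#' `theta`.
#'
#' @param image Real (or complex) matrix, at least 32 x 32.
#' @param n_scales Number of scales (>= 3), default 5.
#' @param n_angles_scale2 Wedges at scale 2, a multiple of 4; default 8.
#' @return Object of class `curvelet2d`: `scales` is a list (one entry per
#'   scale) of lists of complex coefficient matrices (one per wedge), plus
#'   `n_scales`, `n_angles_scale2`, `wedge_counts`, `input_shape`.
#' @export
fdct_wrapping <- function(image, n_scales = 5, n_angles_scale2 = 8) {
  stopifnot(is.matrix(image))
  n1 <- nrow(image); n2 <- ncol(image)
  sys <- curvelet_system(n1, n2, n_scales, n_angles_scale2)
  Xs <- fftshift2(fft(image) / sqrt(n1 * n2))
  scales <- lapply(sys$counts, function(nw) vector("list", nw))
  for (wd in sys$wedges) {
    P <- (Xs[wd$rows, wd$cols, drop = FALSE] * wd$win)[wd$roll_r, wd$roll_c,
                                                       drop = FALSE]
    scales[[wd$scale]][[wd$wedge]] <-
      fft(P, inverse = TRUE) / sqrt(length(P))
  }
  structure(list(scales = scales, n_scales = n_scales,
                 n_angles_scale2 = n_angles_scale2,
                 wedge_counts = sys$counts,
                 input_shape = c(n1, n2), real_input = is.numeric(image)),
            class = "curvelet2d")
}

#' Inverse fast discrete curvelet transform (wrapping)
#'
#' Adjoint reconstruction of the tight frame: exact up to machine precision.
#'
#' @param dec A `curvelet2d` decomposition.
#' @return The reconstructed matrix (real if the input was real).
#' @export
ifdct_wrapping <- function(dec) {
  stopifnot(inherits(dec, "curvelet2d"))
  n1 <- dec$input_shape[1]; n2 <- dec$input_shape[2]
  sys <- curvelet_system(n1, n2, dec$n_scales, dec$n_angles_scale2)
  Xs <- matrix(0+0i, n1, n2)
  for (wd in sys$wedges) {
    cf <- dec$scales[[wd$scale]][[wd$wedge]]
    if (!all(dim(cf) == c(length(wd$rows), length(wd$cols))))
      stop("coefficient shape mismatch at scale ", wd$scale, " wedge ", wd$wedge)
    P <- (fft(cf) / sqrt(length(cf)))[wd$unroll_r, wd$unroll_c, drop = FALSE]
    Xs[wd$rows, wd$cols] <- Xs[wd$rows, wd$cols] + P * wd$win
  }
  out <- fft(ifftshift2(Xs), inverse = TRUE) / sqrt(n1 * n2)
  if (isTRUE(dec$real_input)) Re(out) else out
}

#' Select the non-redundant curvelet sub-bands for feature extraction
#'
#' For a real image, wedges at orientations `theta` and `theta + pi` carry
#' the same information, so only the first half of the wedges (orientations
#' covering the upper half-plane) is kept at the directional scales; the
#' isotropic coarsest and finest scales are kept whole. With 5 scales and 8
#' angles at scale 2 this keeps 1 + 4 + 8 + 8 + 1 = 22 matrices, ordered
#' coarse to fine with ascending wedge index.
#'
#' @param dec A `curvelet2d` decomposition with wedge counts
#'   `[1, 8, 16, 16, 1]` (5 scales, 8 angles).
#' @return Named list of 22 complex coefficient matrices
#'   (`"s<scale>_w<wedge>"`).
#' @export
select_subbands <- function(dec) {
  stopifnot(inherits(dec, "curvelet2d"))
  if (!identical(dec$wedge_counts, c(1L, 8L, 16L, 16L, 1L)))
    stop("sub-band selection expects wedge counts [1, 8, 16, 16, 1]")
  out <- list()
  for (j in seq_len(dec$n_scales)) {
    nw <- dec$wedge_counts[j]
    keep <- if (nw == 1) 1L else seq_len(nw / 2)
    for (w in keep)
      out[[sprintf("s%d_w%d", j, w)]] <- dec$scales[[j]][[w]]
  }
  out
}
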