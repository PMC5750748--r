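test_that("4-level Haar produces 13 sub-bands with exact reconstruction", {
  set.seed(21)
  img <- matrix(rnorm(64 * 64), 64)
  dec <- dwt2(img, levels = 4)
  expect_length(dec$details, 12)
  expect_length(wavelet_subbands(dec), 13)
  expect_equal(dim(dec$approximation), c(4, 4))
  for (d in dec$details)
    expect_equal(dim(d$coefficients), c(64, 64) / 2^d$level)

  expect_lt(max(abs(idwt2(dec) - img)), 1e-10)

  # Parseval for the orthonormal transform
  en <- sum(dec$approximation^2) +
    sum(vapply(dec$details, function(d) sum(d$coefficients^2), 0))
  expect_lt(abs(en - sum(img^2)) / sum(img^2), 1e-9)
})

test_that("Haar of a constant image is the scaled constant with zero details", {
  dec <- dwt2(matrix(3, 32, 32), 4)
  expect_true(all(abs(dec$approximation - 3 * 2^4) < 1e-12))
  for (d in dec$details) expect_lt(max(abs(d$coefficients)), 1e-12)
  expect_lt(max(abs(idwt2(dwt2(matrix(0, 32, 32), 4)))), 1e-15)
})

test_that("Haar round-trips a ramp and rejects undersized images", {
  ramp <- outer(1:32, 1:32, `+`) / 64
  expect_lt(max(abs(idwt2(dwt2(ramp, 4)) - ramp)), 1e-10)
  expect_error(dwt2(matrix(0, 8, 8), 4), "divisible")
})

test_that("both 2D transforms are linear", {
  set.seed(22)
  X <- matrix(rnorm(64 * 64), 64); Y <- matrix(rnorm(64 * 64), 64)
  a <- 2.5; b <- -1.25
  wd <- dwt2(a * X + b * Y, 4)
  wx <- dwt2(X, 4); wy <- dwt2(Y, 4)
  expect_lt(max(abs(wd$approximation - (a * wx$approximation + b * wy$approximation))),
            1e-9 * max(abs(wd$approximation)))
  cd <- fdct_wrapping(a * X + b * Y)
  cx <- fdct_wrapping(X); cy <- fdct_wrapping(Y)
  for (j in 1:5) for (w in seq_along(cd$scales[[j]])) {
    lhs <- cd$scales[[j]][[w]]
    rhs <- a * cx$scales[[j]][[w]] + b * cy$scales[[j]][[w]]
    expect_lt(max(Mod(lhs - rhs)), 1e-9 * (1 + max(Mod(lhs))))
  }
})

test_that("curvelet wedge counts, inversion, and tight-frame energy hold", {
  expect_equal(curvelet_wedge_counts(5, 8), c(1L, 8L, 16L, 16L, 1L))
  expect_equal(curvelet_wedge_counts(6, 8), c(1L, 8L, 16L, 16L, 32L, 1L))
  expect_equal(curvelet_wedge_counts(5, 16), c(1L, 16L, 32L, 32L, 1L))
  expect_error(curvelet_wedge_counts(5, 6))

  for (n in c(64, 128)) {
    set.seed(23 + n)
    img <- matrix(rnorm(n * n), n)
    dec <- fdct_wrapping(img)
    expect_equal(vapply(dec$scales, length, 0L), c(1, 8, 16, 16, 1))
    rec <- ifdct_wrapping(dec)
    expect_lt(sqrt(sum((rec - img)^2) / sum(img^2)), 1e-6)
    expect_lt(abs(curvelet_energy(dec) - sum(img^2)) / sum(img^2), 0.01)
  }
})

test_that("zeroed coefficients invert to zero and a coarse impulse is low-pass", {
  dec <- fdct_wrapping(matrix(rnorm(64 * 64), 64))
  for (j in 1:5) for (w in seq_along(dec$scales[[j]]))
    dec$scales[[j]][[w]][] <- 0
  expect_lt(max(abs(ifdct_wrapping(dec))), 1e-12)

  dec$scales[[1]][[1]][2, 2] <- 1
  img <- ifdct_wrapping(dec)
  S <- eegmra:::fftshift2(Mod(fft(img))^2)
  m <- eegmra:::fft_freq_index(64)
  r <- pmax(abs(matrix(sort(m), 64, 64)) / 32,
            abs(matrix(sort(m), 64, 64, byrow = TRUE)) / 32)
  b1 <- 2^-(5 - 1)                               # scale-1 band edge
  expect_gt(sum(S[r <= b1]) / sum(S), 0.99)
})

test_that("round-trip on a chirp TF image is exact to tolerance", {
  tf <- compute_tfd(make_chirp(10, 60), tfd_kernel("swvd"), fs = 256)
  img <- resize_image(tf$values, 64, 64)
  rec <- ifdct_wrapping(fdct_wrapping(img))
  expect_lt(sqrt(sum((rec - img)^2) / sum(img^2)), 1e-6)
})

test_that("sub-band selection keeps 22 matrices whose partners are redundant", {
  set.seed(24)
  dec <- fdct_wrapping(matrix(rnorm(64 * 64), 64))
  sel <- select_subbands(dec)
  expect_length(sel, 22)
  per_scale <- table(sub("_.*", "", names(sel)))
  expect_equal(unname(per_scale[c("s1", "s2", "s3", "s4", "s5")]),
               table(factor(c(rep(1, 1), rep(2, 4), rep(3, 8), rep(4, 8), 5)))[1:5],
               ignore_attr = TRUE)
  # dropped wedge at theta+pi carries the same magnitudes (real input)
  for (j in 2:4) {
    nw <- dec$wedge_counts[j]
    for (w in seq_len(nw / 2)) {
      kept <- sort(Mod(dec$scales[[j]][[w]]))
      dropped <- sort(Mod(dec$scales[[j]][[w + nw / 2]]))
      expect_lt(max(abs(kept - dropped)), 1e-8 * (1 + max(kept)))
    }
  }
  bad <- fdct_wrapping(matrix(rnorm(64 * 64), 64), n_scales = 4)
  expect_error(select_subbands(bad), "wedge counts")
})

test_that("curvelets represent an oriented curved ripple more sparsely than Haar", {
  # an oscillatory band along a curved path: oblique anisotropic structure,
  # the regime where a directional frame needs far fewer coefficients than
  # a separable basis
  n <- 128
  ii <- matrix(1:n, n, n); jj <- t(ii)
  env <- exp(-((ii - 64 - 0.003 * (jj - 64)^2) / 18)^2)
  img <- cos(2 * pi * (0.15 * ii + 0.1 * jj)) * env
  coeffs_needed <- function(v, frac = 0.95) {
    s <- sort(v^2, decreasing = TRUE)
    which(cumsum(s) >= frac * sum(s))[1]
  }
  cd <- fdct_wrapping(img)
  cv <- unlist(lapply(cd$scales, function(sc) lapply(sc, function(m) as.vector(Mod(m)))))
  wd <- dwt2(img, 4)
  wv <- c(as.vector(wd$approximation),
          unlist(lapply(wd$details, function(d) as.vector(d$coefficients))))
  expect_lt(coeffs_needed(cv), coeffs_needed(wv))
})

test_that("resize is exact bilinear interpolation and preserves constants", {
  m <- outer(1:16, 1:12, function(i, j) 2 * i - 3 * j)
  out <- resize_image(m, 31, 23)                 # bilinear reproduces planes
  xi <- seq(1, 12, length.out = 23); yi <- seq(1, 16, length.out = 31)
  expect_equal(out, outer(yi, xi, function(i, j) 2 * i - 3 * j),
               tolerance = 1e-10)
  expect_equal(resize_image(matrix(5, 7, 7), 64, 64), matrix(5, 64, 64),
               tolerance = 1e-12)
})
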