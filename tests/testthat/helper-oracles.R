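# Independent brute-force oracles used to pin down expected values.

# Literal double-sum evaluation of the four co-occurrence properties from a
# normalized G x G probability matrix p (indices 0-based).
oracle_glcm_props <- function(p) {
  G <- nrow(p)
  contrast <- corr_num <- energy <- homog <- 0
  mu_k <- mu_l <- 0
  for (k in 0:(G - 1)) for (l in 0:(G - 1)) {
    mu_k <- mu_k + k * p[k + 1, l + 1]
    mu_l <- mu_l + l * p[k + 1, l + 1]
  }
  s_k <- s_l <- 0
  for (k in 0:(G - 1)) for (l in 0:(G - 1)) {
    s_k <- s_k + (k - mu_k)^2 * p[k + 1, l + 1]
    s_l <- s_l + (l - mu_l)^2 * p[k + 1, l + 1]
  }
  for (k in 0:(G - 1)) for (l in 0:(G - 1)) {
    pkl <- p[k + 1, l + 1]
    contrast <- contrast + abs(k - l)^2 * pkl
    energy <- energy + pkl^2
    homog <- homog + pkl / (1 + abs(k - l))
    corr_num <- corr_num + (k - mu_k) * (l - mu_l) * pkl
  }
  correlation <- if (s_k < 1e-14 || s_l < 1e-14) 1 else corr_num / sqrt(s_k * s_l)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homog)
}

# Symmetric co-occurrence probability matrix counted pair by pair.
oracle_glcm_matrix <- function(q, G, dy, dx) {
  counts <- matrix(0, G, G)
  nr <- nrow(q); nc <- ncol(q)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + dy; j2 <- j + dx
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
      counts[q[i, j] + 1, q[i2, j2] + 1] <- counts[q[i, j] + 1, q[i2, j2] + 1] + 1
      counts[q[i2, j2] + 1, q[i, j] + 1] <- counts[q[i2, j2] + 1, q[i, j] + 1] + 1
    }
  }
  counts / sum(counts)
}

# Recursive flood-fill connected-component labelling of a logical mask.
oracle_label_mask <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && labels[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (labels[p[1], p[2]] != 0L) next
        labels[p[1], p[2]] <- cur
        for (k in seq_len(nrow(nb))) {
          q <- p + nb[k, ]
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] && labels[q[1], q[2]] == 0L)
            stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  labels
}

# Total coefficient energy of a curvelet decomposition.
curvelet_energy <- function(dec) {
  sum(unlist(lapply(dec$scales, function(sc)
    vapply(sc, function(m) sum(Mod(m)^2), numeric(1)))))
}

# Deterministic test tone / chirp segments.
make_tone <- function(f0, n = 256, fs = 256) cos(2 * pi * f0 * (0:(n - 1)) / fs)
make_chirp <- function(f0, f1, n = 256, fs = 256) {
  t <- (0:(n - 1)) / fs
  cos(2 * pi * (f0 * t + (f1 - f0) / (2 * max(t)) * t^2))
}
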