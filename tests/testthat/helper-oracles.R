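# Independent reference implementations used as oracles. These deliberately
# re-derive results with plain R loops and closed forms, not via the
# package's own code paths.

# half-sample symmetric padding, matching the filters' boundary rule
mirror_pad_R <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  refl <- function(j, n) {
    while (j < 1L || j > n) {
      if (j < 1L) j <- 1L - j
      if (j > n) j <- 2L * n - j + 1L
    }
    j
  }
  out <- matrix(0, H + 2L * k, W + 2L * k)
  for (i in seq_len(H + 2L * k))
    for (j in seq_len(W + 2L * k))
      out[i, j] <- m[refl(i - k, H), refl(j - k, W)]
  out
}

# literal per-pixel adaptive trimmed mean, looping the defining equations
atm_oracle <- function(m, beta, lam, delta) {
  H <- nrow(m); W <- ncol(m)
  mx <- max(m)
  if (mx <= 0) return(m)
  hb <- beta %/% 2L
  P <- mirror_pad_R(m, hb)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      x <- m[i, j]
      pz <- max(x - delta, 0)
      Mreal <- (2 * beta * lam * mx) / (2 * lam * mx + beta * pz)
      kk <- floor((Mreal - 1) / 2 + 0.5 + 1e-12)  # nearest odd, ties up
      mm <- min(max(2 * kk + 1, 3), beta)
      alpha <- min(max(x / (lam * mx), 0), 0.5)
      h <- mm %/% 2
      win <- sort(as.vector(P[(i + hb - h):(i + hb + h),
                              (j + hb - h):(j + hb + h)]))
      n <- mm^2
      t <- ceiling(alpha * n - 1e-9)
      out[i, j] <- if (n - 2 * t <= 0) win[(n + 1) / 2]
                   else mean(win[(t + 1):(n - t)])
    }
  }
  out
}

# plain Gaussian smoothing with a truncated normalized kernel and mirror
# padding (the bilateral filter's sigma_r -> Inf limit)
gauss_blur_oracle <- function(m, sigma, window) {
  h <- window %/% 2L
  d <- (-h):h
  k2 <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k2 <- k2 / sum(k2)
  P <- mirror_pad_R(m, h)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- sum(k2 * P[i:(i + 2L * h), j:(j + 2L * h)])
  out
}

# literal evaluation of the NLM weighted average at one site (1-based),
# optionally with a Gaussian patch kernel
nlm_site_oracle <- function(m, i, j, sigma, hw, hp, gauss = FALSE,
                            gsigma = 1) {
  k <- hw + hp
  P <- mirror_pad_R(m, k)
  a <- i + k; b <- j + k
  num <- 0; Z <- 0
  for (di in -hw:hw) {
    for (dj in -hw:hw) {
      ssd <- 0
      for (pi in -hp:hp) for (pj in -hp:hp) {
        g <- if (gauss) exp(-(pi^2 + pj^2) / (2 * gsigma^2)) else 1
        ssd <- ssd + g * (P[a + pi, b + pj] - P[a + di + pi, b + dj + pj])^2
      }
      w <- exp(-ssd / sigma^2)
      num <- num + w * P[a + di, b + dj]
      Z <- Z + w
    }
  }
  num / Z
}

# slanted step edge blurred along the edge normal by a Gaussian of std sb
# (the ESF is exactly amp * pnorm(d / sb)); angle in degrees from vertical
blurred_edge_image <- function(H, W, sb, angleDeg, amp = 1000,
                               edgeCol = W / 2) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  s <- tan(angleDeg * pi / 180)
  xe <- edgeCol + s * (rows - (H + 1) / 2)
  d <- (xe - cols) / sqrt(1 + s^2)  # positive on the bright (left) side
  cherenkovImage(amp * pnorm(d / sb))
}

# orthonormal DCT-II matrix, written from the textbook formula
dct_matrix_R <- function(n) {
  D <- matrix(0, n, n)
  for (k in 0:(n - 1))
    for (j in 0:(n - 1))
      D[k + 1, j + 1] <- sqrt((if (k == 0) 1 else 2) / n) *
        cos(pi * (2 * j + 1) * k / (2 * n))
  D
}

# orthonormal Haar transform of a power-of-two vector (averages cascade)
haar_R <- function(v) {
  n <- length(v)
  len <- n
  while (len > 1) {
    half <- len / 2
    a <- (v[seq(1, len, 2)] + v[seq(2, len, 2)]) / sqrt(2)
    d <- (v[seq(1, len, 2)] - v[seq(2, len, 2)]) / sqrt(2)
    v[1:half] <- a
    v[(half + 1):len] <- d
    len <- half
  }
  v
}

default_test_noise <- function(...) noiseModel(...)
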