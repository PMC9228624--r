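# Independent reference implementations used as oracles. These deliberately
# use direct (slow) formulations so they share no code path with the package.

# Direct spatial 2D convolution with reflective boundaries.
conv2_direct <- function(x, k) {
  kh <- (nrow(k) - 1) %/% 2
  kw <- (ncol(k) - 1) %/% 2
  n1 <- nrow(x); n2 <- ncol(x)
  ri <- c(kh:1, 1:n1, n1:(n1 - kh + 1))
  ci <- c(kw:1, 1:n2, n2:(n2 - kw + 1))
  p <- x[ri, ci]
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    out[i, j] <- sum(p[i:(i + 2 * kh), j:(j + 2 * kw)] * k[(2 * kh + 1):1, (2 * kw + 1):1])
  }
  out
}

# Plain textbook Richardson-Lucy (no damping, no acceleration), spatial
# convolutions, denominator floored at 1e-12.
rl_textbook <- function(observed, psf, k_iter) {
  psf_f <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf)))]
  est <- observed
  for (k in seq_len(k_iter)) {
    blurred <- conv2_direct(est, psf)
    ratio <- observed / pmax(blurred, 1e-12)
    est <- est * conv2_direct(ratio, psf_f)
  }
  est
}

# Brute-force mean SSIM: explicit loop over all fully interior 11x11
# windows with the standard Gaussian weights.
ssim_brute <- function(a, b, dynamic_range = 1) {
  h <- 5
  k <- exp(-((-h):h)^2 / (2 * 1.5^2))
  w <- outer(k, k); w <- w / sum(w)
  c1 <- (0.01 * dynamic_range)^2; c2 <- (0.03 * dynamic_range)^2
  vals <- c()
  for (i in (1 + h):(nrow(a) - h)) for (j in (1 + h):(ncol(a) - h)) {
    wa <- a[(i - h):(i + h), (j - h):(j + h)]
    wb <- b[(i - h):(i + h), (j - h):(j + h)]
    m1 <- sum(w * wa); m2 <- sum(w * wb)
    v1 <- sum(w * wa^2) - m1^2; v2 <- sum(w * wb^2) - m2^2
    cv <- sum(w * wa * wb) - m1 * m2
    vals <- c(vals, ((2 * m1 * m2 + c1) * (2 * cv + c2)) /
                    ((m1^2 + m2^2 + c1) * (v1 + v2 + c2)))
  }
  mean(vals)
}

# 4-connected component count of a 0/1 matrix (iterative flood fill).
n_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (s in which(m == 1 & lab == 0L)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      if (lab[q] != 0L) next
      lab[q] <- cur
      i <- (q - 1L) %% nrow(m) + 1L; j <- (q - 1L) %/% nrow(m) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] == 1 && lab[ii, jj] == 0L)
          queue <- c(queue, (jj - 1L) * nrow(m) + ii)
      }
    }
  }
  cur
}

# Small reproducible smooth test image (sum of random Gaussian blobs).
blob_image <- function(n, n_blobs = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(0, n, n)
  ix <- row(x); jx <- col(x)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 1, n); cx <- runif(1, 1, n); s <- runif(1, n / 16, n / 6)
    x <- x + runif(1, 50, 200) * exp(-((ix - cy)^2 + (jx - cx)^2) / (2 * s^2))
  }
  x
}

# Light 3x3 binomial smoothing (test-local, independent of package helpers).
sep_conv2_reflect_for_test <- function(x) {
  k <- c(0.25, 0.5, 0.25)
  pad <- function(m) m[c(1, 1:nrow(m), nrow(m)), c(1, 1:ncol(m), ncol(m))]
  p <- pad(x)
  n1 <- nrow(x); n2 <- ncol(x)
  out <- matrix(0, n1, n2)
  for (i in 1:3) for (j in 1:3)
    out <- out + k[i] * k[j] * p[(i - 1) + seq_len(n1), (j - 1) + seq_len(n2)]
  out
}
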