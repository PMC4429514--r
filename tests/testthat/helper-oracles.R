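# Brute-force oracles, deliberately written as plain loops so they share no
# code path with the implementation they check.

gauss1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# O(n^2 k^2) sliding-window convolution with replicate padding
naiveConvolve <- function(field, w1d) {
  r <- (length(w1d) - 1L) %/% 2L
  k2 <- outer(w1d, w1d)
  nr <- nrow(field); nc <- ncol(field)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1L), nr)
      jj <- min(max(j + dj, 1L), nc)
      acc <- acc + k2[di + r + 1L, dj + r + 1L] * field[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

loopGlobalMeans <- function(image, phi, eps) {
  n1 <- d1 <- n2 <- d2 <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    h <- 0.5 * (1 + (2 / pi) * atan(phi[i, j] / eps))
    n1 <- n1 + image[i, j] * h;       d1 <- d1 + h
    n2 <- n2 + image[i, j] * (1 - h); d2 <- d2 + (1 - h)
  }
  c(c1 = n1 / d1, c2 = n2 / d2)
}

naiveLocalFits <- function(image, phi, sigma, eps) {
  h <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  list(f1 = naiveConvolve(h * image, gauss1d(sigma)) /
         pmax(naiveConvolve(h, gauss1d(sigma)), 1e-12),
       f2 = naiveConvolve((1 - h) * image, gauss1d(sigma)) /
         pmax(naiveConvolve(1 - h, gauss1d(sigma)), 1e-12))
}

loopContrast <- function(image, window) {
  r <- window %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, image[min(max(i + di, 1L), nr),
                            min(max(j + dj, 1L), nc)])
    out[i, j] <- (max(vals) - min(vals)) / (max(vals) + min(vals) + 1e-8)
  }
  out
}

loopEvolve <- function(phi, spf, alpha, dt) {
  nr <- nrow(phi); nc <- ncol(phi)
  out <- phi
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gy <- (phi[min(i + 1L, nr), j] - phi[max(i - 1L, 1L), j]) / 2
    gx <- (phi[i, min(j + 1L, nc)] - phi[i, max(j - 1L, 1L)]) / 2
    out[i, j] <- phi[i, j] + dt * alpha * spf[i, j] * sqrt(gx^2 + gy^2)
  }
  out
}

loopFourPhaseMeans <- function(image, m) {
  out <- numeric(4)
  for (k in 1:4) {
    num <- den <- 0
    for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
      num <- num + image[i, j] * m[[k]][i, j]
      den <- den + m[[k]][i, j]
    }
    out[k] <- num / max(den, 1e-12)
  }
  out
}

allPermutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPermutations(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

bruteBestPermMean <- function(l1, l2) {
  labs <- sort(unique(c(l1, l2)))
  best <- -Inf
  for (p in allPermutations(labs)) {
    m2 <- l2
    for (i in seq_along(labs)) m2[l2 == p[i]] <- labs[i]
    ds <- sapply(labs, function(l) {
      a <- l1 == l; b <- m2 == l
      if (sum(a) + sum(b) == 0) 1 else 2 * sum(a & b) / (sum(a) + sum(b))
    })
    best <- max(best, mean(ds))
  }
  best
}

randomImage <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

randomPhi <- function(n, seed) {
  set.seed(seed)
  matrix(sample(c(-1, 1), n * n, replace = TRUE), n, n)
}
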