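# Independent naive reference implementation of the contour chain, written
# as per-pixel nested loops against the documented conventions (reflected
# borders with edge duplication, (dy, dx) accumulation order, 4-bin
# direction quantisation with >= ties, inclusive high threshold,
# 8-connected hysteresis).  Deliberately shares no code with the package.

ref_gray <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  g <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    g[i, j] <- 0.299 * px[i, j, 1] + 0.587 * px[i, j, 2] + 0.114 * px[i, j, 3]
  }
  g
}

ref_reflect <- function(i, n) {
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n + 1 - i)
  i
}

ref_conv <- function(x, kern) {
  k <- nrow(kern); p <- (k - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (dy in seq_len(k)) for (dx in seq_len(k)) {
      w <- kern[dy, dx]
      if (w == 0) next
      ii <- ref_reflect(i + dy - 1 - p, H)
      jj <- ref_reflect(j + dx - 1 - p, W)
      acc <- acc + w * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

ref_gauss_kernel <- function(k, sigma) {
  c0 <- (k + 1) / 2
  g <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    g[i, j] <- exp(-((i - c0)^2 + (j - c0)^2) / (2 * sigma^2))
  }
  g / sum(g)
}

ref_canny <- function(px, kernel = 5, sigma = 0.3 * ((kernel - 1) / 2 - 1) + 0.8,
                      low = 0.10, high = 0.30) {
  g <- if (length(dim(px)) == 3) ref_gray(px) else px
  sm <- ref_conv(g, ref_gauss_kernel(kernel, sigma))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- ref_conv(sm, kx)
  gy <- ref_conv(sm, ky)
  H <- nrow(g); W <- ncol(g)
  mag <- matrix(0, H, W); th <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    mag[i, j] <- sqrt(gx[i, j]^2 + gy[i, j]^2)
    a <- atan2(gy[i, j], gx[i, j]) * 180 / pi
    if (a < 0) a <- a + 180
    if (a >= 180) a <- a - 180
    th[i, j] <- a
  }
  # non-maximum suppression
  nms <- matrix(0, H, W)
  nbr <- function(i, j) if (i < 1 || i > H || j < 1 || j > W) 0 else mag[i, j]
  for (i in seq_len(H)) for (j in seq_len(W)) {
    a <- th[i, j]
    if (a < 22.5 || a >= 157.5) {
      n1 <- nbr(i, j - 1); n2 <- nbr(i, j + 1)
    } else if (a < 67.5) {
      n1 <- nbr(i - 1, j - 1); n2 <- nbr(i + 1, j + 1)
    } else if (a < 112.5) {
      n1 <- nbr(i - 1, j); n2 <- nbr(i + 1, j)
    } else {
      n1 <- nbr(i - 1, j + 1); n2 <- nbr(i + 1, j - 1)
    }
    if (mag[i, j] >= n1 && mag[i, j] >= n2) nms[i, j] <- mag[i, j]
  }
  mx <- max(nms)
  if (mx <= 1e-9) return(matrix(0L, H, W))
  hi <- high * mx; lo <- low * mx
  strong <- nms >= hi
  weak <- nms >= lo & nms < hi
  # hysteresis by explicit queue flood fill
  out <- strong
  queue <- which(strong)
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    qi <- (q - 1) %% H + 1; qj <- (q - 1) %/% H + 1
    for (di in -1:1) for (dj in -1:1) {
      ii <- qi + di; jj <- qj + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      if (weak[ii, jj] && !out[ii, jj]) {
        out[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1) * H + ii)
      }
    }
  }
  m <- matrix(0L, H, W)
  m[out] <- 1L
  m
}
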