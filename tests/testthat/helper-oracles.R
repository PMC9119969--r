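# Brute-force oracles and shared fixtures for the test suite.

# Reference implementation of windowed Shannon entropy: literal reflective
# padding + per-pixel histogram, no shared state with the C++ kernel.
entropy_oracle <- function(px, window = 9) {
  q <- pmax(0L, pmin(255L, as.integer(floor(px))))
  q <- matrix(q, nrow(px), ncol(px))
  r <- (window - 1L) / 2L
  h <- nrow(q); w <- ncol(q)
  reflect <- function(i, n) {
    # symmetric (half-sample-free) reflection: 0 -> 1, -1 -> 2, n+1 -> n, ...
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- reflect((i - r):(i + r), h)
      jj <- reflect((j - r):(j + r), w)
      vals <- as.vector(q[ii, jj])
      p <- tabulate(vals + 1L, nbins = 256L) / length(vals)
      p <- p[p > 0]
      out[i, j] <- -sum(p * log2(p))
    }
  }
  out
}

# Reference 8-connected labelling via repeated dilation-limited flood fill.
label_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  attr(lab, "n") <- nxt
  lab
}
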