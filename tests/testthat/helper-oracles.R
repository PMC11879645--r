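# Independent brute-force oracles used across tests. These deliberately share
# no code with the implementation they check.

# Eq.-style Gaussian window smooth: explicit double sum with kernel truncated
# at `radius` and renormalized over the in-range support.
brute_smooth <- function(Y, h, radius = ceiling(4 * h)) {
  n <- nrow(Y); m <- ncol(Y)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    num <- 0; den <- 0
    for (k in max(1, i - radius):min(n, i + radius)) {
      for (l in max(1, j - radius):min(m, j + radius)) {
        w <- stats::dnorm(i - k, sd = h) * stats::dnorm(j - l, sd = h)
        num <- num + w * Y[k, l]
        den <- den + w
      }
    }
    out[i, j] <- num / den
  }
  out
}

# Index table for the band-removal shear: for every retained upper-triangle
# source pair, the sheared pixel it lands on (all 1-based).
brute_shear_table <- function(d, c) {
  rows <- list()
  for (i in 1:(d - 1)) {
    if (i + c + 1 > d) next
    for (j in (i + c + 1):d) {
      rows[[length(rows) + 1]] <- data.frame(src_i = i, src_j = j,
                                             new_i = i, new_j = j - c - 1)
    }
  }
  do.call(rbind, rows)
}

# Flood-fill (BFS) connected components under 8-adjacency on pixel pairs.
flood_fill_components <- function(bin_a, bin_b) {
  n <- length(bin_a)
  comp <- rep(NA_integer_, n)
  key <- paste(bin_a, bin_b)
  lookup <- stats::setNames(seq_len(n), key)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (da in -1:1) for (db in -1:1) {
        if (da == 0 && db == 0) next
        nb <- lookup[paste(bin_a[p] + da, bin_b[p] + db)]
        if (!is.na(nb) && is.na(comp[nb])) {
          comp[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

# Convenience: build a pixel data.frame.
px <- function(bin_a, bin_b, strength = 1) {
  data.frame(bin_a = bin_a, bin_b = bin_b,
             strength = rep_len(strength, length(bin_a)))
}
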