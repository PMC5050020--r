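# Independent oracle implementations used to cross-check the package's
# algorithms. These deliberately share no code with the implementation.

# breadth-first connected-component labeling in plain R
flood_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2L)
    lab[i, j] <- cur
    while (nrow(queue) > 0L) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1L] + nb[k, 1L]; jj <- p[2L] + nb[k, 2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# sort-and-slice trimmed mean, coded independently
trimmed_mean_oracle <- function(x, trim = 0.10) {
  n <- length(x)
  if (n < 3L) return(mean(x))
  k <- floor(trim * n)
  xs <- x[order(x)]
  if (k > 0L) xs <- xs[-c(seq_len(k), n - seq_len(k) + 1L)]
  sum(xs) / length(xs)
}

# brute-force object-level gating: keep a red object iff any of its pixels
# lies on the blue mask (iterates objects explicitly)
gate_oracle <- function(red_mask, blue_mask, connectivity = 8L) {
  lab <- flood_label(red_mask, connectivity)
  out <- red_mask & FALSE
  for (l in seq_len(max(lab))) {
    px <- lab == l
    if (any(px & blue_mask)) out <- out | px
  }
  out
}

# small random binary scene for property tests
random_scene <- function(nr, nc, p_red, p_blue, seed) {
  set.seed(seed)
  list(red = matrix(runif(nr * nc) < p_red, nr, nc),
       blue = matrix(runif(nr * nc) < p_blue, nr, nc))
}

# permutation test on the difference of group means
perm_test_oracle <- function(x, y, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), length(x))
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / n_perm
}
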