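# Naive quadruple-loop oracles for the spatial metrics: deliberately
# brute-force, independent of the package implementations.

naive_box_count <- function(mask, eps) {
  cnt <- 0
  for (bi in seq(1, nrow(mask), by = eps)) {
    for (bj in seq(1, ncol(mask), by = eps)) {
      hit <- FALSE
      for (i in bi:min(bi + eps - 1, nrow(mask)))
        for (j in bj:min(bj + eps - 1, ncol(mask)))
          if (mask[i, j]) hit <- TRUE
      if (hit) cnt <- cnt + 1
    }
  }
  cnt
}

naive_window_masses <- function(mask, eps) {
  out <- numeric(0)
  for (bi in seq(1, nrow(mask) - eps + 1, by = eps)) {
    if (bi + eps - 1 > nrow(mask)) next
    for (bj in seq(1, ncol(mask) - eps + 1, by = eps)) {
      if (bj + eps - 1 > ncol(mask)) next
      m <- 0
      for (i in bi:(bi + eps - 1))
        for (j in bj:(bj + eps - 1))
          if (mask[i, j]) m <- m + 1
      out <- c(out, m)
    }
  }
  out
}
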