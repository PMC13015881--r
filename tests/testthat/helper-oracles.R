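## Independent brute-force oracles; deliberately naive implementations that
## share no code with the package internals.

## Topographic prominence by exhaustive scanning. A local maximum is a
## sample (or centred plateau) with strictly lower neighbours; walk out to
## each side until a strictly taller sample (or the end), track the minima,
## prominence = height - max(left minimum, right minimum).
oracle_prominence <- function(y) {
  n <- length(y)
  idx <- integer(0); prom <- numeric(0)
  i <- 2
  while (i <= n - 1) {
    if (y[i] > y[i - 1]) {
      j <- i
      while (j <= n - 1 && y[j + 1] == y[i]) j <- j + 1
      if (j <= n - 1 && y[j + 1] < y[i]) {
        mid <- i + floor((j - i) / 2)
        h <- y[mid]
        left <- y[seq_len(i - 1)]
        lmin <- h
        for (v in rev(left)) {
          if (v > h) break
          lmin <- min(lmin, v)
        }
        rmin <- h
        if (j < n) for (v in y[(j + 1):n]) {
          if (v > h) break
          rmin <- min(rmin, v)
        }
        idx <- c(idx, mid)
        prom <- c(prom, h - max(lmin, rmin))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  list(index = idx, prominence = prom)
}

## pick_peaks reimplemented on top of the oracle, including the merge rule.
oracle_pick_peaks <- function(spectrum, min_prominence, ppm_window) {
  res <- oracle_prominence(spectrum$intensity)
  keep <- which(res$prominence >= min_prominence)
  mz <- spectrum$mz[res$index[keep]]
  intensity <- spectrum$intensity[res$index[keep]]
  prominence <- res$prominence[keep]
  chosen <- logical(length(mz))
  for (i in order(-intensity, mz)) {
    close_to_chosen <- any(chosen &
      abs(mz - mz[i]) <= pmax(mz, mz[i]) * ppm_window * 1e-6)
    if (!close_to_chosen) chosen[i] <- TRUE
  }
  o <- order(mz[chosen])
  data.frame(mz = mz[chosen][o], intensity = intensity[chosen][o],
             prominence = prominence[chosen][o])
}

## Random profile-like spectrum: smooth baseline bumps plus sharp spikes.
random_spectrum <- function(n = 400) {
  mz <- sort(runif(n, 100, 900))
  y <- abs(rnorm(n, 0, 120))
  for (k in seq_len(sample(3:8, 1))) {
    c0 <- sample(n, 1)
    w <- sample(2:6, 1)
    win <- max(1, c0 - w):min(n, c0 + w)
    y[win] <- y[win] + runif(1, 300, 5000) * exp(-(win - c0)^2 / w)
  }
  mass_spectrum(mz, y)
}
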