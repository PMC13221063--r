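# tiny deterministic site table used across tests (4 parameters, 8 sites)
make_sites <- function(n = 8, seed = 42) {
  pars <- data.frame(
    parameter = c("depth", "temperature", "pH", "do"),
    low = c(25, 28, 7.9, 5.8), high = c(84, 31.6, 8.6, 10.4))
  simulate_sites(true_model(parameters = pars, seed = seed),
                 n_sites = n)$sites
}

# brute-force MESS oracle: literal per-variable similarity, no shortcuts
mess_oracle <- function(ref, points) {
  ref <- as.matrix(ref); points <- as.matrix(points)
  sapply(seq_len(nrow(points)), function(i) {
    sims <- sapply(seq_len(ncol(ref)), function(j) {
      rv <- ref[, j]; p <- points[i, j]
      f <- 100 * sum(rv < p) / length(rv)
      if (max(rv) == min(rv)) {
        if (p == rv[1]) 100 else -1000
      } else if (f == 0) {
        100 * (p - min(rv)) / (max(rv) - min(rv))
      } else if (f <= 50) {
        2 * f
      } else if (f < 100) {
        2 * (100 - f)
      } else {
        100 * (max(rv) - p) / (max(rv) - min(rv))
      }
    })
    min(sims)
  })
}

# brute-force AUC oracle: count concordant pairs, ties half
auc_oracle <- function(presence, background) {
  tot <- 0
  for (p in presence) for (b in background)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(presence) * length(background))
}
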