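# Shared fixtures and independent brute-force oracles.

# deterministic draws without touching the global RNG
draw_normal <- function(n, seed, sub = 0L) {
  cogsim:::rng_normal(n, seed, "misc", sub)
}
draw_unif <- function(n, seed, sub = 0L) {
  cogsim:::rng_unif(n, seed, "misc", sub)
}

tiny_run_spec <- c(text = 10, code_comprehension = 10, bug_inspection = 16)

tiny_dataset <- function(seed = 1, runs = 1, fs = 200, nchan = 4,
                         grid = c(6, 6, 4), n_voi = 8, ...) {
  simulate_dataset(seed = seed, runs = runs, run_spec = tiny_run_spec,
                   fs = fs, montage = default_montage()[seq_len(nchan)],
                   responsive_channels = default_montage()[1],
                   grid_shape = grid, n_voi = n_voi, ...)
}

# Benjamini-Hochberg step-up, written straight from the definition
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Hjorth parameters straight from the variance definitions
hjorth_oracle <- function(x, fs) {
  d1 <- (x[-1] - x[-length(x)]) * fs
  d2 <- (d1[-1] - d1[-length(d1)]) * fs
  mob <- sqrt(var(d1) / var(x))
  list(activity = var(x), mobility = mob,
       complexity = sqrt(var(d2) / var(d1)) / mob)
}

# Higuchi curve length written as plain nested loops + lm()
higuchi_oracle <- function(x, kmax) {
  n <- length(x)
  Lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm_ <- numeric(k)
    for (m in 1:k) {
      np <- floor((n - m) / k)
      s <- 0
      for (i in 1:np) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      lm_[m] <- s * (n - 1) / (np * k^2)
    }
    Lk[k] <- mean(lm_)
  }
  fit <- lm(log(Lk) ~ log(1:kmax))
  -unname(coef(fit)[2])
}

# rescaled-range Hurst written from the block definition + lm()
hurst_oracle <- function(x) {
  n <- length(x)
  scales <- 16 * 2^(0:20)
  scales <- scales[scales <= n / 2]
  rs <- vapply(scales, function(s) {
    vals <- vapply(seq_len(n %/% s), function(b) {
      y <- x[((b - 1) * s + 1):(b * s)]
      d <- y - mean(y)
      w <- cumsum(d)
      (max(c(w, 0)) - min(c(w, 0))) / sqrt(mean(d^2))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  unname(coef(lm(log(rs) ~ log(scales)))[2])
}
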