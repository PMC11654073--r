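# Independent oracles used across the suite. These are deliberately naive
# textbook implementations, kept separate from the package's code paths.

# Textbook Pearson correlation of two vectors.
pearson_naive <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Mean Fisher-z over all cross-language item pairs, by explicit double loop.
pairwise_ps_naive <- function(m1, m2) {
  zs <- c()
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(nrow(m2))) {
      r <- pearson_naive(m1[i, ], m2[j, ])
      zs <- c(zs, 0.5 * log((1 + r) / (1 - r)))
    }
  }
  mean(zs)
}

# Grid-search oracle for y = a * x^(-b): two rounds of 50 x 50 refinement.
power_law_grid_oracle <- function(x, y, n_grid = 50) {
  rss <- function(a, b) sum((y - a * x^(-b))^2)
  a_rng <- c(0.2 * max(y), 3 * max(y))
  b_rng <- c(-1, 1.5)
  for (round in 1:3) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = n_grid)
    b_grid <- seq(b_rng[1], b_rng[2], length.out = n_grid)
    vals <- outer(a_grid, b_grid, Vectorize(rss))
    best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    a_step <- diff(a_rng) / (n_grid - 1)
    b_step <- diff(b_rng) / (n_grid - 1)
    a_rng <- a_grid[best[1]] + c(-1.5, 1.5) * a_step
    b_rng <- b_grid[best[2]] + c(-1.5, 1.5) * b_step
  }
  list(a = mean(a_rng), b = mean(b_rng),
       rss = rss(mean(a_rng), mean(b_rng)),
       a_step = diff(a_rng) / (n_grid - 1), b_step = diff(b_rng) / (n_grid - 1))
}

# Brute-force direct-sum convolution of an event boxcar with an HRF kernel,
# sampled at volume times.
convolved_regressor_naive <- function(onset, duration, hrf, tr_s, n_timepoints) {
  dt <- hrf$dt_s
  n_fine <- round(n_timepoints * tr_s / dt)
  box <- numeric(n_fine)
  box[(floor(onset / dt) + 1):min(n_fine, ceiling((onset + duration) / dt))] <- 1
  conv <- numeric(n_fine)
  h <- hrf$values
  for (t in seq_len(n_fine)) {
    ks <- seq_len(min(t, length(h)))
    conv[t] <- sum(h[ks] * box[t - ks + 1])
  }
  conv[round((seq_len(n_timepoints) - 1) * tr_s / dt) + 1] * dt
}

# Small standard cohort scale used by end-to-end tests.
reduced_design <- function(...) {
  cohort_design(n_runs = 4L, n_items = 8L, n_voxels_roi = 80L, ...)
}
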