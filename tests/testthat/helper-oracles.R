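# Shared fixtures and independent oracles used across the test files.

default_nu <- outreach_distribution()                      # U(0,10), U(-30,30) deg
isotropic_nu <- outreach_distribution(angle_deg = c(0, 360))

# Monte-Carlo standard error for serially correlated per-event statistics,
# estimated by batch means (the iid formula underestimates for a Markov chain).
batch_se <- function(x, n_batch = 100L) {
  m <- length(x) %/% n_batch
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], m, n_batch))
  stats::sd(bm) / sqrt(n_batch)
}

# Geometric brute-force oracle for the detach displacements: build the
# sequential state, remove site d, recompute the plain mean of the rest.
geometric_detach_oracle <- function(etas) {
  st <- build_sequential_state(etas)
  k <- nrow(st$v)
  t(vapply(seq_len(k), function(d) {
    rest <- st$v[-d, , drop = FALSE]
    colMeans(rest) - st$centroid
  }, numeric(2)))
}

# Direct enumeration of the n = 2 transition table (state probabilities and
# per-possibility displacements), independent of the package formulas.
mean_jump_n2_oracle <- function(r, Eeta) {
  pi0 <- 1 / (2 * (1 + r)); pi1 <- 1 / 2; pi2 <- r / (2 * (1 + r))
  rp0 <- 1 / 2; rp1 <- r / (1 + r); p2 <- 1 / 2
  pi0 * 2 * rp0 * Eeta +                 # 0 -> 1: two sites, jump eta
    pi1 * rp1 * Eeta / 2 +               # 1 -> 2: jump eta / 2
    pi2 * p2 * (Eeta / 2 - Eeta / 2)     # 2 -> 1: +-eta/2 cancel
}

msd_n2_oracle <- function(r, E2) {
  pi0 <- 1 / (2 * (1 + r)); pi1 <- 1 / 2; pi2 <- r / (2 * (1 + r))
  pi0 * 2 * (1 / 2) * E2 +               # 0 -> 1
    pi1 * (r / (1 + r)) * E2 / 4 +       # 1 -> 2
    pi2 * 2 * (1 / 2) * E2 / 4           # 2 -> 1, two possibilities
}
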