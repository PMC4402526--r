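# Random parameter sets spanning realistic polymerase kinetics; used by the
# property-style tests. Callers set the seed.
random_ratchet_rates <- function() {
  ratchet_rates(k_on = 10^runif(1, -0.5, 1.5),
                k_off = runif(1, 0, 50),
                k_cat = 10^runif(1, 1, 2.5),
                k_ppi = 10^runif(1, 3.5, 4.5),
                k_T0 = 10^runif(1, 2, 3.5),
                k_mT0 = 10^runif(1, 2, 3.5),
                d_T = runif(1, 0, 0.6),
                d_mT = runif(1, 0, 0.3))
}

random_model1_rates <- function() {
  model1_rates(k_on0 = 10^runif(1, -0.5, 1.5),
               k_off0 = runif(1, 0, 100),
               k_cat = 10^runif(1, 1, 2.5),
               d_on = runif(1, 0, 0.5),
               d_off = runif(1, 0, 0.3))
}

random_model2_rates <- function() {
  model2_rates(k_on = 10^runif(1, -0.5, 1.5),
               k_off = runif(1, 0, 100),
               k_cat = 10^runif(1, 1, 2.5),
               k_mcat = runif(1, 0, 50),
               k_ppi0 = 10^runif(1, 3, 4.5),
               d_ppi = runif(1, 0, 0.5))
}

# Independent master-equation oracle: long-time propagation of the cycle
# generator with Matrix::expm, plus flux read-out. Deliberately avoids the
# package's linear-solve path.
expm_cycle_steady_state <- function(forward, backward, t_long = 1e3) {
  n <- length(forward)
  nxt <- c(2:n, 1L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[nxt[i], i] <- A[nxt[i], i] + forward[i]
    A[i, nxt[i]] <- A[i, nxt[i]] + backward[i]
  }
  diag(A) <- diag(A) - colSums(A)
  # scale time so the slowest nonzero rate relaxes
  tscale <- t_long / max(c(forward, backward))
  P <- as.matrix(Matrix::expm(Matrix::Matrix(A * tscale)))
  p <- P %*% rep(1 / n, n)
  p <- as.numeric(p / sum(p))
  list(occupancy = p, velocity = forward[1L] * p[1L] - backward[1L] * p[2L])
}

# closed-form velocity of the ratchet cycle directly from rates
velocity_from_rates <- function(rates, force, dntp, kBT = kbt()) {
  velocity_model3(force, dntp, coefficients_from_rates(rates), kBT)
}
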