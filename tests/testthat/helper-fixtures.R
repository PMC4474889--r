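# Shared fixtures and independent brute-force oracles.

# Random stable MVAR model (rejection sampling on the companion radius).
random_stable_model <- function(k, p = 1, seed = 1, max_radius = 0.9) {
  set.seed(seed)
  repeat {
    A <- array(stats::runif(k * k * p, -0.5, 0.5) / (k * p), c(k, k, p))
    r <- companion_radius(A)
    if (r < max_radius && r > 0) {
      return(new_mvar_model(A, diag(k)))
    }
  }
}

# Spectral tensor with prescribed complex coefficients (epochs x channels x
# freqs), bypassing the FFT: lets estimator tests control phases directly.
make_tensor <- function(coeffs, fs = 512) {
  structure(list(coeffs = coeffs, freqs = seq_len(dim(coeffs)[3]), fs = fs,
                 taper = "none",
                 channel_labels = sprintf("E%03d", seq_len(dim(coeffs)[2]))),
            class = "spectral_tensor")
}

# Tensor from per-epoch phases (radians) for a 2-channel system:
# channel 1 has phase 0, channel 2 has phase -theta_e so that
# arg(X1 conj(X2)) = theta_e; amplitudes default 1.
phase_tensor <- function(theta, amp1 = rep(1, length(theta)),
                         amp2 = rep(1, length(theta))) {
  n <- length(theta)
  co <- array(NA_complex_, c(n, 2, 1))
  co[, 1, 1] <- amp1 + 0i
  co[, 2, 1] <- amp2 * exp(-1i * theta)
  make_tensor(co)
}

# Random complex-Gaussian tensor (independent channels) for null estimators.
null_tensor <- function(n_epochs, n_channels, n_freqs = 1, seed = 1) {
  set.seed(seed)
  co <- array(complex(real = stats::rnorm(n_epochs * n_channels * n_freqs),
                      imaginary = stats::rnorm(n_epochs * n_channels * n_freqs)),
              c(n_epochs, n_channels, n_freqs))
  make_tensor(co)
}

# Brute-force undirected clustering coefficient by neighbour-pair enumeration.
brute_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    cnt <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) if (A[nb[a], nb[b]] == 1) cnt <- cnt + 1
    }
    2 * cnt / (k * (k - 1))
  }, numeric(1))
}

# Brute-force directed (Fagiolo) clustering by triple enumeration.
brute_clustering_directed <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    if (den <= 0) return(0)
    t3 <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        t3 <- t3 + (A[i, j] + A[j, i]) * (A[j, h] + A[h, j]) *
          (A[h, i] + A[i, h])
      }
    }
    (t3 / 2) / den
  }, numeric(1))
}

# Brute-force Newman assortativity: Pearson over the edge list, both
# orientations.
brute_assortativity <- function(A) {
  deg <- rowSums(A)
  xs <- c(); ys <- c()
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && A[i, j] == 1) {
        xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
      }
    }
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NaN)
  stats::cor(xs, ys)
}

# Random undirected graph with given edge probability.
random_graph <- function(n, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
  A <- A + t(A)
  new_network_graph(A, directed = FALSE)
}

# Small fast cohort for pipeline-level tests.
small_cohort_spec <- function(seed = 1, effect_strength = 0.35,
                              n_patients = 3, n_controls = 3, epochs = 8) {
  m <- make_montage(6)
  cohort_spec(n_patients = n_patients, n_controls = n_controls, montage = m,
              effect = if (effect_strength > 0) {
                default_effect_spec(m, strength = effect_strength, n_nodes = 3)
              } else coupling_spec(),
              epochs_per_subject = epochs, epoch_len_s = 1, fs = 256,
              seed = seed)
}
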