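test_that("csd scales linearly and matches mean power on the diagonal concept", {
  st <- null_tensor(20, 1, seed = 1)
  co <- st$coeffs
  co2 <- array(NA_complex_, c(20, 2, 1))
  co2[, 1, 1] <- co[, 1, 1]
  co2[, 2, 1] <- 2 * co[, 1, 1]          # Y = 2X
  res <- csd_magnitude(make_tensor(co2))
  sxx <- mean(Mod(co[, 1, 1])^2)
  expect_equal(res$values[1, 2, 1], 2 * sxx, tolerance = 1e-10)
  expect_true(is.nan(res$values[1, 1, 1]))  # diagonal convention
})

test_that("csd of independent noise decays like 1/sqrt(N) (Monte-Carlo)", {
  est <- vapply(c(50, 200), function(N) {
    mean(vapply(1:30, function(s) {
      st <- null_tensor(N, 2, seed = s)
      csd_magnitude(st)$values[1, 2, 1]
    }, numeric(1)))
  }, numeric(1))
  expect_equal(est[1] / est[2], 2, tolerance = 0.25)  # sqrt(200/50) = 2
})

test_that("coherence is 1 for identical and for filtered copies, with known null bias", {
  st <- null_tensor(30, 1, seed = 2)
  co <- array(NA_complex_, c(30, 2, 1))
  co[, 1, 1] <- st$coeffs[, 1, 1]
  co[, 2, 1] <- st$coeffs[, 1, 1]
  expect_equal(coherence(make_tensor(co))$values[1, 2, 1], 1)
  co[, 2, 1] <- st$coeffs[, 1, 1] * (0.3 - 0.8i)  # fixed linear relation
  expect_equal(coherence(make_tensor(co))$values[1, 2, 1], 1)
  # small-sample null bias E[coh] ~ 1/N
  N <- 100
  bias <- mean(vapply(1:40, function(s) {
    coherence(null_tensor(N, 2, seed = 300 + s))$values[1, 2, 1]
  }, numeric(1)))
  expect_equal(bias, 1 / N, tolerance = 0.3)
})

test_that("power correlation hits the closed-form extremes and bounds", {
  st <- null_tensor(20, 1, seed = 3)
  x <- st$coeffs[, 1, 1]
  co <- array(NA_complex_, c(20, 2, 1))
  co[, 1, 1] <- x
  co[, 2, 1] <- x
  expect_equal(power_correlation(make_tensor(co))$values[1, 2, 1], 1)
  # |Y|^2 = c - |X|^2 construction => exactly -1
  c0 <- max(Mod(x)^2) + 1
  co[, 2, 1] <- complex(modulus = sqrt(c0 - Mod(x)^2),
                        argument = stats::runif(20, 0, 2 * pi))
  expect_equal(power_correlation(make_tensor(co))$values[1, 2, 1], -1)
  # null: |r| < 0.2 in at least 95% of seeded runs (N = 200)
  hits <- vapply(1:40, function(s) {
    abs(power_correlation(null_tensor(200, 2, seed = 500 + s))$values[1, 2, 1])
  }, numeric(1))
  expect_gte(mean(hits < 0.2), 0.95)
})

test_that("plv closed forms: constant phase 1, antipodal cancellation 0", {
  expect_equal(plv(phase_tensor(rep(0.7, 10)))$values[1, 2, 1], 1)
  expect_equal(plv(phase_tensor(rep(c(0, pi), 5)))$values[1, 2, 1], 0,
               tolerance = 1e-12)
})

test_that("ppc closed forms: constant phase 1; N=2 gives cos of the difference", {
  expect_equal(ppc(phase_tensor(rep(1.1, 8)))$values[1, 2, 1], 1)
  expect_equal(ppc(phase_tensor(c(0, pi / 3)))$values[1, 2, 1], 0.5,
               tolerance = 1e-12)
})

test_that("plv-family null behaviour: E[PLV^2] = 1/N, PPC unbiased at 0", {
  N <- 50; runs <- 400
  plv2 <- numeric(runs); ppcv <- numeric(runs)
  for (s in seq_len(runs)) {
    set.seed(900 + s)
    st <- phase_tensor(stats::runif(N, 0, 2 * pi))
    plv2[s] <- plv(st)$values[1, 2, 1]^2
    ppcv[s] <- ppc(st)$values[1, 2, 1]
  }
  expect_equal(mean(plv2), 1 / N, tolerance = 0.15)
  expect_lt(abs(mean(ppcv)), 0.01)
  # PLV itself is biased upward: E[PLV] ~ sqrt(pi / (4N))
  expect_equal(mean(sqrt(plv2)), sqrt(pi / (4 * N)), tolerance = 0.1)
})

test_that("wppc reduces to ppc under equal weights and is 1 at constant phase", {
  th <- c(0.2, 1.4, 2.2, -0.5, 0.9)
  equal <- phase_tensor(th)                       # all amplitudes 1
  expect_equal(wppc(equal)$values[1, 2, 1], ppc(equal)$values[1, 2, 1],
               tolerance = 1e-12)
  set.seed(4)
  wt <- phase_tensor(rep(0.3, 6), amp1 = stats::runif(6, 0.5, 2),
                     amp2 = stats::runif(6, 0.5, 2))
  expect_equal(wppc(wt)$values[1, 2, 1], 1, tolerance = 1e-12)
  # null mean ~ 0 with heterogeneous weights
  v <- vapply(1:300, function(s) {
    set.seed(1500 + s)
    wppc(phase_tensor(stats::runif(20, 0, 2 * pi),
                      amp1 = stats::runif(20, 0.5, 2),
                      amp2 = stats::runif(20, 0.5, 2)))$values[1, 2, 1]
  }, numeric(1))
  expect_lt(abs(mean(v)), 0.02)
})

test_that("wpli closed forms: quarter-cycle lag 1, zero-lag 0, balanced mixture 0", {
  expect_equal(wpli(phase_tensor(rep(pi / 2, 6)))$values[1, 2, 1], 1)
  zl <- wpli(phase_tensor(rep(0, 6)))            # Im identically 0
  expect_equal(zl$values[1, 2, 1], 0)
  expect_gt(attr(zl, "zero_lag_flags"), 0)
  # +Im and -Im epochs of equal magnitude and number cancel exactly
  expect_equal(wpli(phase_tensor(rep(c(pi / 2, -pi / 2), 4)))$values[1, 2, 1],
               0, tolerance = 1e-12)
})

test_that("wpli is invariant to zero-lag common signal where plv is not", {
  set.seed(8)
  N <- 60
  x <- complex(real = rnorm(N), imaginary = rnorm(N))
  y <- complex(real = rnorm(N), imaginary = rnorm(N))
  common <- complex(real = rnorm(N), imaginary = rnorm(N)) * 3
  co0 <- array(NA_complex_, c(N, 2, 1)); co0[, 1, 1] <- x; co0[, 2, 1] <- y
  co1 <- co0; co1[, 1, 1] <- x + common; co1[, 2, 1] <- y + common
  w0 <- wpli(make_tensor(co0))$values[1, 2, 1]
  w1 <- wpli(make_tensor(co1))$values[1, 2, 1]
  p0 <- plv(make_tensor(co0))$values[1, 2, 1]
  p1 <- plv(make_tensor(co1))$values[1, 2, 1]
  # the common zero-lag signal inflates PLV strongly but WPLI stays small
  expect_gt(p1 - p0, 0.3)
  expect_lt(w1, 0.35)
})

test_that("pdc zero-coupling pattern and exact formula at 5 Hz", {
  A <- array(c(0.5, 0.4, 0, 0.5), c(2, 2, 1))
  m <- new_mvar_model(A, diag(2))
  fac <- spectral_factor(m, freqs = 1:20, fs = 512)
  res <- pdc(fac)
  expect_equal(max(res$values[1, 2, ]), 0)       # no 2 -> 1 influence
  expect_true(all(res$values[2, 1, ] > 0))
  # brute-force formula oracle at f = 5
  z <- exp(-2i * pi * 5 / 512)
  Ab <- diag(2) - A[, , 1] * z
  expect_equal(res$values[2, 1, 5],
               Mod(Ab[2, 1]) / sqrt(Mod(Ab[1, 1])^2 + Mod(Ab[2, 1])^2),
               tolerance = 1e-12)
  # identity pattern for the all-zero model
  m0 <- new_mvar_model(array(0, c(3, 3, 1)), diag(3))
  r0 <- pdc(spectral_factor(m0, freqs = 1:5, fs = 512))
  expect_equal(unique(as.vector(r0$values[!is.nan(r0$values)])), 0)
  expect_equal(unique(as.vector(r0$values_full[, , 1][diag(3) == 1])), 1)
})

test_that("dtf matches an independent inversion and kills reverse chains", {
  A <- array(c(0.5, 0.4, 0, 0.5), c(2, 2, 1))
  m <- new_mvar_model(A, diag(2))
  res <- dtf(spectral_factor(m, freqs = 1:20, fs = 512))
  expect_equal(max(res$values[1, 2, ]), 0)       # DTF(2 -> 1) = 0
  mm <- random_stable_model(3, p = 1, seed = 77)
  fac <- spectral_factor(mm, freqs = 1:10, fs = 512)
  r <- dtf(fac)
  f <- 7
  H <- solve(diag(3) - mm$A[, , 1] * exp(-2i * pi * f / 512))
  expect_equal(r$values[1, 2, f],
               Mod(H[1, 2]) / sqrt(sum(Mod(H[1, ])^2)), tolerance = 1e-10)
})

test_that("pdc/dtf normalization identities hold on random stable models", {
  for (s in 1:10) {
    mm <- random_stable_model(sample(2:5, 1), p = 2, seed = 200 + s)
    fac <- spectral_factor(mm, freqs = c(2, 11, 43), fs = 512)
    p <- pdc(fac)$values_full
    d <- dtf(fac)$values_full
    for (fi in 1:3) {
      expect_lt(max(abs(colSums(p[, , fi]^2) - 1)), 1e-10)
      expect_lt(max(abs(rowSums(d[, , fi]^2) - 1)), 1e-10)
    }
  }
})

test_that("spectral Granger recovers planted direction and nulls out independence", {
  set.seed(55)
  ind <- new_recording(array(rnorm(40 * 2 * 512), c(40, 2, 512)), 512,
                       c("a", "b"))
  g0 <- granger_spectral(ind, order = 2)
  expect_lt(max(g0$values[1, 2, ], g0$values[2, 1, ]), 0.05)

  sp <- coupling_spec(tibble::tibble(source = "E001", target = "E002",
                                     band = "theta", strength = 0.4))
  m <- build_generating_mvar(sp, 2, fs = 512)
  rec <- simulate_subject(m, epochs = 40, epoch_len_s = 2, fs = 512, seed = 56)
  g <- granger_spectral(rec, order = 4)
  theta <- 4:7
  expect_gt(mean(g$values[2, 1, theta]), mean(g$values[1, 2, theta]))
  expect_true(all(g$values[!is.nan(g$values)] >= 0))
})

test_that("time-domain Granger log variance ratio agrees in sign with integrated spectral GC", {
  sp <- coupling_spec(tibble::tibble(source = "E001", target = "E002",
                                     band = "alpha", strength = 0.5))
  m <- build_generating_mvar(sp, 2, fs = 512)
  rec <- simulate_subject(m, epochs = 30, epoch_len_s = 2, fs = 512, seed = 60)
  g <- granger_spectral(rec, order = 3)
  # independent time-domain oracle: restricted vs full AR residual variances
  td_gc <- function(y_idx, x_idx, p = 3) {
    x <- as_continuous(rec)
    n <- nrow(x)
    lag <- function(v, r) v[(p + 1 - r):(n - r)]
    y <- x[(p + 1):n, y_idx]
    own <- sapply(1:p, function(r) lag(x[, y_idx], r))
    oth <- sapply(1:p, function(r) lag(x[, x_idx], r))
    full <- stats::lm.fit(cbind(1, own, oth), y)
    restr <- stats::lm.fit(cbind(1, own), y)
    log(mean(restr$residuals^2) / mean(full$residuals^2))
  }
  gc_12_td <- td_gc(2, 1)   # 1 -> 2
  gc_21_td <- td_gc(1, 2)
  gc_12_sp <- mean(g$values[2, 1, ])
  gc_21_sp <- mean(g$values[1, 2, ])
  expect_gt(gc_12_td, gc_21_td)
  expect_gt(gc_12_sp, gc_21_sp)
})

test_that("bounded measures respect their ranges on random inputs (fuzzing)", {
  for (s in 1:25) {
    set.seed(700 + s)
    st <- null_tensor(sample(3:12, 1), sample(2:4, 1),
                      n_freqs = sample(1:3, 1), seed = 700 + s)
    checks <- list(
      coherence = c(0, 1), plv = c(0, 1), wpli = c(0, 1), pli = c(0, 1),
      ppc = c(-1, 1), wppc = c(-1, 1), power_correlation = c(-1, 1),
      imcoh = c(0, 1))
    for (msn in names(checks)) {
      fn <- switch(msn, coherence = coherence, plv = plv, wpli = wpli,
                   pli = pli, ppc = ppc, wppc = wppc,
                   power_correlation = power_correlation,
                   imcoh = imaginary_coherency)
      v <- fn(st)$values
      v <- v[!is.nan(v) & !is.na(v)]
      expect_gte(min(v), checks[[msn]][1] - 1e-12)
      expect_lte(max(v), checks[[msn]][2] + 1e-12)
    }
  }
})

test_that("undirected results are symmetric; the registry drives compute_all_measures", {
  spec <- small_cohort_spec(seed = 5, n_patients = 1, n_controls = 1,
                            epochs = 6)
  rec <- generate_cohort(spec)$recordings[[1]]
  out <- compute_all_measures(rec, order = 2)
  expect_equal(nrow(measure_registry()), 12)
  expect_setequal(names(out), measure_registry()$measure)
  for (ms in names(out)) {
    r <- out[[ms]]
    if (!r$directed) {
      expect_equal(r$values, aperm(r$values, c(2, 1, 3)), tolerance = 1e-10)
    }
  }
  one <- compute_all_measures(rec, measures = "plv")
  expect_named(one, "plv")
  expect_error(compute_all_measures(rec, measures = "nope"), "unknown")
})
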