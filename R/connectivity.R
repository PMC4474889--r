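#' Connectivity result containers
#'
#' All estimators return a `connectivity_result`: a channels x channels x
#' frequencies (or bands) array of connection weights, plus the measure name
#' and a directedness flag. By convention the diagonal (self-connection) is
#' `NaN`; directed AR-based measures additionally keep the full normalized
#' array (including self-terms, needed for their normalization identities) in
#' `values_full`.
#'
#' For directed measures `values[i, j, f]` is the influence of source `j` on
#' target `i`.
#'
#' @param measure measure name.
#' @param directed logical flag.
#' @param values numeric array channels x channels x frequencies/bands.
#' @param freqs frequency grid (Hz) or band names the third axis indexes.
#' @param labels channel labels.
#' @param axis `"frequency"` or `"band"`.
#' @param values_full optional array retaining self-connection values.
#' @return object of class `connectivity_result`.
#' @export
new_connectivity_result <- function(measure, directed, values, freqs, labels,
                                    axis = "frequency", values_full = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            dim(values)[1] == dim(values)[2],
            dim(values)[3] == length(freqs))
  k <- dim(values)[1]
  for (f in seq_len(dim(values)[3])) diag(values[, , f]) <- NaN
  dimnames(values) <- list(labels, labels, as.character(freqs))
  structure(list(measure = measure, directed = directed, values = values,
                 freqs = freqs, labels = labels, axis = axis,
                 values_full = values_full),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<connectivity_result> %s (%s): %d x %d x %d %s bins\n",
              x$measure, if (x$directed) "directed" else "undirected",
              d[1], d[2], d[3], x$axis))
  invisible(x)
}

#' @export
tidy.connectivity_result <- function(x, ...) {
  d <- dim(x$values)
  out <- tibble::tibble(
    target = rep(x$labels, times = d[2] * d[3]),
    source = rep(rep(x$labels, each = d[1]), times = d[3]),
    !!(if (x$axis == "band") "band" else "freq_hz") :=
      rep(x$freqs, each = d[1] * d[2]),
    value = as.vector(x$values))
  out$measure <- x$measure
  dplyr::filter(out, .data$target != .data$source)
}

# ---- internal helpers over the spectral tensor --------------------------

# Apply fun(Xf) for each frequency slice Xf (epochs x channels, complex),
# assembling a channels x channels x nfreq array.
.per_freq <- function(st, fun) {
  d <- dim(st$coeffs)
  out <- array(NA_real_, c(d[2], d[2], d[3]))
  for (fi in seq_len(d[3])) {
    Xf <- matrix(st$coeffs[, , fi], nrow = d[1])
    out[, , fi] <- fun(Xf)
  }
  out
}

.check_epochs <- function(st, n_min) {
  stopifnot(inherits(st, "spectral_tensor"))
  if (dim(st$coeffs)[1] < n_min) {
    stop(sprintf("need at least %d epochs", n_min), call. = FALSE)
  }
}

# mean cross-spectrum S_ij(f) = mean_e X_ei conj(X_ej)
.mean_csd <- function(Xf) (t(Xf) %*% Conj(Xf)) / nrow(Xf)

# ---- nonparametric estimators -------------------------------------------

#' Cross-spectral density magnitude
#'
#' `|S_xy(f)|` with `S_xy = mean over epochs of X conj(Y)`; units are squared
#' amplitude per frequency bin.
#' @param st a [compute_fft()] spectral tensor.
#' @return a [new_connectivity_result()].
#' @export
csd_magnitude <- function(st) {
  .check_epochs(st, 2)
  v <- .per_freq(st, function(Xf) Mod(.mean_csd(Xf)))
  new_connectivity_result("csd", FALSE, v, st$freqs, st$channel_labels)
}

#' Magnitude-squared coherence
#'
#' `|S_xy|^2 / (S_xx S_yy)`, in \[0, 1\]. Zero autospectra yield NaN entries
#' with a warning.
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
coherence <- function(st) {
  .check_epochs(st, 2)
  any_zero <- FALSE
  v <- .per_freq(st, function(Xf) {
    S <- .mean_csd(Xf)
    a <- Re(diag(S))
    if (any(a == 0)) any_zero <<- TRUE
    den <- outer(a, a)
    out <- Mod(S)^2 / den
    out[den == 0] <- NaN
    out
  })
  if (any_zero) warning("zero autospectrum: coherence undefined at some entries")
  new_connectivity_result("coherence", FALSE, v, st$freqs, st$channel_labels)
}

#' Imaginary part of coherency
#'
#' `|Im(S_xy)| / sqrt(S_xx S_yy)`, insensitive to zero-lag (volume-conducted)
#' coupling.
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
imaginary_coherency <- function(st) {
  .check_epochs(st, 2)
  v <- .per_freq(st, function(Xf) {
    S <- .mean_csd(Xf)
    den <- sqrt(outer(Re(diag(S)), Re(diag(S))))
    out <- abs(Im(S)) / den
    out[den == 0] <- NaN
    out
  })
  new_connectivity_result("imcoh", FALSE, v, st$freqs, st$channel_labels)
}

#' Epoch-wise power correlation
#'
#' Pearson correlation, across epochs, of the per-epoch powers `|X|^2` and
#' `|Y|^2`; in \[-1, 1\]. Zero-variance channels yield NaN.
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
power_correlation <- function(st) {
  .check_epochs(st, 3)
  v <- .per_freq(st, function(Xf) {
    suppressWarnings(stats::cor(Mod(Xf)^2))
  })
  new_connectivity_result("power_correlation", FALSE, v, st$freqs,
                          st$channel_labels)
}

#' Phase locking value
#'
#' Magnitude of the mean unit phasor of the epoch-wise phase difference:
#' `|mean_e exp(i theta_e)|`, in \[0, 1\]. Zero-amplitude coefficients (phase
#' undefined) propagate NaN.
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
plv <- function(st) {
  .check_epochs(st, 2)
  v <- .per_freq(st, function(Xf) {
    U <- Xf / Mod(Xf)            # unit phasors; 0/0 -> NaN
    Mod((t(U) %*% Conj(U)) / nrow(Xf))
  })
  new_connectivity_result("plv", FALSE, v, st$freqs, st$channel_labels)
}

#' Pairwise phase consistency
#'
#' Unbiased PLV-family estimator: mean cosine of phase differences over all
#' epoch pairs, equal to `(N PLV^2 - 1) / (N - 1)`; in \[-1, 1\].
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
ppc <- function(st) {
  .check_epochs(st, 2)
  N <- dim(st$coeffs)[1]
  v <- .per_freq(st, function(Xf) {
    U <- Xf / Mod(Xf)
    plv2 <- Mod((t(U) %*% Conj(U)) / N)^2
    (N * plv2 - 1) / (N - 1)
  })
  new_connectivity_result("ppc", FALSE, v, st$freqs, st$channel_labels)
}

#' Weighted pairwise phase consistency
#'
#' PPC with epoch pairs weighted by cross-spectral magnitude
#' `w_e = |X_e||Y_e|`. With `z_e = w_e exp(i theta_e)` (the per-epoch
#' cross-spectrum) it equals
#' `(|sum z|^2 - sum |z|^2) / ((sum w)^2 - sum w^2)`. Reduces to PPC when all
#' weights are equal.
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
wppc <- function(st) {
  .check_epochs(st, 2)
  v <- .per_freq(st, function(Xf) {
    A <- Mod(Xf)
    Sz <- t(Xf) %*% Conj(Xf)       # sum_e z_e
    Sw <- t(A) %*% A               # sum_e w_e
    Sw2 <- t(A^2) %*% A^2          # sum_e w_e^2
    den <- Sw^2 - Sw2
    out <- (Mod(Sz)^2 - Sw2) / den
    out[den == 0] <- NaN
    out
  })
  new_connectivity_result("wppc", FALSE, v, st$freqs, st$channel_labels)
}

#' Weighted phase lag index
#'
#' `|sum_e Im(Z_e)| / sum_e |Im(Z_e)|` with `Z_e = X_e conj(Y_e)`; in
#' \[0, 1\] and insensitive to zero-lag common signals. A zero denominator
#' (purely zero-lag relation) is defined as 0 and counted in the result's
#' `zero_lag_flags` attribute.
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
wpli <- function(st) {
  .check_epochs(st, 2)
  n_flag <- 0
  v <- .per_freq(st, function(Xf) {
    num <- abs(Im(t(Xf) %*% Conj(Xf)))
    den <- matrix(0, ncol(Xf), ncol(Xf))
    for (e in seq_len(nrow(Xf))) {
      xe <- Xf[e, ]
      den <- den + abs(Im(outer(xe, Conj(xe))))
    }
    out <- num / den
    zero <- den == 0
    diag(zero) <- FALSE
    n_flag <<- n_flag + sum(zero)
    out[den == 0] <- 0
    out
  })
  res <- new_connectivity_result("wpli", FALSE, v, st$freqs,
                                 st$channel_labels)
  attr(res, "zero_lag_flags") <- n_flag
  res
}

#' Phase lag index
#'
#' `|mean_e sign(Im(Z_e))|`, in \[0, 1\].
#' @inheritParams csd_magnitude
#' @return a [new_connectivity_result()].
#' @export
pli <- function(st) {
  .check_epochs(st, 2)
  v <- .per_freq(st, function(Xf) {
    acc <- matrix(0, ncol(Xf), ncol(Xf))
    for (e in seq_len(nrow(Xf))) {
      xe <- Xf[e, ]
      acc <- acc + sign(Im(outer(xe, Conj(xe))))
    }
    abs(acc) / nrow(Xf)
  })
  new_connectivity_result("pli", FALSE, v, st$freqs, st$channel_labels)
}

# ---- AR-based directed estimators ---------------------------------------

#' Partial directed coherence
#'
#' Column-normalized magnitude of the spectral coefficient matrix:
#' `PDC[i, j, f] = |Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)` — the direct
#' directed influence of source `j` on target `i`. Columns satisfy
#' `sum_i PDC^2 = 1` exactly (see `values_full` for the self-terms).
#' @param factor a [spectral_factor()].
#' @return a [new_connectivity_result()] (directed).
#' @export
pdc <- function(factor) {
  stopifnot(inherits(factor, "spectral_factor"))
  d <- dim(factor$Abar)
  full <- array(NA_real_, d)
  for (fi in seq_len(d[3])) {
    M <- Mod(factor$Abar[, , fi])
    cn <- sqrt(colSums(M^2))
    if (any(cn == 0)) warning("zero column norm in PDC normalization")
    full[, , fi] <- sweep(M, 2, cn, "/")
  }
  new_connectivity_result("pdc", TRUE, full, factor$freqs, factor$labels,
                          values_full = full)
}

#' Directed transfer function
#'
#' Row-normalized magnitude of the transfer matrix:
#' `DTF[i, j, f] = |H_ij(f)| / sqrt(sum_k |H_ik(f)|^2)` — total (direct plus
#' cascaded) influence of source `j` on target `i`. Rows satisfy
#' `sum_j DTF^2 = 1` exactly.
#' @param factor a [spectral_factor()].
#' @return a [new_connectivity_result()] (directed).
#' @export
dtf <- function(factor) {
  stopifnot(inherits(factor, "spectral_factor"))
  d <- dim(factor$H)
  full <- array(NA_real_, d)
  for (fi in seq_len(d[3])) {
    M <- Mod(factor$H[, , fi])
    rn <- sqrt(rowSums(M^2))
    if (any(stats::na.omit(rn) == 0)) warning("zero row norm in DTF normalization")
    full[, , fi] <- sweep(M, 1, rn, "/")
  }
  new_connectivity_result("dtf", TRUE, full, factor$freqs, factor$labels,
                          values_full = full)
}

#' Spectral (Geweke) Granger causality, pairwise-bivariate
#'
#' For every channel pair a bivariate MVAR is fitted and Geweke's
#' frequency-domain causality computed:
#' `f_{j->i}(f) = ln( S_ii(f) / (S_ii(f) - (Sigma_jj - Sigma_ij^2/Sigma_ii) |H_ij(f)|^2) )`,
#' where `S = H Sigma H^H` is the model spectrum. Nonnegative; numerically
#' nonpositive log arguments are clamped to 0 with a warning.
#'
#' @param recording an [new_recording()] (the pairwise refits need the data).
#' @param order bivariate MVAR order, or `"auto"`.
#' @param freqs frequencies in Hz.
#' @param max_order cap for `"auto"`.
#' @return a [new_connectivity_result()] (directed).
#' @export
granger_spectral <- function(recording, order = "auto", freqs = 1:100,
                             max_order = 20) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- dim(recording$data)
  k <- d[2]
  v <- array(NaN, c(k, k, length(freqs)))
  clamped <- FALSE
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      sub <- recording
      sub$data <- recording$data[, c(a, b), , drop = FALSE]
      sub$channel_labels <- recording$channel_labels[c(a, b)]
      sub$montage <- NULL
      m <- fit_mvar(sub, order = order, max_order = max_order)
      fac <- spectral_factor(m, freqs = freqs, fs = recording$fs)
      S2 <- m$Sigma
      for (fi in seq_along(freqs)) {
        Hf <- fac$H[, , fi]
        Sf <- Hf %*% S2 %*% Conj(t(Hf))
        # b -> a : i = 1 (a), j = 2 (b) in the bivariate system
        gba <- Re(Sf[1, 1]) /
          (Re(Sf[1, 1]) - (S2[2, 2] - S2[1, 2]^2 / S2[1, 1]) * Mod(Hf[1, 2])^2)
        gab <- Re(Sf[2, 2]) /
          (Re(Sf[2, 2]) - (S2[1, 1] - S2[1, 2]^2 / S2[2, 2]) * Mod(Hf[2, 1])^2)
        if (!is.finite(gba) || gba <= 0) { gba <- 1; clamped <- TRUE }
        if (!is.finite(gab) || gab <= 0) { gab <- 1; clamped <- TRUE }
        v[a, b, fi] <- log(gba)   # target a <- source b
        v[b, a, fi] <- log(gab)   # target b <- source a
      }
    }
  }
  v[!is.na(v) & v < 0] <- 0
  if (clamped) warning("nonpositive Granger log argument clamped to 0")
  new_connectivity_result("granger", TRUE, v, freqs, recording$channel_labels)
}

#' The measure registry and one-call computation of all measures
#'
#' `measure_registry()` lists the twelve implemented connectivity measures;
#' `compute_all_measures()` runs any subset on one recording, sharing the
#' spectral tensor and MVAR factorization across measures. A failure in one
#' measure is reported as a warning and does not abort the others.
#'
#' @return `measure_registry()`: tibble with columns `measure`, `directed`,
#'   `family`.
#' @export
measure_registry <- function() {
  tibble::tribble(
    ~measure, ~directed, ~family,
    "csd", FALSE, "spectral",
    "coherence", FALSE, "spectral",
    "imcoh", FALSE, "spectral",
    "power_correlation", FALSE, "spectral",
    "plv", FALSE, "phase",
    "ppc", FALSE, "phase",
    "wppc", FALSE, "phase",
    "wpli", FALSE, "phase",
    "pli", FALSE, "phase",
    "pdc", TRUE, "ar",
    "dtf", TRUE, "ar",
    "granger", TRUE, "ar")
}

#' @rdname measure_registry
#' @param recording an [new_recording()] (preprocessed).
#' @param measures character vector of registry names (default: all 12).
#' @param order MVAR order for the AR-based measures (`"auto"` or integer).
#' @param freqs frequency grid in Hz.
#' @return `compute_all_measures()`: named list of
#'   [new_connectivity_result()] objects.
#' @export
compute_all_measures <- function(recording,
                                 measures = measure_registry()$measure,
                                 order = "auto", freqs = 1:100) {
  known <- measure_registry()$measure
  bad <- setdiff(measures, known)
  if (length(bad) > 0) {
    stop("unknown measures: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  st <- NULL
  fac <- NULL
  get_st <- function() {
    if (is.null(st)) st <<- compute_fft(recording, freqs = freqs)
    st
  }
  get_fac <- function() {
    if (is.null(fac)) {
      m <- fit_mvar(recording, order = order)
      fac <<- spectral_factor(m, freqs = freqs, fs = recording$fs)
    }
    fac
  }
  out <- list()
  for (ms in measures) {
    res <- tryCatch(switch(ms,
      csd = csd_magnitude(get_st()),
      coherence = coherence(get_st()),
      imcoh = imaginary_coherency(get_st()),
      power_correlation = power_correlation(get_st()),
      plv = plv(get_st()),
      ppc = ppc(get_st()),
      wppc = wppc(get_st()),
      wpli = wpli(get_st()),
      pli = pli(get_st()),
      pdc = pdc(get_fac()),
      dtf = dtf(get_fac()),
      granger = granger_spectral(recording, order = order, freqs = freqs)),
      error = function(e) {
        warning(sprintf("measure %s failed: %s", ms, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) out[[ms]] <- res
  }
  out
}
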