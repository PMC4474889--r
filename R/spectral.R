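#' Per-epoch Fourier coefficients on the 1-100 Hz integer grid
#'
#' Computes, for every epoch and channel, the tapered discrete Fourier
#' transform and keeps the coefficients at the 100 integer frequencies
#' 1, 2, ..., 100 Hz. With 2-second epochs the native resolution is 0.5 Hz, so
#' every integer bin is exact; for other epoch lengths coefficients are
#' linearly interpolated (real and imaginary parts) between the two nearest
#' native bins.
#'
#' @param recording an [new_recording()].
#' @param freqs integer frequency grid in Hz (default `1:100`).
#' @param taper `"hann"` (default) or `"none"`.
#' @return object of class `spectral_tensor`: list with `coeffs` (complex
#'   array epochs x channels x frequencies), `freqs`, `fs`, `taper`,
#'   `channel_labels`.
#' @examples
#' rec <- new_recording(array(sin(2 * pi * 10 * (1:1024) / 512),
#'                            c(1, 1, 1024)), 512, "Cz")
#' st <- compute_fft(rec)
#' which.max(Mod(st$coeffs[1, 1, ]))  # 10 Hz bin
#' @export
compute_fft <- function(recording, freqs = 1:100, taper = c("hann", "none")) {
  stopifnot(inherits(recording, "eeg_recording"))
  taper <- match.arg(taper)
  d <- dim(recording$data)
  n <- d[3]
  fs <- recording$fs
  if (n < 2) stop("epochs must contain at least 2 samples", call. = FALSE)
  if (fs < 2 * max(freqs)) {
    stop("sampling rate too low for the requested frequency grid",
         call. = FALSE)
  }
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
       else rep(1, n)
  df <- fs / n
  pos <- freqs / df + 1            # fractional native bin index (1-based)
  lo <- floor(pos); frac <- pos - lo
  out <- array(NA_complex_, c(d[1], d[2], length(freqs)))
  for (e in seq_len(d[1])) {
    xm <- matrix(recording$data[e, , , drop = FALSE], nrow = d[2]) # ch x samp
    X <- stats::mvfft(t(xm * rep(w, each = d[2])))
    co <- X[lo, , drop = FALSE] * (1 - frac) +
      X[pmin(lo + 1, n), , drop = FALSE] * frac
    out[e, , ] <- t(co)
  }
  structure(list(coeffs = out, freqs = freqs, fs = fs, taper = taper,
                 channel_labels = recording$channel_labels),
            class = "spectral_tensor")
}

#' @export
print.spectral_tensor <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<spectral_tensor> %d epochs x %d channels x %d bins (%g-%g Hz, %s taper)\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), x$taper))
  invisible(x)
}

#' Fit a multivariate autoregressive model to epoched data
#'
#' Pooled multichannel least squares: each epoch contributes its own lagged
#' design block (no lag crosses an epoch boundary), all epochs share one
#' coefficient set. With `order = "auto"` the order minimizing the Schwarz
#' (BIC) criterion over `1..max_order` is selected.
#'
#' @param recording an [new_recording()].
#' @param order a positive integer, or `"auto"` (default).
#' @param max_order largest order tried under `"auto"` (default 20).
#' @return an [new_mvar_model()]; `meta` records epochs, samples, BIC. A
#'   warning is raised (and `stable = FALSE` recorded) if the fitted model is
#'   unstable.
#' @export
fit_mvar <- function(recording, order = "auto", max_order = 20) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- dim(recording$data)
  if (identical(order, "auto")) {
    cands <- seq_len(max_order)
    bics <- vapply(cands, function(p) .mvar_ls(recording, p)$bic, numeric(1))
    p <- cands[which.min(bics)]
  } else {
    if (!is.numeric(order) || order < 1) {
      stop("order must be a positive integer or \"auto\"", call. = FALSE)
    }
    p <- as.integer(order)
  }
  if (d[1] * (d[3] - p) * 1 <= d[2] * p * 10) {
    stop("too few samples for the requested order (identifiability)",
         call. = FALSE)
  }
  fit <- .mvar_ls(recording, p)
  m <- new_mvar_model(fit$A, fit$Sigma, labels = recording$channel_labels,
                      meta = list(epochs = d[1], samples_per_epoch = d[3],
                                  bic = fit$bic, order_policy = order))
  if (!m$stable) warning("fitted MVAR model is unstable (spectral radius >= 1)")
  m
}

# Least-squares MVAR fit at fixed order p; returns A, Sigma, BIC.
.mvar_ls <- function(recording, p) {
  d <- dim(recording$data)
  k <- d[2]; n <- d[3]
  if (n <= p) stop("epoch shorter than model order", call. = FALSE)
  XtX <- matrix(0, k * p, k * p)
  XtY <- matrix(0, k * p, k)
  YtY <- matrix(0, k, k)
  n_eff <- 0
  for (e in seq_len(d[1])) {
    x <- t(matrix(recording$data[e, , , drop = FALSE], nrow = k)) # samples x k
    Y <- x[(p + 1):n, , drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(p), function(r) {
      x[(p + 1 - r):(n - r), , drop = FALSE]
    }))
    XtX <- XtX + crossprod(X)
    XtY <- XtY + crossprod(X, Y)
    YtY <- YtY + crossprod(Y)
    n_eff <- n_eff + (n - p)
  }
  B <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  if (is.null(B)) {
    # exactly collinear channels (e.g. an interpolated channel is a convex
    # combination of its neighbours): fall back to a minimally ridged solve
    ridge <- 1e-8 * mean(diag(XtX))
    B <- tryCatch(solve(XtX + diag(ridge, nrow(XtX)), XtY),
                  error = function(e) {
                    stop("singular MVAR regression", call. = FALSE)
                  })
    warning("collinear channels in MVAR regression; ridge-regularized fit")
  }
  Sigma <- (YtY - crossprod(XtY, B)) / n_eff
  Sigma <- (Sigma + t(Sigma)) / 2
  A <- array(0, c(k, k, p))
  for (r in seq_len(p)) A[, , r] <- t(B[((r - 1) * k + 1):(r * k), , drop = FALSE])
  ld <- determinant(Sigma, logarithm = TRUE)
  bic <- as.numeric(ld$modulus) + log(n_eff) * p * k^2 / n_eff
  list(A = A, Sigma = Sigma, bic = bic)
}

#' Frequency-domain factorization of an MVAR model
#'
#' Evaluates, at each requested frequency, the spectral coefficient matrix
#' `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)` and the transfer matrix
#' `H(f) = Abar(f)^{-1}`. Ill-conditioned frequencies (reciprocal condition
#' number below `rcond_min`) yield NaN matrices with a warning.
#'
#' @param model an [new_mvar_model()].
#' @param freqs frequencies in Hz (default `1:100`).
#' @param fs sampling rate in Hz (default 512).
#' @param rcond_min conditioning guard for the inversion (default 1e-12).
#' @return object of class `spectral_factor`: list with complex arrays
#'   `Abar`, `H` (channels x channels x frequencies), `freqs`, `fs`, `Sigma`,
#'   `labels`.
#' @export
spectral_factor <- function(model, freqs = 1:100, fs = 512,
                            rcond_min = 1e-12) {
  stopifnot(inherits(model, "mvar_model"))
  k <- dim(model$A)[1]; p <- model$order
  Abar <- array(NA_complex_, c(k, k, length(freqs)))
  H <- array(NA_complex_, c(k, k, length(freqs)))
  I <- diag(k)
  bad <- 0
  for (fi in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[fi] * seq_len(p) / fs)
    Af <- I + 0i
    for (r in seq_len(p)) Af <- Af - model$A[, , r] * z[r]
    Abar[, , fi] <- Af
    rc <- Mod(rcond(Af))
    if (is.finite(rc) && rc > rcond_min) {
      H[, , fi] <- solve(Af)
    } else {
      H[, , fi] <- NaN + 0i
      bad <- bad + 1
    }
  }
  if (bad > 0) warning(sprintf("%d frequencies ill-conditioned; H set to NaN", bad))
  structure(list(Abar = Abar, H = H, freqs = freqs, fs = fs,
                 Sigma = model$Sigma, labels = model$labels),
            class = "spectral_factor")
}

#' @export
tidy.mvar_model <- function(x, ...) {
  k <- dim(x$A)[1]
  tibble::tibble(
    target = rep(rep(x$labels, times = k), times = x$order),
    source = rep(rep(x$labels, each = k), times = x$order),
    lag = rep(seq_len(x$order), each = k * k),
    coefficient = as.vector(x$A))
}

#' @export
glance.mvar_model <- function(x, ...) {
  tibble::tibble(order = x$order, n_channels = dim(x$A)[1],
                 spectral_radius = x$radius, stable = x$stable,
                 bic = x$meta$bic %||% NA_real_)
}
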