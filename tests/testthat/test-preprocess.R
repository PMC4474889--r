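sine_recording <- function(freq_hz, fs = 512, dur_s = 2, amp = 10) {
  t <- seq_len(fs * dur_s) / fs
  new_recording(array(amp * sin(2 * pi * freq_hz * t), c(1, 1, fs * dur_s)),
                fs, "Cz")
}

rms <- function(x) sqrt(mean(x^2))

test_that("high-pass removes a constant offset", {
  rec <- new_recording(array(7, c(1, 1, 1024)), 512, "Cz")
  out <- apply_filters(rec, low_pass_hz = NULL, notch_hz = NULL)
  expect_lt(abs(mean(out$data)), 0.1)
})

test_that("the 50 Hz notch attenuates mains to below 1% RMS at steady state", {
  rec <- sine_recording(50, dur_s = 20)
  out <- apply_filters(rec, low_pass_hz = NULL, high_pass_hz = NULL)
  interior <- 1025:(20 * 512 - 1024)   # outside the edge-transient zone
  expect_lt(rms(out$data[1, 1, interior]) / rms(rec$data[1, 1, interior]),
            0.01)
})

test_that("a 10 Hz passband tone survives within 5% amplitude", {
  rec <- sine_recording(10)
  out <- apply_filters(rec)
  mid <- 200:800   # avoid filter edge effects at the epoch borders
  expect_equal(rms(out$data[1, 1, mid]), rms(rec$data[1, 1, mid]),
               tolerance = 0.05)
})

test_that("filtering is idempotent in the passband sense", {
  # a signal whose energy lives inside the passband (away from the cutoffs
  # and the notch) must come through a second pass essentially unchanged
  t <- seq_len(4 * 512) / 512
  x <- sin(2 * pi * 5 * t) + 0.7 * sin(2 * pi * 12 * t) +
    0.5 * sin(2 * pi * 40 * t)
  rec <- epoch_data(cbind(a = x, b = 0.5 * x), fs = 512, epoch_len_s = 2)
  once <- apply_filters(rec)
  twice <- apply_filters(once)
  expect_equal(rms(twice$data), rms(once$data), tolerance = 0.01)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- sine_recording(10, fs = 128)
  expect_error(apply_filters(rec, low_pass_hz = 100), "Nyquist|low-pass")
})

test_that("a planted high-noise channel is flagged, clean montages are not", {
  m <- make_montage(16, seed = 2)
  set.seed(42)
  clean <- new_recording(array(rnorm(4 * 16 * 256), c(4, 16, 256)), 256,
                         m$labels, montage = m)
  rep0 <- detect_bad_channels(clean, m)
  expect_length(attr(rep0, "flagged"), 0)
  dirty <- clean
  dirty$data[, 5, ] <- dirty$data[, 5, ] * 100
  rep1 <- detect_bad_channels(dirty, m)
  expect_true(m$labels[5] %in% attr(rep1, "flagged"))
})

test_that("clean i.i.d. montages rarely flag channels (Monte-Carlo calibration)", {
  m <- make_montage(12, seed = 1)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    rec <- new_recording(array(rnorm(2 * 12 * 256), c(2, 12, 256)), 256,
                         m$labels)
    length(attr(detect_bad_channels(rec, m), "flagged")) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("detection refuses degenerate channel counts", {
  m <- make_montage(3)
  rec <- new_recording(array(rnorm(3 * 3 * 64), c(3, 3, 64)), 256, m$labels)
  expect_error(detect_bad_channels(rec, m), "4 channels")
})

test_that("interpolation is the inverse-distance-weighted neighbour mean", {
  # 3 channels on a line: "b" at distance d from "a" and 2d from "c"
  m <- new_montage(c("a", "b", "c"),
                   rbind(c(0, 0.1, 1), c(0, 0, 1), c(0, -0.2, 1)),
                   c("F", "C", "P"), k_neighbors = 2)
  rec <- new_recording(array(c(1, 0, 0, 1, 0, 0), c(1, 3, 2)), 256,
                       c("a", "b", "c"))
  # flag channel b by hand; neighbours a (dist ~0.1) value 1, c (~0.2) value 0
  rep <- structure(tibble::tibble(), flagged = "b", z_thresh = 3,
                   class = "channel_quality_report")
  out <- interpolate_bad_channels(rec, rep, m)
  expect_equal(out$data[1, 2, ], c(2 / 3, 2 / 3), tolerance = 1e-6)
})

test_that("equal constant neighbours interpolate to that constant", {
  m <- make_montage(5, seed = 1)
  rec <- new_recording(array(3, c(2, 5, 10)), 256, m$labels)
  rec$data[, 2, ] <- 99
  rep <- structure(tibble::tibble(), flagged = m$labels[2], z_thresh = 3,
                   class = "channel_quality_report")
  out <- interpolate_bad_channels(rec, rep, m)
  expect_equal(unname(out$data[, 2, ]), matrix(3, 2, 10))
})

test_that("interpolated samples stay inside the neighbours' range (convexity)", {
  m <- make_montage(10, seed = 3)
  set.seed(5)
  rec <- new_recording(array(rnorm(3 * 10 * 128), c(3, 10, 128)), 256,
                       m$labels)
  rep <- structure(tibble::tibble(), flagged = m$labels[4], z_thresh = 3,
                   class = "channel_quality_report")
  out <- interpolate_bad_channels(rec, rep, m)
  nb <- m$neighbors[[4]]
  for (e in 1:3) {
    seg <- matrix(rec$data[e, nb, , drop = FALSE], nrow = length(nb))
    expect_true(all(out$data[e, 4, ] <= apply(seg, 2, max) + 1e-12))
    expect_true(all(out$data[e, 4, ] >= apply(seg, 2, min) - 1e-12))
  }
})

test_that("epoching splits, drops remainders, and inverts exactly", {
  set.seed(1)
  x <- matrix(rnorm(512 * 120 * 2), ncol = 2)    # 120 s at 512 Hz
  rec <- epoch_data(x, fs = 512, epoch_len_s = 2)
  expect_equal(dim(rec$data), c(60, 2, 1024))
  expect_equal(as_continuous(rec), x, ignore_attr = TRUE)

  short <- epoch_data(matrix(rnorm(ceiling(3.5 * 512) * 2), ncol = 2),
                      fs = 512, epoch_len_s = 2)
  expect_equal(dim(short$data)[1], 1)
  expect_error(epoch_data(matrix(rnorm(512), ncol = 1), fs = 512,
                          epoch_len_s = 2), "shorter")
})

test_that("artifact rejection drops exactly the spiking epochs", {
  set.seed(2)
  arr <- array(rnorm(5 * 2 * 100, sd = 10), c(5, 2, 100))
  rec <- new_recording(arr, 256, c("a", "b"))
  out0 <- reject_artifact_epochs(rec)
  expect_equal(dim(out0$data)[1], 5)
  rec$data[3, 1, 50] <- 500
  out1 <- reject_artifact_epochs(rec)
  expect_equal(dim(out1$data)[1], 4)
  expect_equal(attr(out1, "n_rejected"), 1)
  expect_equal(out1$data[3, , ], rec$data[4, , ])
  expect_error(reject_artifact_epochs(rec, abs_amp_uv = 0), "survives")
})
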