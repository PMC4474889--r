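#' Band center frequencies used by the signal generator
#'
#' One oscillation center per canonical EEG band, rounded to integer Hz on the
#' analysis grid: delta 2, theta 6, alpha 10, low-beta 18, high-beta 26,
#' gamma 40. `"beta"` is accepted as an alias for the low-beta center.
#' @return named numeric vector of frequencies in Hz.
#' @export
band_centers <- function() {
  c(delta = 2, theta = 6, alpha = 10,
    low_beta = 18, beta = 18, high_beta = 26, gamma = 40)
}

#' Specify directed couplings for the cohort generator
#'
#' A coupling spec lists directed lagged couplings between channels (or ROIs):
#' each edge `(source, target, band, strength)` plants an influence of the
#' source's activity on the target at the band's oscillation frequency.
#' Strengths live in \[0, 1\] and map directly onto lag-1 MVAR coefficients;
#' the builder scales them down if they would destabilize the system.
#'
#' @param edges a data frame with columns `source`, `target` (channel labels
#'   or 1-based indices), `band` (name in [band_centers()]), `strength`
#'   (in \[0,1\]). May be empty (`NULL`): no coupling.
#' @param centers named numeric vector of per-band oscillation center
#'   frequencies in Hz; defaults to [band_centers()].
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(edges = NULL, centers = band_centers()) {
  if (is.null(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            band = character(), strength = numeric())
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target", "band", "strength") %in% names(edges)))
  if (nrow(edges) > 0) {
    stopifnot(all(edges$strength >= 0), all(edges$strength <= 1),
              all(edges$band %in% names(centers)))
  }
  structure(list(edges = edges, centers = centers), class = "coupling_spec")
}

# Merge two coupling specs (baseline + group effect).
merge_coupling <- function(a, b) {
  coupling_spec(dplyr::bind_rows(a$edges, b$edges), centers = a$centers)
}

#' MVAR model objects
#'
#' A multivariate autoregressive model of order p:
#' `x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t`, `e_t ~ N(0, Sigma)`.
#' Stability means the companion-matrix spectral radius is below 1.
#'
#' @param A numeric array, channels x channels x order.
#' @param Sigma innovation covariance (channels x channels), symmetric PSD.
#' @param labels channel labels.
#' @param meta optional list of fitting metadata.
#' @return object of class `mvar_model` with fields `A`, `Sigma`, `order`,
#'   `labels`, `radius` (companion spectral radius), `stable`, `meta`.
#' @export
new_mvar_model <- function(A, Sigma, labels = NULL, meta = list()) {
  stopifnot(is.array(A), length(dim(A)) == 3, dim(A)[1] == dim(A)[2])
  k <- dim(A)[1]
  stopifnot(nrow(Sigma) == k, ncol(Sigma) == k,
            isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-8)))
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(k))
  r <- companion_radius(A)
  structure(list(A = A, Sigma = (Sigma + t(Sigma)) / 2, order = dim(A)[3],
                 labels = labels, radius = r, stable = r < 1, meta = meta),
            class = "mvar_model")
}

#' Companion-matrix spectral radius of an MVAR coefficient array
#' @param A channels x channels x order array.
#' @return largest eigenvalue modulus of the stacked companion matrix.
#' @export
companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, k * p, k * p)
  for (r in seq_len(p)) C[1:k, ((r - 1) * k + 1):(r * k)] <- A[, , r]
  if (p > 1) C[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> %d channels, order %d, spectral radius %.3f (%s)\n",
              dim(x$A)[1], x$order, x$radius,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Build a stable generating MVAR system from a coupling spec
#'
#' Each channel's own dynamics are a damped order-2 resonator at the center
#' frequency of the band of its first incident coupling (default alpha, 10 Hz,
#' for uncoupled channels): `a1 = 2 rho cos(2 pi f0 / fs)`, `a2 = -rho^2`.
#' Each directed edge `j -> i` of strength `s` couples through the source
#' band's resonator polynomial: `A_1[i, j] += s * 2 rho cos(w)`,
#' `A_2[i, j] -= s * rho^2`. Band-matched coupling keeps the induced shared
#' modes at the coupled band's frequency (a bare lag-1 coupling would shift
#' mode frequencies toward DC) while scaling their pole radius.
#'
#' The assembled system is required to keep its companion spectral radius at
#' or below `stability_margin` (default 0.98 — a hard radius-1 boundary would
#' admit modes with mixing times far beyond an epoch); otherwise all
#' cross-couplings are repeatedly scaled by 0.8 (up to `max_rescale` times)
#' before giving up.
#'
#' @param spec a [coupling_spec()].
#' @param n_series number of channels/ROIs.
#' @param order model order (>= 2 so the resonators fit; extra lags are zero).
#' @param fs sampling rate in Hz (resonator frequencies are relative to it).
#' @param rho resonator pole radius in (0, 1); default 0.95. Closer to 1 gives
#'   sharper spectral peaks.
#' @param labels channel labels; edges may reference labels or indices.
#' @param noise_sd innovation standard deviation (identical across channels).
#' @param max_rescale down-scaling attempts before an error.
#' @param stability_margin target upper bound for the companion spectral
#'   radius of the generated system.
#' @return a stable [new_mvar_model()].
#' @export
build_generating_mvar <- function(spec, n_series, order = 2, fs = 512,
                                  rho = 0.95, labels = NULL, noise_sd = 1,
                                  max_rescale = 25, stability_margin = 0.98) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  order <- max(order, 2L)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(n_series))
  idx <- function(v) {
    if (is.numeric(v)) as.integer(v) else match(v, labels)
  }
  ed <- spec$edges
  src <- idx(ed$source); tgt <- idx(ed$target)
  if (nrow(ed) > 0 && (anyNA(src) || anyNA(tgt))) {
    stop("coupling edges reference unknown channels", call. = FALSE)
  }
  # channel oscillation band: band of first incident edge, else alpha
  ch_band <- rep("alpha", n_series)
  if (nrow(ed) > 0) {
    for (e in rev(seq_len(nrow(ed)))) {
      ch_band[src[e]] <- ed$band[e]
      ch_band[tgt[e]] <- ed$band[e]
    }
  }
  f0 <- spec$centers[ch_band]
  A <- array(0, c(n_series, n_series, order))
  w <- 2 * pi * f0 / fs
  for (ch in seq_len(n_series)) {
    A[ch, ch, 1] <- 2 * rho * cos(w[ch])
    A[ch, ch, 2] <- -rho^2
  }
  strengths <- ed$strength
  margin <- max(stability_margin, rho)   # never demand less than the diagonal
  for (attempt in 0:max_rescale) {
    Ak <- A
    if (nrow(ed) > 0) {
      for (e in seq_len(nrow(ed))) {
        wb <- 2 * pi * spec$centers[[ed$band[e]]] / fs
        Ak[tgt[e], src[e], 1] <- Ak[tgt[e], src[e], 1] +
          strengths[e] * 2 * rho * cos(wb)
        Ak[tgt[e], src[e], 2] <- Ak[tgt[e], src[e], 2] -
          strengths[e] * rho^2
      }
    }
    if (companion_radius(Ak) <= margin + 1e-9) {
      return(new_mvar_model(Ak, diag(noise_sd^2, n_series), labels = labels,
                            meta = list(generator = TRUE, rho = rho,
                                        rescale_attempts = attempt)))
    }
    strengths <- strengths * 0.8
  }
  stop("coupling spec cannot be stabilized by down-scaling", call. = FALSE)
}

#' Simulate one subject's epoched EEG from an MVAR model
#'
#' Each epoch is an independent realization: fresh innovations are drawn, the
#' recursion is run from zero initial conditions, and a burn-in long enough
#' for the start-up transient to die (default `max(10 * order, 512)` samples,
#' i.e. about five time constants of a pole at radius 0.95) is discarded.
#'
#' @param model a stable [new_mvar_model()].
#' @param epochs number of epochs.
#' @param epoch_len_s epoch length in seconds (default 2).
#' @param fs sampling rate in Hz (default 512).
#' @param noise_sd innovation standard deviation (scales `Sigma = noise_sd^2 I`
#'   of generator models; ignored if 0 together with zero coefficients the
#'   output is exactly zero).
#' @param seed integer seed; output is a deterministic function of
#'   (model, dimensions, seed).
#' @param burn_in samples discarded at the start of each epoch.
#' @inheritParams new_recording
#' @return an [new_recording()] with `epochs x channels x samples` data.
#' @export
simulate_subject <- function(model, epochs = 60, epoch_len_s = 2, fs = 512,
                             noise_sd = 1, seed = 1,
                             burn_in = max(10 * model$order, 512),
                             subject_id = "S01", group = NA_character_,
                             montage = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  if (!model$stable) stop("model is unstable; refusing to simulate", call. = FALSE)
  k <- dim(model$A)[1]
  len <- as.integer(round(epoch_len_s * fs))
  set.seed(as.integer(seed))
  out <- array(NA_real_, c(epochs, k, len))
  for (e in seq_len(epochs)) {
    E <- matrix(stats::rnorm((len + burn_in) * k, sd = noise_sd),
                len + burn_in, k)
    X <- mvar_filter_cpp(model$A, E)
    out[e, , ] <- t(X[(burn_in + 1):(burn_in + len), , drop = FALSE])
  }
  new_recording(out, fs, model$labels, subject_id = subject_id, group = group,
                montage = montage)
}

#' Default planted patient effect: a fronto-central theta subnetwork
#'
#' Couples the first `n_nodes` fronto-central (F or C region) channels of a
#' montage into a mutually (bidirectionally) coupled theta-band clique: every
#' unordered pair gets edges in both directions. This is the package's
#' default group difference: patients carry these couplings on top of the
#' baseline, controls do not.
#'
#' A mutually coupled subnetwork — rather than disjoint pairs or a one-way
#' cascade — is chosen deliberately: symmetric coupling splits the channels'
#' degenerate resonator poles into shared network modes (strong band-limited
#' dependence without cascade amplification of amplitude), and the planted
#' pairwise edges form triangles, so degree *and* clustering rise in
#' fronto-central channels — the group signature the pipeline is built to
#' detect. The system builder scales the couplings to the stable region, so
#' `strength` is an upper bound on the realized lag-1 coefficients.
#'
#' @param montage a [new_montage()].
#' @param strength nominal coupling strength (default 0.35).
#' @param band band name (default `"theta"`).
#' @param n_nodes number of fronto-central channels to couple (default 4,
#'   capped at the available F/C channels).
#' @return a [coupling_spec()].
#' @export
default_effect_spec <- function(montage, strength = 0.35, band = "theta",
                                n_nodes = 4) {
  fc <- which(montage$region %in% c("F", "C"))
  if (length(fc) < 2) stop("montage has fewer than 2 fronto-central channels",
                           call. = FALSE)
  nodes <- fc[seq_len(min(n_nodes, length(fc)))]
  pairs <- t(utils::combn(nodes, 2))
  coupling_spec(tibble::tibble(
    source = montage$labels[c(pairs[, 1], pairs[, 2])],
    target = montage$labels[c(pairs[, 2], pairs[, 1])],
    band = band, strength = strength))
}

#' Cohort specifications
#'
#' Bundles everything the cohort generator needs. Defaults mirror the study
#' design the package targets: 18 patients vs 17 controls, 2-second epochs at
#' 512 Hz, 60 epochs (two minutes of clean data) per subject.
#'
#' @param n_patients,n_controls group sizes (>= 1).
#' @param montage sensor montage (or ROI montage).
#' @param baseline [coupling_spec()] shared by both groups.
#' @param effect [coupling_spec()] added to patients only; defaults to the
#'   fronto-central theta effect of [default_effect_spec()].
#' @param epochs_per_subject epochs per subject.
#' @param epoch_len_s epoch length in seconds.
#' @param fs sampling rate in Hz; must be at least twice the highest analysis
#'   frequency (200 Hz for the 1-100 Hz grid).
#' @param noise_sd innovation SD.
#' @param order generator MVAR order.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 18, n_controls = 17,
                        montage = make_montage(16),
                        baseline = coupling_spec(),
                        effect = default_effect_spec(montage),
                        epochs_per_subject = 60, epoch_len_s = 2, fs = 512,
                        noise_sd = 1, order = 2, seed = 1) {
  stopifnot(n_patients >= 1, n_controls >= 1, epoch_len_s > 0)
  if (fs < 200) {
    stop("sampling rate must be >= 200 Hz (Nyquist for the 1-100 Hz grid)",
         call. = FALSE)
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 montage = montage, baseline = baseline, effect = effect,
                 epochs_per_subject = epochs_per_subject,
                 epoch_len_s = epoch_len_s, fs = fs, noise_sd = noise_sd,
                 order = order, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted connectivity structure
#'
#' Builds one generating MVAR system per group (baseline for controls,
#' baseline + effect for patients) and simulates every subject independently
#' with a seed derived from the cohort seed, so the whole cohort is a
#' deterministic function of its spec.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `recordings` (list of [new_recording()], patients
#'   first), `ground_truth` (tibble of planted patient-only edges), and
#'   `manifest` (tibble: subject_id, group, seed).
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 2, n_controls = 2,
#'                                   montage = make_montage(4),
#'                                   epochs_per_subject = 5))
#' length(co$recordings)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- length(spec$montage$labels)
  m_control <- build_generating_mvar(spec$baseline, n, order = spec$order,
                                     fs = spec$fs, labels = spec$montage$labels,
                                     noise_sd = spec$noise_sd)
  m_patient <- build_generating_mvar(merge_coupling(spec$baseline, spec$effect),
                                     n, order = spec$order, fs = spec$fs,
                                     labels = spec$montage$labels,
                                     noise_sd = spec$noise_sd)
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  ids <- sprintf("%s%02d", ifelse(groups == "patient", "P", "C"),
                 c(seq_len(spec$n_patients), seq_len(spec$n_controls)))
  seeds <- vapply(seq_along(groups), function(i) derive_seed(spec$seed, i), 1L)
  recordings <- lapply(seq_along(groups), function(i) {
    simulate_subject(if (groups[i] == "patient") m_patient else m_control,
                     epochs = spec$epochs_per_subject,
                     epoch_len_s = spec$epoch_len_s, fs = spec$fs,
                     noise_sd = spec$noise_sd, seed = seeds[i],
                     subject_id = ids[i], group = groups[i],
                     montage = spec$montage)
  })
  list(recordings = recordings,
       ground_truth = spec$effect$edges,
       manifest = tibble::tibble(subject_id = ids, group = groups,
                                 seed = seeds))
}

#' The default 17-ROI set (DMN / CEN / SN)
#'
#' A documented stand-in set of 17 named regions of interest covering the
#' default-mode, central-executive and salience networks; names are
#' config-overridable wherever a ROI montage is accepted.
#'
#' @return tibble with columns `roi` and `network`.
#' @export
default_roi_set <- function() {
  tibble::tibble(
    roi = c("VMPFC", "DMPFC", "PCC", "Precuneus", "IPL_L", "IPL_R",
            "DLPFC_L", "DLPFC_R", "PPC_L", "PPC_R",
            "AI_L", "AI_R", "ACC", "VLPFC_L", "VLPFC_R", "preSMA", "dmThal"),
    network = c(rep("DMN", 6), rep("CEN", 4), rep("SN", 7)))
}

#' Build a 17-node ROI montage
#'
#' ROI "positions" are a quasi-uniform hemisphere layout (they only serve
#' neighbour/adjacency bookkeeping); network tags are attached per ROI.
#' @param roi_set tibble with columns `roi`, `network`; default
#'   [default_roi_set()].
#' @param k_neighbors neighbour count.
#' @return a [new_montage()] with `networks` set.
#' @export
make_roi_montage <- function(roi_set = default_roi_set(), k_neighbors = 4) {
  n <- nrow(roi_set)
  base <- make_montage(n, seed = 1, k_neighbors = k_neighbors)
  new_montage(roi_set$roi, base$positions, base$region,
              k_neighbors = k_neighbors, networks = roi_set$network)
}

#' Default salience-network patient effect for the nodal track
#'
#' Directed beta-band couplings internal to the salience network
#' (anterior insula to ACC, bilaterally).
#' @param montage a ROI montage from [make_roi_montage()].
#' @param strength coupling strength (default 0.35).
#' @param band band name (default `"beta"`).
#' @return a [coupling_spec()].
#' @export
default_sn_effect_spec <- function(montage, strength = 0.35, band = "beta") {
  stopifnot(all(c("AI_L", "AI_R", "ACC") %in% montage$labels))
  coupling_spec(tibble::tibble(
    source = c("AI_L", "AI_R"), target = c("ACC", "ACC"),
    band = band, strength = strength))
}

#' Generate a synthetic ROI (nodal-track) cohort
#'
#' As [generate_cohort()] but the channels are the 17 ROI signals of
#' [make_roi_montage()] and the default patient effect is the SN-internal
#' coupling of [default_sn_effect_spec()].
#'
#' @param spec a [cohort_spec()] whose montage is a ROI montage; if called
#'   with the scalp default montage, a 17-ROI montage and SN effect are
#'   substituted.
#' @return as [generate_cohort()].
#' @export
generate_roi_cohort <- function(spec = NULL) {
  if (is.null(spec)) {
    m <- make_roi_montage()
    spec <- cohort_spec(montage = m, effect = default_sn_effect_spec(m))
  }
  if (is.null(spec$montage$networks)) {
    stop("ROI cohorts need a montage with network tags (make_roi_montage)",
         call. = FALSE)
  }
  generate_cohort(spec)
}
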