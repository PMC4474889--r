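#' Vectorized two-sample unpaired (pooled-variance) t-tests
#'
#' Classic Student t with pooled variance, two-sided, applied independently
#' to every unit (edge, node, or channel-frequency cell). The sign convention
#' is fixed: `t > 0` means the patient mean exceeds the control mean.
#' Degenerate units (zero pooled variance) get `p = 1` when the means are
#' identical and `p = 0` (flagged) otherwise.
#'
#' @param patients numeric matrix, subjects x units (group A, "patients").
#' @param controls numeric matrix, subjects x units (group B, "controls").
#' @param alpha significance level for the mask (default 0.05).
#' @param units optional tibble of per-unit metadata (one row per unit),
#'   bound onto the output.
#' @return object of class `group_comparison`: tibble with columns `unit`,
#'   `t`, `p`, `mean_patient`, `mean_control`, `significant`, `degenerate`,
#'   plus attribute `alpha`.
#' @export
edgewise_ttest <- function(patients, controls, alpha = 0.05, units = NULL) {
  patients <- as.matrix(patients); controls <- as.matrix(controls)
  stopifnot(ncol(patients) == ncol(controls),
            nrow(patients) >= 2, nrow(controls) >= 2)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  na <- nrow(patients); nb <- nrow(controls)
  ma <- colMeans(patients); mb <- colMeans(controls)
  va <- apply(patients, 2, stats::var); vb <- apply(controls, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  df <- na + nb - 2
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- !is.na(se) & se == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  tt[degen] <- ifelse(ma[degen] == mb[degen], 0, Inf * sign(ma - mb)[degen])
  out <- tibble::tibble(unit = seq_along(tt), t = tt, p = p,
                        mean_patient = ma, mean_control = mb,
                        significant = !is.na(p) & p < alpha,
                        degenerate = degen)
  if (!is.null(units)) out <- dplyr::bind_cols(units, out[-1])
  structure(out, alpha = alpha,
            class = c("group_comparison", class(out)))
}

#' Per-unit variance-ratio (F) tests
#'
#' `F = s_A^2 / s_B^2` with `(n_A - 1, n_B - 1)` degrees of freedom;
#' two-sided p by doubling the smaller tail. Zero denominator variance gives
#' NaN.
#' @param patients,controls numeric matrices, subjects x units.
#' @return tibble with columns `unit`, `F`, `p`, `var_patient`,
#'   `var_control`.
#' @export
variance_ratio_test <- function(patients, controls) {
  patients <- as.matrix(patients); controls <- as.matrix(controls)
  stopifnot(nrow(patients) >= 3, nrow(controls) >= 3)
  va <- apply(patients, 2, stats::var)
  vb <- apply(controls, 2, stats::var)
  Fv <- ifelse(vb > 0, va / vb, NaN)
  dfa <- nrow(patients) - 1; dfb <- nrow(controls) - 1
  lower <- stats::pf(Fv, dfa, dfb)
  p <- pmin(1, 2 * pmin(lower, 1 - lower))
  tibble::tibble(unit = seq_along(Fv), F = Fv, p = p,
                 var_patient = va, var_control = vb)
}

#' Channel-by-frequency group comparison of a node metric
#'
#' Runs [edgewise_ttest()] on every (channel, frequency) cell of a per-subject
#' metric array — the non-aggregated analysis that feeds cluster
#' identification.
#'
#' @param patients numeric array, subjects x channels x frequencies.
#' @param controls numeric array, same channel/frequency dimensions.
#' @param alpha significance level.
#' @param channel_labels,freqs optional axis labels.
#' @return a `group_comparison` tibble with `channel` and `freq` columns and
#'   attributes `mask` and `t_matrix` (channels x frequencies matrices).
#' @export
metric_comparison_per_frequency <- function(patients, controls, alpha = 0.05,
                                            channel_labels = NULL,
                                            freqs = NULL) {
  stopifnot(length(dim(patients)) == 3, length(dim(controls)) == 3,
            all(dim(patients)[-1] == dim(controls)[-1]))
  k <- dim(patients)[2]; nf <- dim(patients)[3]
  channel_labels <- channel_labels %||% sprintf("E%03d", seq_len(k))
  freqs <- freqs %||% seq_len(nf)
  pa <- matrix(patients, nrow = dim(patients)[1])   # cells column-major (ch fast)
  co <- matrix(controls, nrow = dim(controls)[1])
  units <- tibble::tibble(channel = rep(channel_labels, times = nf),
                          freq = rep(freqs, each = k))
  res <- edgewise_ttest(pa, co, alpha = alpha, units = units)
  attr(res, "mask") <- matrix(res$significant, k, nf,
                              dimnames = list(channel_labels, freqs))
  attr(res, "t_matrix") <- matrix(res$t, k, nf,
                                  dimnames = list(channel_labels, freqs))
  res
}

#' Identify clusters of significant channel-frequency cells
#'
#' Connected components of the significance mask under the joint adjacency:
#' two cells are adjacent when they share a frequency bin and are montage
#' neighbours, or share a channel and sit in adjacent (+/- 1) frequency bins.
#' Clusters are returned sorted by mass (sum of |t| over members; member
#' count when `t` is not supplied).
#'
#' @param mask logical matrix, channels x frequencies.
#' @param montage a [new_montage()] supplying spatial adjacency.
#' @param t_matrix optional matrix of t statistics matching `mask`.
#' @return tibble with columns `cluster`, `channel`, `freq`, and attribute
#'   `summary` (tibble: cluster, size, mass).
#' @export
find_clusters <- function(mask, montage, t_matrix = NULL) {
  stopifnot(is.matrix(mask), nrow(mask) == length(montage$labels))
  adj <- montage_adjacency(montage)
  k <- nrow(mask); nf <- ncol(mask)
  id <- matrix(0L, k, nf)
  nxt <- 0L
  for (start in which(mask)) {
    if (id[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    id[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ch <- (cur - 1) %% k + 1
      fr <- (cur - 1) %/% k + 1
      nbr_ch <- which(adj[ch, ])
      cand <- c((fr - 1) * k + nbr_ch,                       # same bin, neighbours
                if (fr > 1) (fr - 2) * k + ch,               # bin below
                if (fr < nf) fr * k + ch)                    # bin above
      cand <- cand[mask[cand] & id[cand] == 0]
      id[cand] <- nxt
      queue <- c(queue, cand)
    }
  }
  if (nxt == 0L) {
    out <- tibble::tibble(cluster = integer(), channel = character(),
                          freq = integer())
    attr(out, "summary") <- tibble::tibble(cluster = integer(),
                                           size = integer(), mass = numeric())
    return(out)
  }
  cells <- which(id > 0)
  ch <- (cells - 1) %% k + 1
  fr <- (cells - 1) %/% k + 1
  mass_of <- vapply(seq_len(nxt), function(cl) {
    mem <- cells[id[cells] == cl]
    if (is.null(t_matrix)) length(mem) else sum(abs(t_matrix[mem]))
  }, numeric(1))
  rank <- order(-mass_of)
  relabel <- match(seq_len(nxt), rank)
  out <- tibble::tibble(cluster = relabel[id[cells]],
                        channel = montage$labels[ch],
                        freq = as.integer(colnames(mask) %||% seq_len(nf))[fr])
  out <- dplyr::arrange(out, .data$cluster, .data$freq)
  attr(out, "summary") <- tibble::tibble(
    cluster = seq_len(nxt),
    size = as.integer(table(factor(relabel[id[cells]], seq_len(nxt)))),
    mass = mass_of[rank])
  out
}

#' Band-average a per-frequency assortativity trace
#'
#' Assortativity yields one value per frequency for the whole network; this
#' averages it over each band's bins, excluding NaN (undefined) frequencies.
#' @param values numeric vector indexed by `freqs`.
#' @param scheme a [band_scheme()]-style tibble.
#' @param freqs frequency grid matching `values` (default `1:length(values)`).
#' @return tibble with columns `band`, `value`, `n_bins_used`.
#' @export
aggregate_assortativity_bands <- function(values, scheme = band_scheme(),
                                          freqs = seq_along(values)) {
  .validate_scheme(scheme)
  purrr::pmap_dfr(scheme, function(band, lo, hi) {
    v <- values[freqs >= lo & freqs <= hi]
    v <- v[!is.na(v)]
    tibble::tibble(band = band,
                   value = if (length(v) > 0) mean(v) else NaN,
                   n_bins_used = length(v))
  })
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(n_units = nrow(x), alpha = attr(x, "alpha"),
                 n_significant = sum(x$significant),
                 prop_significant = mean(x$significant),
                 min_p = suppressWarnings(min(x$p, na.rm = TRUE)))
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}
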