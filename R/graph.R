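#' Frequency band schemes
#'
#' The scalp-track scheme splits beta: delta 1-3, theta 4-7, alpha 8-13,
#' low-beta 14-21, high-beta 22-30, gamma 31-60 Hz (integer-Hz edges on the
#' 1-100 Hz grid). The nodal-track scheme collapses beta to 14-30 Hz.
#'
#' @return tibble with columns `band`, `lo`, `hi` (inclusive integer edges).
#' @export
band_scheme <- function() {
  tibble::tribble(
    ~band, ~lo, ~hi,
    "delta", 1, 3,
    "theta", 4, 7,
    "alpha", 8, 13,
    "low_beta", 14, 21,
    "high_beta", 22, 30,
    "gamma", 31, 60)
}

#' @rdname band_scheme
#' @export
band_scheme_nodal <- function() {
  tibble::tribble(
    ~band, ~lo, ~hi,
    "delta", 1, 3,
    "theta", 4, 7,
    "alpha", 8, 13,
    "beta", 14, 30,
    "gamma", 31, 60)
}

.validate_scheme <- function(scheme) {
  stopifnot(all(c("band", "lo", "hi") %in% names(scheme)))
  if (any(scheme$lo > scheme$hi)) stop("empty band in scheme", call. = FALSE)
  bins <- unlist(Map(seq, scheme$lo, scheme$hi))
  if (anyDuplicated(bins)) stop("overlapping bands in scheme", call. = FALSE)
  invisible(scheme)
}

#' Average a connectivity result over frequency bands
#'
#' Arithmetic mean of each entry over the integer bins of each band;
#' NaN bins are excluded from the mean (an entry whose bins are all NaN stays
#' NaN — expected on the diagonal, warned about elsewhere).
#'
#' @param result a full-grid [new_connectivity_result()].
#' @param scheme a [band_scheme()]-style tibble.
#' @return a band-indexed `connectivity_result` (`axis = "band"`).
#' @export
aggregate_bands <- function(result, scheme = band_scheme()) {
  stopifnot(inherits(result, "connectivity_result"))
  if (result$axis != "frequency") {
    stop("result is already band-aggregated", call. = FALSE)
  }
  .validate_scheme(scheme)
  k <- dim(result$values)[1]
  out <- array(NA_real_, c(k, k, nrow(scheme)))
  warn_nan <- FALSE
  for (b in seq_len(nrow(scheme))) {
    bins <- which(result$freqs >= scheme$lo[b] & result$freqs <= scheme$hi[b])
    if (length(bins) == 0) stop("band off the frequency grid", call. = FALSE)
    slab <- result$values[, , bins, drop = FALSE]
    nan <- is.nan(slab) | is.na(slab)
    slab[nan] <- 0
    m <- rowSums(slab, dims = 2) / rowSums(!nan, dims = 2)   # 0/0 -> NaN
    off <- m[row(m) != col(m)]
    if (any(is.nan(off) | is.na(off))) warn_nan <- TRUE
    out[, , b] <- m
  }
  if (warn_nan) warning("some off-diagonal entries are NaN across a whole band")
  new_connectivity_result(result$measure, result$directed, out, scheme$band,
                          result$labels, axis = "band")
}

#' Network graph objects
#'
#' A binarized graph obtained by proportional thresholding of one band (or
#' frequency) slice of a connectivity result.
#' @param adjacency logical/0-1 matrix (no self-loops; symmetric when
#'   undirected).
#' @param directed logical flag.
#' @param measure,band provenance strings.
#' @return object of class `network_graph`.
#' @export
new_network_graph <- function(adjacency, directed, measure = NA_character_,
                              band = NA_character_) {
  adjacency <- (adjacency != 0) * 1L
  diag(adjacency) <- 0L
  if (!directed && !identical(adjacency, t(adjacency))) {
    stop("undirected adjacency must be symmetric", call. = FALSE)
  }
  n_edges <- if (directed) sum(adjacency) else sum(adjacency) / 2
  structure(list(adjacency = adjacency, directed = directed,
                 n_edges = n_edges, measure = measure, band = band),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %s/%s: %d nodes, %d %s edges\n",
              x$measure, x$band, nrow(x$adjacency), x$n_edges,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' @export
tidy.network_graph <- function(x, ...) {
  idx <- which(x$adjacency == 1, arr.ind = TRUE)
  if (!x$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  lab <- rownames(x$adjacency) %||% as.character(seq_len(nrow(x$adjacency)))
  tibble::tibble(from = lab[idx[, 2]], to = lab[idx[, 1]])
}

#' Proportional thresholding of a connectivity matrix
#'
#' Ranks all candidate entries (upper triangle for undirected measures, all
#' off-diagonal ordered pairs for directed ones) by weight, keeps the top
#' `round(fraction * n_candidates)`, and binarizes. Ties at the cut are
#' broken deterministically in row-major index order; NaN weights sort last.
#'
#' @param result a band-aggregated [new_connectivity_result()] (or any
#'   `connectivity_result`).
#' @param band which band/frequency slice to threshold (name or index).
#' @param fraction fraction of candidate pairs to retain, in (0, 1\];
#'   default 0.2.
#' @return a [new_network_graph()].
#' @export
threshold_top_fraction <- function(result, band = 1, fraction = 0.2) {
  stopifnot(inherits(result, "connectivity_result"))
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  bi <- if (is.character(band)) match(band, as.character(result$freqs)) else band
  if (is.na(bi) || bi < 1 || bi > dim(result$values)[3]) {
    stop("unknown band: ", band, call. = FALSE)
  }
  W <- result$values[, , bi]
  k <- nrow(W)
  if (all(is.na(W[row(W) != col(W)]))) {
    stop("all-NaN connectivity matrix: cannot threshold", call. = FALSE)
  }
  if (result$directed) {
    cand <- which(row(W) != col(W))              # column-major order of pairs
  } else {
    cand <- which(upper.tri(W))
  }
  # row-major position of each candidate, for the documented tie-break
  rowmajor <- (row(W)[cand] - 1) * k + col(W)[cand]
  w <- W[cand]
  w[is.na(w)] <- -Inf
  keep_n <- round(fraction * length(cand))
  ord <- order(-w, rowmajor)
  keep <- cand[ord[seq_len(keep_n)]]
  adj <- matrix(0L, k, k, dimnames = dimnames(W))
  adj[keep] <- 1L
  if (!result$directed) adj <- adj + t(adj)
  new_network_graph(adj, result$directed, measure = result$measure,
                    band = as.character(result$freqs[bi]))
}

#' Node degree
#'
#' Undirected: incident edge count. Directed: in-degree plus out-degree.
#' @param graph a [new_network_graph()].
#' @return named integer vector, one value per node.
#' @export
graph_degree <- function(graph) {
  A <- graph$adjacency
  deg <- if (graph$directed) rowSums(A) + colSums(A) else rowSums(A)
  stats::setNames(as.integer(deg),
                  rownames(A) %||% as.character(seq_len(nrow(A))))
}

#' Clustering coefficient
#'
#' Undirected: `2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through node i. Directed: Fagiolo's generalization on the binarized
#' digraph, `[ (A + A^T)^3 ]_ii / (2 (d_i^tot (d_i^tot - 1) - 2 d_i^bi))`.
#' Nodes of degree < 2 get 0 by convention.
#' @param graph a [new_network_graph()].
#' @return named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  A <- graph$adjacency * 1
  n <- nrow(A)
  if (graph$directed) {
    S <- A + t(A)
    t3 <- diag(S %*% S %*% S) / 2
    dtot <- rowSums(A) + colSums(A)
    dbi <- diag(A %*% A)
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    cc <- ifelse(den > 0, t3 / den, 0)
  } else {
    tri <- diag(A %*% A %*% A) / 2
    k <- rowSums(A)
    den <- k * (k - 1) / 2
    cc <- ifelse(k >= 2, tri / den, 0)           # = 2 tri / (k (k-1))
  }
  stats::setNames(as.numeric(cc),
                  rownames(A) %||% as.character(seq_len(n)))
}

#' Degree assortativity
#'
#' Newman's degree assortativity: the Pearson correlation of end-node degrees
#' over the edge list; for undirected graphs each edge contributes both
#' orientations. Directed graphs are measured on their undirected skeleton.
#' Regular graphs (zero degree variance over edge endpoints) return NaN with
#' a warning.
#' @param graph a [new_network_graph()].
#' @return scalar in \[-1, 1\] or NaN.
#' @export
assortativity_degree <- function(graph) {
  A <- graph$adjacency
  if (graph$directed) A <- ((A + t(A)) > 0) * 1L
  if (sum(A) / 2 < 2) stop("assortativity needs at least 2 edges", call. = FALSE)
  deg <- rowSums(A)
  idx <- which(A == 1, arr.ind = TRUE)            # both orientations
  x <- deg[idx[, 1]]; y <- deg[idx[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("regular graph: assortativity undefined")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Average a per-node metric over scalp regions
#'
#' @param values named numeric vector of node metrics (names = channel
#'   labels) or unnamed vector in montage order.
#' @param montage a [new_montage()].
#' @return tibble with columns `region`, `mean_value`, `n_channels`.
#' @export
region_average <- function(values, montage) {
  if (!is.null(names(values))) {
    values <- values[montage$labels]
  }
  tibble::tibble(region = montage$region, value = as.numeric(values)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_channels = dplyr::n(), .groups = "drop")
}
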