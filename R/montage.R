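#' Sensor montages
#'
#' A montage describes where each channel sits on the (idealised, unit-radius)
#' scalp, which scalp region it belongs to, and which channels count as its
#' spatial neighbours. Region codes follow the frontal / central / parietal /
#' occipital convention ("F", "C", "P", "O"). Neighbour lists drive bad-channel
#' interpolation and spatial cluster adjacency.
#'
#' @param labels character vector of unique channel labels.
#' @param positions numeric matrix (channels x 3) of unit-sphere coordinates;
#'   +y is anterior, +z is up.
#' @param region character vector of region codes, one per channel.
#' @param k_neighbors number of nearest neighbours (by chord distance) to
#'   record per channel; capped at `n - 1`.
#' @param networks optional character vector of resting-state network tags
#'   (e.g. "DMN", "CEN", "SN") for ROI-style montages.
#'
#' @return An object of class `montage`: a list with elements `labels`,
#'   `positions`, `region`, `neighbors` (list of integer vectors) and
#'   optionally `networks`.
#' @export
new_montage <- function(labels, positions, region, k_neighbors = 4,
                        networks = NULL) {
  n <- length(labels)
  stopifnot(n >= 2, !anyDuplicated(labels),
            is.matrix(positions), nrow(positions) == n, ncol(positions) == 3,
            length(region) == n)
  k <- max(1L, min(as.integer(k_neighbors), n - 1L))
  d <- as.matrix(stats::dist(positions))
  neighbors <- lapply(seq_len(n), function(i) {
    order(d[i, ])[-1][seq_len(k)]
  })
  structure(
    list(labels = labels, positions = positions,
         region = region, neighbors = neighbors,
         networks = networks),
    class = "montage")
}

#' Build a quasi-uniform scalp montage
#'
#' Places `n_channels` electrodes on the upper hemisphere along a Fibonacci
#' spiral (deterministic, quasi-uniform), assigns F/C/P/O regions by
#' anterior-posterior position, and records the `k_neighbors` nearest channels
#' of each channel. The layout is fully determined by `n_channels` and `seed`.
#'
#' @param n_channels number of electrodes (at least 2).
#' @param seed integer seed (layout is deterministic; the seed only controls a
#'   tiny positional jitter that breaks exact distance ties).
#' @param k_neighbors nearest-neighbour count, default 4.
#' @return A [new_montage()] object.
#' @examples
#' m <- make_montage(16, seed = 1)
#' table(m$region)
#' @export
make_montage <- function(n_channels, seed = 1, k_neighbors = 4) {
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  n <- as.integer(n_channels)
  i <- seq_len(n) - 1
  z <- (i + 0.5) / n                  # height above the equatorial plane
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  set.seed(as.integer(seed))
  pos <- pos + matrix(stats::rnorm(3 * n, sd = 1e-6), n, 3)
  # anterior-posterior bands: front, central, parietal, occipital
  region <- cut(pos[, "y"], breaks = c(-Inf, -0.4, 0, 0.4, Inf),
                labels = c("O", "P", "C", "F"))
  region <- as.character(region)
  labels <- sprintf("E%03d", seq_len(n))
  new_montage(labels, pos, region, k_neighbors = k_neighbors)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels, regions: %s\n", length(x$labels),
              paste(sprintf("%s=%d", names(table(x$region)),
                            table(x$region)), collapse = " ")))
  invisible(x)
}

#' @rdname new_montage
#' @param x a montage.
#' @param ... unused.
#' @export
as_tibble.montage <- function(x, ...) {
  pos <- x$positions
  labs <- x$labels
  regions <- x$region
  nets <- if (is.null(x$networks)) NA_character_ else x$networks
  nbrs <- lapply(x$neighbors, function(i) labs[i])
  tibble::tibble(channel = labs, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 region = regions, network = nets, neighbors = nbrs)
}

#' Read / write a montage as tab-separated text
#'
#' Columns: `channel`, `x`, `y`, `z`, `region` and optionally `network`.
#' @param montage a montage object.
#' @param path file path.
#' @param k_neighbors neighbour count used when rebuilding neighbour lists.
#' @return `read_montage()` returns a montage; `write_montage()` returns
#'   `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  df <- as_tibble.montage(montage)
  df$neighbors <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path, k_neighbors = 4) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel", "x", "y", "z", "region")
  if (!all(need %in% names(df))) {
    stop("montage file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  networks <- if ("network" %in% names(df) && !all(is.na(df$network))) {
    df$network
  } else NULL
  new_montage(df$channel, as.matrix(df[, c("x", "y", "z")]), df$region,
              k_neighbors = k_neighbors, networks = networks)
}

# Symmetric channel adjacency (union of neighbour relations), used for
# spatial cluster finding.
montage_adjacency <- function(montage) {
  n <- length(montage$labels)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, montage$neighbors[[i]]] <- TRUE
  adj | t(adj)
}
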