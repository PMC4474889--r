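band_result <- function(W, directed = FALSE, bands = "theta") {
  arr <- array(W, c(nrow(W), ncol(W), length(bands)))
  new_connectivity_result("test", directed, arr, bands,
                          sprintf("E%03d", seq_len(nrow(W))), axis = "band")
}

test_that("band edges partition the grid with the documented bin counts", {
  sch <- band_scheme()
  bins <- unlist(Map(seq, sch$lo, sch$hi))
  expect_false(anyDuplicated(bins) > 0)
  expect_equal(sch$hi[sch$band == "gamma"] - sch$lo[sch$band == "gamma"] + 1,
               30)   # 31..60 inclusive
  expect_equal(range(bins), c(1, 60))
})

test_that("band aggregation averages bins, excludes NaN, respects constants", {
  set.seed(1)
  arr <- array(stats::runif(3 * 3 * 100), c(3, 3, 100))
  cr <- new_connectivity_result("x", FALSE, arr, 1:100, c("a", "b", "c"))
  ag <- aggregate_bands(cr)
  # delta 1,2,3 Hz mean by hand
  expect_equal(ag$values[1, 2, 1], mean(arr[1, 2, 1:3]))
  # gamma = mean of 30 bins
  expect_equal(ag$values[2, 3, 6], mean(arr[2, 3, 31:60]))
  const <- new_connectivity_result("c", FALSE, array(0.4, c(2, 2, 100)),
                                   1:100, c("a", "b"))
  agc <- aggregate_bands(const)
  expect_equal(as.vector(agc$values[1, 2, ]), rep(0.4, 6))
  # NaN-excluded mean
  arr2 <- array(1, c(2, 2, 100)); arr2[1, 2, 4] <- NaN; arr2[2, 1, 4] <- NaN
  cr2 <- new_connectivity_result("y", FALSE, arr2, 1:100, c("a", "b"))
  expect_equal(aggregate_bands(cr2)$values[1, 2, 2], 1)   # theta 4:7, NaN at 4
})

test_that("proportional thresholding keeps round(fraction x candidates) edges", {
  # the 128-channel case: 8128 undirected pairs -> 1626 edges at 20%
  set.seed(2)
  W <- matrix(stats::runif(128^2), 128, 128); W <- (W + t(W)) / 2
  g <- threshold_top_fraction(band_result(W), band = "theta", fraction = 0.2)
  expect_equal(choose(128, 2), 8128)
  expect_equal(g$n_edges, round(0.2 * 8128))
  expect_equal(g$n_edges, 1626)
  # fraction 1 -> complete graph
  gc <- threshold_top_fraction(band_result(W), fraction = 1)
  expect_equal(gc$n_edges, 8128)
  expect_equal(unname(graph_degree(gc)), rep(127L, 128))
})

test_that("all-equal weights fall back to the deterministic tie-break at full size", {
  W <- matrix(1, 128, 128)
  g1 <- threshold_top_fraction(band_result(W), fraction = 0.2)
  g2 <- threshold_top_fraction(band_result(W), fraction = 0.2)
  expect_equal(g1$n_edges, 1626)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("thresholding is monotone in the retained fraction", {
  set.seed(3)
  for (s in 1:5) {
    W <- matrix(stats::runif(20^2), 20, 20); W <- W + t(W)
    ga <- threshold_top_fraction(band_result(W), fraction = 0.1)
    gb <- threshold_top_fraction(band_result(W), fraction = 0.35)
    expect_true(all(gb$adjacency[ga$adjacency == 1] == 1))
  }
})

test_that("directed thresholding ranks all ordered pairs", {
  set.seed(4)
  W <- matrix(stats::runif(25), 5, 5)
  g <- threshold_top_fraction(band_result(W, directed = TRUE), fraction = 0.2)
  expect_equal(g$n_edges, round(0.2 * 20))
  expect_true(g$directed)
})

test_that("degree obeys closed forms and the handshake lemma", {
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  g <- new_network_graph(star, FALSE)
  expect_equal(unname(graph_degree(g)), c(3L, 1L, 1L, 1L))
  for (s in 1:20) {
    gr <- random_graph(sample(4:15, 1), p_edge = stats::runif(1, 0.2, 0.8),
                       seed = 400 + s)
    expect_equal(sum(graph_degree(gr)), 2 * gr$n_edges)
  }
})

test_that("clustering coefficient: triangle 1, path 0, brute-force on random graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coefficient(new_network_graph(tri, FALSE))),
               rep(1, 3))
  path <- matrix(0, 4, 4); path[cbind(1:3, 2:4)] <- 1; path <- path + t(path)
  expect_equal(unname(clustering_coefficient(new_network_graph(path, FALSE))),
               rep(0, 4))
  for (s in 1:30) {
    gr <- random_graph(sample(4:20, 1), p_edge = stats::runif(1, 0.1, 0.9),
                       seed = 500 + s)
    expect_equal(unname(clustering_coefficient(gr)),
                 brute_clustering(gr$adjacency), tolerance = 1e-12)
  }
})

test_that("directed clustering matches brute-force triple enumeration", {
  for (s in 1:15) {
    set.seed(600 + s)
    n <- sample(4:10, 1)
    A <- matrix(stats::rbinom(n * n, 1, 0.4), n, n); diag(A) <- 0
    g <- new_network_graph(A, directed = TRUE)
    expect_equal(unname(clustering_coefficient(g)),
                 brute_clustering_directed(g$adjacency), tolerance = 1e-12)
  }
})

test_that("clustering agrees with igraph's local transitivity", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    gr <- random_graph(12, p_edge = 0.4, seed = 800 + s)
    ig <- igraph::graph_from_adjacency_matrix(gr$adjacency, mode = "undirected")
    ref <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    # igraph leaves degree-1 vertices NaN under some versions; align convention
    ref[is.na(ref)] <- 0
    expect_equal(unname(clustering_coefficient(gr)), ref, tolerance = 1e-12)
  }
})

test_that("assortativity: star is -1, regular graphs are NaN, brute-force agreement", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(assortativity_degree(new_network_graph(star, FALSE)), -1,
               tolerance = 1e-12)
  comp <- matrix(1, 4, 4); diag(comp) <- 0
  expect_warning(r <- assortativity_degree(new_network_graph(comp, FALSE)),
                 "regular")
  expect_true(is.nan(r))
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- 1; two_tri[4:6, 4:6] <- 1; diag(two_tri) <- 0
  expect_warning(r2 <- assortativity_degree(new_network_graph(two_tri, FALSE)))
  expect_true(is.nan(r2))
  for (s in 1:30) {
    gr <- random_graph(sample(5:20, 1), p_edge = stats::runif(1, 0.2, 0.7),
                       seed = 900 + s)
    if (gr$n_edges < 2) next
    got <- suppressWarnings(assortativity_degree(gr))
    ref <- brute_assortativity(gr$adjacency)
    if (is.nan(ref)) expect_true(is.nan(got)) else {
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("assortativity agrees with igraph on non-degenerate graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    gr <- random_graph(15, p_edge = 0.3, seed = 1000 + s)
    got <- suppressWarnings(assortativity_degree(gr))
    ig <- igraph::graph_from_adjacency_matrix(gr$adjacency, mode = "undirected")
    ref <- igraph::assortativity_degree(ig)
    if (!is.nan(got)) expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("region averages reduce to plain means with hand-checked values", {
  m <- make_montage(8, seed = 1)
  v <- seq(0.1, 0.8, by = 0.1)
  ra <- region_average(stats::setNames(v, m$labels), m)
  for (rg in unique(m$region)) {
    expect_equal(ra$mean_value[ra$region == rg], mean(v[m$region == rg]))
  }
  const <- region_average(stats::setNames(rep(0.5, 8), m$labels), m)
  expect_true(all(const$mean_value == 0.5))
})
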