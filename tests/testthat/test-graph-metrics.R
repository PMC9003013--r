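g_from_W <- function(W)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)

test_that("vertex strength follows the handshake identity", {
  tri <- g_from_W(sym_from_edges(3, cbind(c(1, 1, 2), c(2, 3, 3), 0.5)))
  expect_equal(avg_vertex_strength(tri), 1)
  star <- g_from_W(sym_from_edges(5, cbind(1, 2:5, 1)))
  expect_equal(avg_vertex_strength(star), 1.6)   # (4 + 4*1)/5
  withr::local_seed(30)
  W <- random_connected_matrix(8)
  g <- g_from_W(W)
  expect_equal(avg_vertex_strength(g), 2 * sum(W[upper.tri(W)]) / 8,
               tolerance = 1e-12)
  expect_equal(avg_vertex_strength(igraph::make_empty_graph(3, directed = FALSE)), 0)
})

test_that("average path length counts unweighted hops", {
  K19 <- g_from_W((matrix(1, 19, 19) - diag(19)) * 0.3)
  expect_equal(avg_path_length(K19), 1)
  path3 <- g_from_W(sym_from_edges(3, cbind(c(1, 2), c(2, 3), c(0.9, 0.1))))
  expect_equal(avg_path_length(path3), 4 / 3)
})

test_that("APL equals 2 - density on hop-diameter-2 graphs", {
  withr::local_seed(31)
  for (i in 1:10) {
    n <- 12
    W <- matrix(0, n, n)
    W[1, 2:n] <- W[2:n, 1] <- runif(n - 1)      # universal node => diameter 2
    extra <- which(upper.tri(W) & W == 0)
    pick <- sample(extra, 20)
    W[pick] <- runif(20)
    W <- pmax(W, t(W))
    g <- g_from_W(W)
    density <- sum(W[upper.tri(W)] > 0) / choose(n, 2)
    expect_equal(avg_path_length(g), 2 - density, tolerance = 1e-12)
  }
})

test_that("weighted diameter uses weight as length", {
  e1 <- g_from_W(sym_from_edges(2, cbind(1, 2, 0.22)))
  expect_equal(weighted_diameter(e1), 0.22)
  tri <- g_from_W(sym_from_edges(3, cbind(c(1, 1, 2), c(2, 3, 3), c(0.1, 0.1, 0.5))))
  expect_equal(weighted_diameter(tri), 0.2)     # 0.5 edge bypassed via 0.1+0.1
})

test_that("path metrics match the Floyd-Warshall oracle on random graphs", {
  withr::local_seed(32)
  for (i in 1:10) {
    W <- random_connected_matrix(9)
    g <- g_from_W(W)
    o <- oracle_path_metrics(W)
    expect_equal(avg_path_length(g), o$apl, tolerance = 1e-12)
    expect_equal(weighted_diameter(g), o$diam, tolerance = 1e-12)
  }
})

test_that("transitivity is the binary triangle density", {
  tri <- g_from_W(sym_from_edges(3, cbind(c(1, 1, 2), c(2, 3, 3), 0.7)))
  expect_equal(transitivity_coef(tri), 1)
  star <- g_from_W(sym_from_edges(5, cbind(1, 2:5, 1)))
  expect_equal(transitivity_coef(star), 0)      # triples but no triangles
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_equal(transitivity_coef(empty), 0)
})

test_that("mean transitivity of G(n, p) is close to p", {
  withr::local_seed(33)
  vals <- replicate(100, transitivity_coef(igraph::sample_gnp(19, 0.36)))
  expect_lt(abs(mean(vals) - 0.36), 0.03)
})

test_that("metrics are scale-covariant in the documented pattern", {
  withr::local_seed(34)
  W <- random_connected_matrix(10)
  g1 <- g_from_W(W)
  g2 <- g_from_W(3 * W)
  expect_equal(avg_vertex_strength(g2), 3 * avg_vertex_strength(g1))
  expect_equal(weighted_diameter(g2), 3 * weighted_diameter(g1))
  expect_equal(avg_path_length(g2), avg_path_length(g1))
  expect_equal(transitivity_coef(g2), transitivity_coef(g1))
  expect_equal(small_world_index(g2, n_random = 5, seed = 3),
               small_world_index(g1, n_random = 5, seed = 3))
})

test_that("small-world index is 1 on complete graphs and reproducible", {
  K7 <- g_from_W(matrix(1, 7, 7) - diag(7))
  expect_equal(small_world_index(K7, n_random = 3, seed = 1), 1)
  withr::local_seed(35)
  W <- random_connected_matrix(12)
  g <- g_from_W(W)
  expect_identical(small_world_index(g, n_random = 10, seed = 4),
                   small_world_index(g, n_random = 10, seed = 4))
})

test_that("static_features bundles the five metrics in fixed order", {
  tri <- g_from_W(sym_from_edges(3, cbind(c(1, 1, 2), c(2, 3, 3), 1)))
  f <- static_features(tri, n_random = 3, seed = 1)
  expect_named(f, c("small_world", "strength", "path_length",
                    "transitivity", "diameter"))
  expect_equal(as.vector(f), c(1, 2, 1, 1, 1))
  expect_equal(as.numeric(attr(f, "n_components")), 1)
})

test_that("disconnected graphs fall back to the largest component", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 0.5   # triangle
  W[5, 6] <- 0.2                          # separate dyad; node 4 isolated
  W <- pmax(W, t(W))
  g <- g_from_W(W)
  expect_warning(f <- static_features(g, n_random = 3, seed = 1), "components")
  expect_equal(attr(f, "n_components"), 3)
  expect_equal(unname(f["path_length"]), 1)  # largest component is the triangle
  expect_true(all(is.finite(f)))
})
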