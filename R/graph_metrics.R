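# The five topological features.
#
# Deliberately mixed conventions (the historical defaults of igraph, which
# the source analyses also used): average path length counts unweighted hops,
# the diameter treats edge weight as length, transitivity is computed on the
# binary skeleton, and vertex strength sums weights. Under one uniform
# convention a diameter smaller than the average path length would be
# impossible; under these it is typical of thresholded coupling networks.

#' Average vertex strength
#'
#' Mean over nodes of the summed weights of incident edges.
#'
#' @param g A weighted undirected igraph graph.
#' @return Mean strength; 0 for an empty graph.
#' @export
avg_vertex_strength <- function(g) {
  if (igraph::vcount(g) == 0) return(0)
  if (igraph::ecount(g) == 0) return(0)
  mean(igraph::strength(g, weights = igraph::E(g)$weight))
}

#' Average path length (unweighted hops)
#'
#' Mean shortest-path hop count over all connected node pairs; disconnected
#' pairs are excluded from the average.
#'
#' @param g An igraph graph.
#' @return Mean hop distance.
#' @export
avg_path_length <- function(g) {
  if (igraph::vcount(g) < 2 || igraph::ecount(g) == 0) return(NaN)
  igraph::mean_distance(g, weights = NA, unconnected = TRUE)
}

#' Weighted diameter
#'
#' Maximum over connected node pairs of the weighted shortest-path length
#' with edge weight used as edge length.
#'
#' @param g A weighted igraph graph.
#' @return The weighted diameter; 0 if no pair is connected.
#' @export
weighted_diameter <- function(g) {
  if (igraph::vcount(g) < 2 || igraph::ecount(g) == 0) return(0)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (!length(d)) return(0)
  max(d)
}

#' Transitivity (global clustering coefficient)
#'
#' `3 * triangles / connected triples` on the binary skeleton of the graph;
#' 0 when the graph has no connected triples.
#'
#' @param g An igraph graph.
#' @return A fraction in \[0, 1\].
#' @export
transitivity_coef <- function(g) {
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t)) 0 else t
}

#' Small-world index
#'
#' `S = (C / C_rand) / (L / L_rand)` where `C` is the transitivity and `L`
#' the average (hop) path length of the graph, and `C_rand`, `L_rand` are
#' the means over `n_random` uniform random graphs with the same node and
#' edge counts (Erdos-Renyi G(n, m)). `S > 1` indicates small-world
#' organization: more clustered than a size-matched random graph at
#' comparable path length. A disconnected input is reduced to its largest
#' connected component (with a warning unless `quiet = TRUE`).
#'
#' @param g An igraph graph.
#' @param n_random Number of reference random graphs (default 20).
#' @param seed Integer seed for the random-graph draws.
#' @param quiet Suppress the disconnectedness warning.
#' @return The small-world index.
#' @export
small_world_index <- function(g, n_random = 20, seed = 1, quiet = FALSE) {
  if (n_random < 1) stop("n_random must be >= 1")
  if (!igraph::is_connected(g)) {
    if (!quiet)
      warning("graph is disconnected; small-world index computed on the largest component")
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  C <- transitivity_coef(g)
  L <- avg_path_length(g)
  refs <- withr::with_seed(as.integer(seed %% 2147483647), {
    replicate(n_random, {
      r <- igraph::sample_gnm(n, m)
      c(transitivity_coef(r), avg_path_length(r))
    })
  })
  C_rand <- mean(refs[1, ])
  L_rand <- mean(refs[2, ])
  (C / C_rand) / (L / L_rand)
}

static_feature_names <- c("small_world", "strength", "path_length",
                          "transitivity", "diameter")

#' The five static topological features
#'
#' Bundles [small_world_index()], [avg_vertex_strength()],
#' [avg_path_length()], [transitivity_coef()] and [weighted_diameter()] in
#' fixed order. A disconnected graph is reduced to its largest component for
#' the path-based metrics; the number of components is attached as the
#' `"n_components"` attribute.
#'
#' @inheritParams small_world_index
#' @return Named numeric vector of length 5.
#' @export
static_features <- function(g, n_random = 20, seed = 1, quiet = FALSE) {
  ncomp <- igraph::components(g)$no
  gc <- g
  if (ncomp > 1) {
    if (!quiet)
      warning("graph has ", ncomp, " components; path metrics use the largest")
    comp <- igraph::components(g)
    gc <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  out <- c(small_world = small_world_index(gc, n_random, seed, quiet = TRUE),
           strength = avg_vertex_strength(g),
           path_length = avg_path_length(gc),
           transitivity = transitivity_coef(g),
           diameter = weighted_diameter(gc))
  attr(out, "n_components") <- ncomp
  out
}
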