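#' Element-wise average of connectivity matrices
#'
#' Used to superimpose individual (or per-window) networks into a group
#' average before threshold selection: static networks average over
#' participants, dynamic ones over participants and window snapshots.
#'
#' @param mats List of `connectivity_matrix` objects sharing labels, method
#'   and band.
#' @return A `connectivity_matrix` of the element-wise means.
#' @export
average_network <- function(mats) {
  if (!length(mats)) stop("no matrices to average")
  ref <- mats[[1]]
  for (m in mats) {
    if (!identical(m$channel_labels, ref$channel_labels))
      stop("matrices have mismatched channel labels")
    if (!identical(m$method, ref$method))
      stop("matrices mix connectivity methods")
  }
  W <- Reduce(`+`, lapply(mats, `[[`, "weights")) / length(mats)
  structure(list(weights = W, method = ref$method, band = ref$band,
                 channel_labels = ref$channel_labels),
            class = "connectivity_matrix")
}

# Edges (strictly positive upper-triangle weights) sorted ascending by
# weight, ties broken by the lexicographic node-index pair so removal order
# is deterministic. Zero entries are non-edges, not zero-weight edges.
sorted_edges <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ord <- order(W[idx], idx[, 1], idx[, 2])
  cbind(idx[ord, , drop = FALSE], weight = W[idx][ord])
}

graph_after_removal <- function(W, edges, k) {
  keep <- edges[setdiff(seq_len(nrow(edges)), seq_len(k)), , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(W), directed = FALSE)
  if (nrow(keep))
    g <- igraph::add_edges(g, as.vector(t(keep[, 1:2])),
                           weight = keep[, "weight"])
  igraph::V(g)$name <- rownames(W) %||% as.character(seq_len(nrow(W)))
  g
}

#' Edge-removal proportion at which a network disconnects
#'
#' Edges are sorted ascending by weight; for each grid proportion `p` the
#' lowest-weight `floor(p * E)` edges are removed and connectivity of the
#' remaining graph (over all nodes) is tested. Returns the smallest `p` at
#' which the graph is disconnected, or 1 if it never disconnects.
#'
#' @param avg A `connectivity_matrix`, connected at 0% removal.
#' @param step Grid resolution (default 0.01, i.e. whole percentages).
#' @return The disconnection proportion.
#' @export
disconnect_point <- function(avg, step = 0.01) {
  W <- avg$weights
  edges <- sorted_edges(W)
  E <- nrow(edges)
  if (!igraph::is_connected(graph_after_removal(W, edges, 0)))
    stop("network is disconnected before any removal; no valid threshold exists")
  grid <- seq(0, 1, by = step)
  last_k <- -1
  for (p in grid) {
    k <- floor(p * E + 1e-9)
    if (k == last_k) next
    last_k <- k
    if (!igraph::is_connected(graph_after_removal(W, edges, k)))
      return(p)
  }
  1
}

#' Select the common edge-removal proportion for two groups
#'
#' The connectivity-preserving rule: find each group-average network's
#' disconnection point and step back one grid notch below the smaller of
#' them, so both group networks survive thresholding connected. The same
#' proportion is then applied to every individual network.
#'
#' @param avg_by_group Named list of group-average `connectivity_matrix`
#'   objects.
#' @param step Grid resolution.
#' @return A `threshold_result`: `proportion`, `disconnect_point_per_group`,
#'   `step`.
#' @examples
#' # with per-group disconnection points 0.65 and 0.82 and a 1% grid the
#' # selected proportion is 0.64
#' @export
select_threshold <- function(avg_by_group, step = 0.01) {
  dps <- vapply(avg_by_group, disconnect_point, numeric(1), step = step)
  prop <- max(0, (round(min(dps) / step) - 1)) * step
  structure(list(proportion = prop, disconnect_point_per_group = dps,
                 step = step), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> proportion =", x$proportion, "\n")
  for (g in names(x$disconnect_point_per_group))
    cat("  ", g, "disconnects at", x$disconnect_point_per_group[[g]], "\n")
  invisible(x)
}

#' Write a threshold report
#'
#' @param thr A `threshold_result`.
#' @param path Output path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(thr, path) {
  df <- data.frame(group = names(thr$disconnect_point_per_group),
                   disconnect_point = unname(thr$disconnect_point_per_group),
                   selected_proportion = thr$proportion)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Proportionally threshold a connectivity matrix into a brain graph
#'
#' Removes the `floor(proportion * E)` lowest-weight edges of this matrix
#' (proportional, per network); surviving edges keep their weights. No
#' connectivity guarantee is given for individual networks -- the
#' threshold-selection rule only protects the group averages.
#'
#' @param mat A `connectivity_matrix`.
#' @param proportion Fraction of edges to remove, in \[0, 1).
#' @return A weighted undirected [igraph][igraph::igraph-package] graph whose
#'   vertices are the channels.
#' @export
apply_threshold <- function(mat, proportion) {
  if (proportion < 0 || proportion >= 1) stop("proportion must lie in [0, 1)")
  W <- mat$weights
  edges <- sorted_edges(W)
  k <- floor(proportion * nrow(edges) + 1e-9)
  graph_after_removal(W, edges, k)
}
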