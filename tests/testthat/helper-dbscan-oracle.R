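# Brute-force O(n^2) reference DBSCAN, independent of the compiled
# implementation. Core points are connected components of the core-core
# eps-graph (components numbered by their first core point in input order);
# border points take the smallest label among their core neighbours, which is
# the same point the sequential cluster expansion reaches first.

oracle_dbscan <- function(pts, eps, minpts) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(pts))
  A <- D <= eps
  core <- rowSums(A) >= minpts  # self included (diagonal is TRUE)
  labels <- integer(n)
  if (any(core)) {
    g <- igraph::graph_from_adjacency_matrix(A & outer(core, core, "&"),
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    comp[!core] <- NA
    # renumber components by first core appearance in input order
    relab <- match(comp, unique(comp[core]))
    labels[core] <- relab[core]
    for (j in which(!core)) {
      nb <- which(A[j, ] & core)
      if (length(nb)) labels[j] <- min(labels[nb])
    }
  }
  labels
}
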