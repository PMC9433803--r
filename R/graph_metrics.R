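#' Undirected binarized adjacency of a graph-like object
#'
#' All graph measures below follow the unweighted connection-status
#' formulation: they operate on the binarized, symmetrized adjacency
#' (an undirected edge wherever at least one directed edge exists), with
#' self-loops removed.
#'
#' @param g A `functional_graph`, square adjacency matrix, or `igraph`.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
as_adjacency_undirected <- function(g) {
  a <- if (inherits(g, "functional_graph")) g$adjacency
       else if (inherits(g, "igraph"))
         as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
       else as.matrix(g)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  a <- (a != 0) * 1L
  a <- ((a + t(a)) > 0) * 1L
  diag(a) <- 0L
  a
}

as_igraph_undirected <- function(g) {
  igraph::graph_from_adjacency_matrix(as_adjacency_undirected(g),
                                      mode = "undirected")
}

#' Node degree
#'
#' `k_i = sum_j a_ij` on the undirected binarized graph.
#' @param g Graph-like object (see [as_adjacency_undirected()]).
#' @return Integer degree per node.
#' @export
node_degree <- function(g) {
  as.integer(rowSums(as_adjacency_undirected(g)))
}

#' Network density
#'
#' `d = 2 l / (n (n - 1))` with `l` undirected links and `n` nodes.
#' @inheritParams node_degree
#' @return Density in \[0, 1\]; `NA` for fewer than 2 nodes.
#' @export
graph_density <- function(g) {
  a <- as_adjacency_undirected(g)
  n <- nrow(a)
  if (n < 2) return(NA_real_)
  l <- sum(a) / 2
  2 * l / (n * (n - 1))
}

#' Global efficiency
#'
#' `E = (1/n) sum_i [ sum_{j != i} 1 / d_ij / (n - 1) ]`, with `d_ij`
#' the shortest-path hop count and `1/Inf := 0` for disconnected pairs.
#' @inheritParams node_degree
#' @return Efficiency in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  a <- as_adjacency_undirected(g)
  n <- nrow(a)
  if (n < 2) return(NA_real_)
  d <- igraph::distances(as_igraph_undirected(g))
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  mean(rowSums(inv) / (n - 1))
}

#' Modularity of a partition
#'
#' `Q = sum_u [ e_uu - (sum_v e_uv)^2 ]` over the modules `u` of a
#' non-overlapping partition, where `e_uu` is the fraction of links
#' inside module `u` and, for `u != v`, `e_uv` is half the fraction of
#' links between `u` and `v` (so that `sum_uv e_uv = 1` and
#' `sum_v e_uv` is the fraction of link endpoints in `u`).
#'
#' @inheritParams node_degree
#' @param membership Integer module label per node (a partition: every
#'   node in exactly one module).
#' @return Modularity Q in \[-1, 1\]; `NA` for an edgeless graph.
#' @export
graph_modularity <- function(g, membership) {
  a <- as_adjacency_undirected(g)
  n <- nrow(a)
  if (length(membership) != n)
    stop("membership must label every node exactly once", call. = FALSE)
  l <- sum(a) / 2
  if (l == 0) return(NA_real_)
  mods <- sort(unique(membership))
  e <- matrix(0, length(mods), length(mods))
  for (ui in seq_along(mods)) {
    for (vi in seq_along(mods)) {
      su <- membership == mods[ui]
      sv <- membership == mods[vi]
      between <- sum(a[su, sv, drop = FALSE])
      e[ui, vi] <- if (ui == vi) (between / 2) / l else between / (2 * l)
    }
  }
  sum(diag(e) - rowSums(e)^2)
}

#' Detect communities by greedy modularity maximization
#'
#' Seeded fast-greedy agglomeration on the undirected binarized graph;
#' module labels are renumbered by the lowest node index they contain,
#' making the output deterministic given the seed.
#'
#' @inheritParams node_degree
#' @param seed RNG seed (the greedy algorithm itself is deterministic;
#'   the seed pins any library-internal tie-breaking).
#' @return Integer membership vector.
#' @export
detect_communities <- function(g, seed = 1L) {
  ig <- as_igraph_undirected(g)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- igraph::membership(igraph::cluster_fast_greedy(ig))
  first <- tapply(seq_along(m), m, min)
  relabel <- rank(first, ties.method = "first")
  as.integer(relabel[as.character(m)])
}

#' Normalized betweenness centrality
#'
#' `b_i = (1 / ((n-1)(n-2))) * sum over unordered pairs {h, j} (h, j != i)`
#' of the fraction of shortest h-j paths passing through `i`.
#'
#' @inheritParams node_degree
#' @return Betweenness per node, in \[0, 1\]; all zero (with a warning)
#'   for fewer than 3 nodes.
#' @export
node_betweenness <- function(g) {
  a <- as_adjacency_undirected(g)
  n <- nrow(a)
  if (n < 3) {
    warning("betweenness undefined for n < 3; returning zeros",
            call. = FALSE)
    return(rep(0, n))
  }
  b <- igraph::betweenness(as_igraph_undirected(g), directed = FALSE)
  as.numeric(b) / ((n - 1) * (n - 2))
}

#' Small-worldness
#'
#' `S = (C / C_rand) / (L / L_rand)`, where `C` is the mean local
#' clustering coefficient (nodes of degree < 2 contribute 0) and `L` the
#' characteristic path length, both on the largest connected component;
#' `C_rand` and `L_rand` are means over `n_nulls` degree-preserving
#' rewired null graphs (10 x edge-count swap attempts each). `S > 1`
#' indicates small-world topology.
#'
#' @inheritParams node_degree
#' @param n_nulls Number of null graphs (default 20).
#' @param seed RNG seed for the rewiring.
#' @return List `S`, `C`, `L`, `C_rand`, `L_rand`, `n_nulls`.
#' @export
small_world <- function(g, n_nulls = 20L, seed = 1L) {
  ig <- as_igraph_undirected(g)
  if (igraph::ecount(ig) < 2)
    stop("graph too sparse for a rewired null model", call. = FALSE)
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  ig <- igraph::induced_subgraph(ig, keep)
  cl_mean <- function(h) {
    lc <- igraph::transitivity(h, type = "local", isolates = "zero")
    mean(lc)
  }
  path_len <- function(h) igraph::mean_distance(h, directed = FALSE)
  C <- cl_mean(ig)
  L <- path_len(ig)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Cr <- Lr <- numeric(n_nulls)
  for (k in seq_len(n_nulls)) {
    null <- igraph::rewire(
      ig, igraph::keeping_degseq(niter = 10 * igraph::ecount(ig)))
    ncomp <- igraph::components(null)
    nkeep <- which(ncomp$membership == which.max(ncomp$csize))
    nlc <- igraph::induced_subgraph(null, nkeep)
    Cr[k] <- cl_mean(null)
    Lr[k] <- path_len(nlc)
  }
  C_rand <- mean(Cr); L_rand <- mean(Lr)
  if (C_rand == 0 || L_rand == 0)
    stop("degenerate null model (zero clustering or path length)",
         call. = FALSE)
  list(S = (C / C_rand) / (L / L_rand), C = C, L = L,
       C_rand = C_rand, L_rand = L_rand, n_nulls = n_nulls)
}

#' Full graph-metric bundle
#'
#' Convenience wrapper computing all node and network measures of a
#' functional graph: degree, normalized betweenness, module membership
#' (greedy modularity maximization), density, global efficiency,
#' modularity Q, and (when the graph admits a null model)
#' small-worldness.
#'
#' @param g A `functional_graph` (or adjacency matrix; node ids default
#'   to 1..n).
#' @param seed RNG seed for community detection and null models.
#' @param n_nulls Null graphs for [small_world()].
#' @return Object of class `graph_metrics`: list with `nodes` (data
#'   frame `electrode,degree,betweenness,module`) and `network` (list
#'   `n_nodes,n_links,density,efficiency,modularity,small_world`).
#' @export
graph_metrics <- function(g, seed = 1L, n_nulls = 20L) {
  a <- as_adjacency_undirected(g)
  ids <- if (inherits(g, "functional_graph")) g$nodes else seq_len(nrow(a))
  deg <- node_degree(a)
  btw <- node_betweenness(a)
  memb <- if (sum(a) > 0) detect_communities(a, seed)
          else seq_len(nrow(a))
  sw <- tryCatch(small_world(a, n_nulls, seed),
                 error = function(e) list(S = NA_real_, note = conditionMessage(e)))
  structure(
    list(nodes = data.frame(electrode = ids, degree = deg,
                            betweenness = btw, module = memb),
         network = list(n_nodes = nrow(a), n_links = sum(a) / 2,
                        density = graph_density(a),
                        efficiency = global_efficiency(a),
                        modularity = if (sum(a) > 0)
                          graph_modularity(a, memb) else NA_real_,
                        small_world = sw)),
    class = "graph_metrics"
  )
}

#' @export
print.graph_metrics <- function(x, ...) {
  nw <- x$network
  cat(sprintf(
    "<graph_metrics> n=%d l=%g density=%.3f efficiency=%.3f Q=%.3f S=%s\n",
    nw$n_nodes, nw$n_links, nw$density, nw$efficiency,
    ifelse(is.na(nw$modularity), NA, nw$modularity),
    format(nw$small_world$S, digits = 3)))
  invisible(x)
}
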