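#' Directed connection density
#'
#' Number of edges as a fraction of all ordered node pairs,
#' `E / (N * (N - 1))` for a simple directed graph.
#'
#' @param net a `logic_network`.
#' @return fraction in `[0, 1]`.
#' @export
connection_density <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2L) stop("density needs at least 2 nodes")
  nrow(net$edges) / (n * (n - 1))
}

#' Average clustering coefficient
#'
#' By default the local clustering coefficient is computed on the undirected
#' projection of the graph (the convention of the common network-analysis
#' GUIs) and averaged over nodes, with nodes of degree < 2 contributing 0.
#' With `directed = TRUE` the local coefficient of a node is the fraction of
#' ordered pairs of its neighbours (union of in- and out-neighbours) that are
#' themselves connected by a directed edge.
#'
#' @param net a `logic_network`.
#' @param directed use the directed variant?
#' @return average coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, directed = FALSE) {
  if (nrow(net$nodes) < 3L) stop("clustering needs at least 3 nodes")
  if (!directed) {
    g <- igraph::as_undirected(.as_igraph(net), mode = "collapse")
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    return(mean(cc))
  }
  ids <- net$nodes$id
  has_edge <- paste(net$edges$source, net$edges$target, sep = "\r")
  local <- vapply(ids, function(v) {
    nb <- setdiff(unique(c(net$edges$target[net$edges$source == v],
                           net$edges$source[net$edges$target == v])), v)
    k <- length(nb)
    if (k < 2L) return(0)
    pairs <- expand.grid(a = nb, b = nb, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    sum(paste(pairs$a, pairs$b, sep = "\r") %in% has_edge) / (k * (k - 1))
  }, 0)
  mean(local)
}

#' Node centralities
#'
#' Per-node in/out degree, closeness, betweenness and mean outgoing
#' shortest-path length on the directed graph. Betweenness uses standard
#' shortest-path counting with endpoints excluded, normalized by
#' `(N-1)(N-2)`. Closeness uses the Wasserman-Faust reachability correction
#' for graphs that are not strongly connected:
#' `C(v) = (r / (N-1)) * (r / sum of distances to the r reachable nodes)`.
#'
#' @param net a `logic_network`.
#' @return data.frame with columns `id`, `indegree`, `outdegree`,
#'   `closeness`, `betweenness`, `avg_shortest_path_out`.
#' @export
node_centralities <- function(net) {
  g <- .as_igraph(net)
  n <- nrow(net$nodes)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  btw_norm <- if (n > 2) btw / ((n - 1) * (n - 2)) else rep(0, n)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  r <- rowSums(is.finite(d))
  sumd <- vapply(seq_len(n), function(i) {
    fi <- d[i, is.finite(d[i, ])]
    if (length(fi)) sum(fi) else 0
  }, 0)
  clo <- ifelse(r > 0, (r / (n - 1)) * (r / sumd), 0)
  aspo <- ifelse(r > 0, sumd / r, NA_real_)
  data.frame(id = net$nodes$id,
             indegree = as.integer(indeg),
             outdegree = as.integer(outdeg),
             closeness = as.numeric(clo),
             betweenness = as.numeric(btw_norm),
             avg_shortest_path_out = as.numeric(aspo),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global descriptive statistics
#'
#' @param net a `logic_network`.
#' @return list with `n_nodes`, `n_edges`, `density`, `clustering`,
#'   `mean_shortest_path` (over reachable ordered pairs).
#' @export
global_metrics <- function(net) {
  g <- .as_igraph(net)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  fin <- d[is.finite(d)]
  list(n_nodes = nrow(net$nodes),
       n_edges = nrow(net$edges),
       density = connection_density(net),
       clustering = clustering_coefficient(net),
       mean_shortest_path = if (length(fin)) mean(fin) else NA_real_)
}
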