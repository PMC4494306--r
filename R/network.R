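#' Build a signed sociogram from a signed association
#'
#' An undirected edge is drawn for every dyad with at least one significant
#' direction (focal -> neighbor or neighbor -> focal) in the chosen sign's
#' weight matrix; the edge weight is the larger of the two directed SR-based
#' weights, and the `direction` attribute records whether one or both
#' directions passed ("one-way" / "two-way"), mirroring single- and
#' double-arrow sociogram edges. Every individual is a node, including
#' isolates.
#'
#' @param assoc A [signed_association].
#' @param sign `"positive"` (attraction network) or `"negative"` (avoidance
#'   network).
#' @return An object of class `"social_graph"` wrapping an undirected igraph
#'   with edge attributes `weight` and `direction`.
#' @export
build_graph <- function(assoc, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (isTRUE(assoc$two_mode)) {
    abort("build_graph() is for 1-mode associations; 2-mode networks are bipartite",
          class = "proxnet_mode_error")
  }
  w <- assoc[[sign]]
  ids <- assoc$individuals
  edges <- which(upper.tri(w) & (w > 0 | t(w) > 0), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges) > 0) {
    i <- edges[, 1]; j <- edges[, 2]
    weight <- pmax(w[cbind(i, j)], w[cbind(j, i)])
    direction <- ifelse(w[cbind(i, j)] > 0 & w[cbind(j, i)] > 0,
                        "two-way", "one-way")
    g <- igraph::add_edges(g, rbind(ids[i], ids[j]))
    g <- igraph::set_edge_attr(g, "weight", value = weight)
    g <- igraph::set_edge_attr(g, "direction", value = direction)
  }
  new_social_graph(g, sign)
}

new_social_graph <- function(g, sign) {
  structure(list(graph = g, sign = sign), class = "social_graph")
}

#' Build a social graph directly from an edge list
#'
#' Convenience constructor for known network structures (e.g. reproducing a
#' published sociogram) without going through association matrices.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column matrix or data frame of node identifiers, one row
#'   per undirected edge; may be empty.
#' @param sign `"positive"` or `"negative"` (annotation only).
#' @param weights Optional edge weights (default 1).
#' @return A `"social_graph"`.
#' @export
social_graph <- function(nodes, edges = NULL,
                         sign = c("positive", "negative"), weights = NULL) {
  sign <- match.arg(sign)
  nodes <- as.character(nodes)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    g <- igraph::add_edges(g, as.vector(t(em)))
    g <- igraph::set_edge_attr(g, "weight",
                               value = weights %||% rep(1, nrow(em)))
    g <- igraph::set_edge_attr(g, "direction",
                               value = rep("two-way", nrow(em)))
  }
  new_social_graph(g, sign)
}

#' @export
print.social_graph <- function(x, ...) {
  cat(sprintf("<social_graph> %s network: %d nodes, %d edges, density %.3f\n",
              x$sign, igraph::vcount(x$graph), igraph::ecount(x$graph),
              net_density(x)))
  invisible(x)
}

graph_of <- function(g) {
  if (inherits(g, "social_graph")) g$graph else g
}

#' Network density
#'
#' The proportion of all possible dyads that carry a significant edge:
#' `edges / (n * (n - 1) / 2)` on the undirected graph.
#'
#' @param g A `"social_graph"`.
#' @return A number in [0, 1].
#' @export
net_density <- function(g) {
  gr <- graph_of(g)
  n <- igraph::vcount(gr)
  if (n < 2) {
    abort("density needs at least 2 nodes", class = "proxnet_empty_error")
  }
  igraph::ecount(gr) / (n * (n - 1) / 2)
}

#' Node-level centrality and subgroup metrics
#'
#' Metrics are computed on the unweighted undirected graph (SR weights are
#' carried for display and export only):
#' \describe{
#'   \item{degree}{number of significant connections.}
#'   \item{betweenness}{unnormalized Freeman betweenness over unordered node
#'     pairs, with fractional credit when several geodesics tie.}
#'   \item{farness}{sum of geodesic distances to all other nodes; each
#'     unreachable node contributes `unreachable` (by default the node count
#'     `n`, the convention under which an isolated node in a 15-node network
#'     scores 14 x 15 = 210). Closeness is its reciprocal.}
#'   \item{cutpoint}{1 if removing the node disconnects part of its
#'     component (articulation point), else 0.}
#' }
#'
#' @param g A `"social_graph"`.
#' @param unreachable Distance charged per unreachable pair: `"n"` (node
#'   count, default) or `"n-1"`.
#' @return A tibble with columns `id`, `degree`, `betweenness`, `farness`,
#'   `closeness`, `cutpoint`.
#' @export
node_metrics <- function(g, unreachable = c("n", "n-1")) {
  gr <- graph_of(g)
  far <- node_farness(g, unreachable = unreachable)
  tibble::tibble(
    id = igraph::V(gr)$name,
    degree = unname(node_degree(g)),
    betweenness = unname(node_betweenness(g)),
    farness = unname(far),
    closeness = unname(1 / far),
    cutpoint = unname(find_cutpoints(g))
  )
}

#' @rdname node_metrics
#' @export
node_degree <- function(g) {
  gr <- graph_of(g)
  setNames(as.integer(igraph::degree(gr)), igraph::V(gr)$name)
}

#' @rdname node_metrics
#' @export
node_betweenness <- function(g) {
  gr <- graph_of(g)
  setNames(igraph::betweenness(gr, directed = FALSE, weights = NA,
                               normalized = FALSE),
           igraph::V(gr)$name)
}

#' @rdname node_metrics
#' @export
node_farness <- function(g, unreachable = c("n", "n-1")) {
  unreachable <- match.arg(unreachable)
  gr <- graph_of(g)
  n <- igraph::vcount(gr)
  d <- igraph::distances(gr, weights = NA)
  d[is.infinite(d)] <- if (unreachable == "n") n else n - 1
  diag(d) <- 0
  setNames(rowSums(d), igraph::V(gr)$name)
}

#' @rdname node_metrics
#' @export
find_cutpoints <- function(g) {
  gr <- graph_of(g)
  ap <- igraph::articulation_points(gr)
  out <- setNames(integer(igraph::vcount(gr)), igraph::V(gr)$name)
  out[as.integer(ap)] <- 1L
  out
}

#' Blocks (biconnected components)
#'
#' The maximal subgraphs that cannot be disconnected by removing a single
#' node; adjacent blocks overlap exactly in cutpoints. Every edge belongs to
#' exactly one block; isolated nodes belong to none. Blocks are numbered
#' deterministically by their smallest member identifier.
#'
#' @param g A `"social_graph"`.
#' @return A list with `blocks` (list of character vectors of member ids) and
#'   `membership` (0/1 node x block matrix).
#' @export
find_blocks <- function(g) {
  gr <- graph_of(g)
  ids <- igraph::V(gr)$name
  bc <- igraph::biconnected_components(gr)
  blocks <- lapply(bc$components, function(vs) sort(ids[as.integer(vs)]))
  ord <- order(vapply(blocks, paste, character(1), collapse = "\r"))
  blocks <- blocks[ord]
  membership <- matrix(0L, nrow = length(ids), ncol = length(blocks),
                       dimnames = list(ids,
                                       if (length(blocks)) paste0("block", seq_along(blocks))))
  for (k in seq_along(blocks)) membership[blocks[[k]], k] <- 1L
  list(blocks = blocks, membership = membership)
}

#' Node metrics table with an averages row
#'
#' One row per node with degree, betweenness, farness, cutpoint flag and
#' block membership flags, plus a final `"Average"` row holding the
#' arithmetic column means (for cutpoint and blocks these are the proportion
#' of nodes flagged).
#'
#' @inheritParams node_metrics
#' @param averages Append the averages row? Default `TRUE`.
#' @return A tibble; `id` is `"Average"` on the summary row.
#' @export
node_table <- function(g, unreachable = c("n", "n-1"), averages = TRUE) {
  metrics <- node_metrics(g, unreachable = unreachable)
  blocks <- find_blocks(g)$membership
  out <- dplyr::bind_cols(metrics[c("id", "degree", "betweenness",
                                    "farness", "cutpoint")],
                          tibble::as_tibble(blocks))
  if (averages) {
    avg <- dplyr::summarise(out, dplyr::across(-"id", mean))
    out <- dplyr::bind_rows(out, dplyr::mutate(avg, id = "Average"))
  }
  out
}

#' Export a social graph to file
#'
#' @param g A `"social_graph"`.
#' @param path Output file path.
#' @param format `"graphml"`, `"edgelist"` (CSV with from, to, weight, sign,
#'   direction columns) or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "edgelist", "dot")) {
  format <- match.arg(format)
  gr <- graph_of(g)
  gr <- igraph::set_graph_attr(gr, "sign", g$sign)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(gr)
    edges <- tibble::tibble(
      from = if (nrow(el)) el[, 1] else character(),
      to = if (nrow(el)) el[, 2] else character(),
      weight = igraph::E(gr)$weight %||% rep(1, nrow(el)),
      sign = rep(g$sign, nrow(el)),
      direction = igraph::E(gr)$direction %||% rep(NA_character_, nrow(el)))
    readr::write_csv(edges, path, progress = FALSE)
  } else {
    igraph::write_graph(gr, path, format = format)
  }
  invisible(path)
}

#' Import a social graph written by [export_graph()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param nodes For `"edgelist"`, the full node list (isolates are not
#'   present in an edge list).
#' @return A `"social_graph"`.
#' @export
import_graph <- function(path, format = c("graphml", "edgelist"),
                         nodes = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    gr <- igraph::read_graph(path, format = "graphml")
    sign <- igraph::graph_attr(gr, "sign") %||% "positive"
    return(new_social_graph(igraph::delete_graph_attr(gr, "sign"), sign))
  }
  edges <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  sign <- if (nrow(edges) > 0) edges$sign[1] else "positive"
  g <- social_graph(nodes, edges[c("from", "to")], sign = sign,
                    weights = edges$weight)
  if (nrow(edges) > 0) {
    g$graph <- igraph::set_edge_attr(g$graph, "direction",
                                     value = edges$direction)
  }
  g
}
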