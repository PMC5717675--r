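#' Generate a Barabasi-Albert scale-free network
#'
#' Grows a simple connected undirected graph by preferential attachment. The
#' seed is a complete graph on `n_attach + 1` nodes; every subsequent node
#' attaches to `n_attach` distinct existing nodes, each chosen with probability
#' proportional to its current degree (sampling without replacement). For large
#' `n_nodes` the mean degree approaches `2 * n_attach`, so `n_attach = 3`
#' yields the mean degree 6 used throughout the shipped study scenarios.
#'
#' @param n_nodes Number of nodes, must exceed `n_attach`.
#' @param n_attach Edges added per new node (the classical BA `m`).
#' @param seed Integer seed; the construction is bit-for-bit reproducible.
#' @return An [igraph::graph] object, simple, undirected and connected.
#' @examples
#' g <- generate_ba_network(1000, 3, seed = 1)
#' mean(igraph::degree(g))
#' @export
generate_ba_network <- function(n_nodes, n_attach, seed = NULL) {
  n_nodes <- assert_scalar_int(n_nodes, "n_nodes", lower = 2)
  n_attach <- assert_scalar_int(n_attach, "n_attach", lower = 1)
  if (n_nodes <= n_attach) {
    stop("`n_nodes` must be greater than `n_attach`", call. = FALSE)
  }
  m <- n_attach
  n0 <- m + 1L
  seed_edges <- t(utils::combn(seq_len(n0), 2L))
  n_new <- n_nodes - n0
  edges <- matrix(0L, nrow = nrow(seed_edges) + n_new * m, ncol = 2L)
  edges[seq_len(nrow(seed_edges)), ] <- seed_edges

  # Endpoint list: each node appears once per incident edge, so uniform
  # sampling from it is degree-proportional attachment.
  ep_len <- 2L * nrow(edges)
  ep <- integer(ep_len)
  ep[seq_len(2L * nrow(seed_edges))] <- as.integer(t(seed_edges))
  ep_n <- 2L * nrow(seed_edges)
  e_n <- nrow(seed_edges)

  with_seed(seed, {
    if (n_new > 0L) {
      for (v in (n0 + 1L):n_nodes) {
        chosen <- integer(m)
        got <- 0L
        while (got < m) {
          cand <- ep[sample.int(ep_n, 1L)]
          if (!any(chosen[seq_len(got)] == cand)) {
            got <- got + 1L
            chosen[got] <- cand
          }
        }
        for (u in chosen) {
          e_n <- e_n + 1L
          edges[e_n, 1L] <- u
          edges[e_n, 2L] <- v
        }
        ep[(ep_n + 1L):(ep_n + 2L * m)] <- c(chosen, rep.int(v, m))
        ep_n <- ep_n + 2L * m
      }
    }
  })

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  validate_network(g)
  g
}

#' Validate the network substrate
#'
#' Checks that a graph is undirected, simple (no self-loops or multi-edges)
#' and connected, the standing assumptions of the diffusion model.
#'
#' @param graph An igraph object.
#' @return The graph, invisibly; errors otherwise.
#' @export
validate_network <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(graph)) stop("graph must be undirected", call. = FALSE)
  if (!igraph::is_simple(graph)) stop("graph must be simple (no loops or parallel edges)", call. = FALSE)
  if (!igraph::is_connected(graph)) stop("graph must be connected", call. = FALSE)
  invisible(graph)
}

#' Highest-degree nodes
#'
#' Nodes ranked by degree, descending, ties broken by ascending node id. Used
#' to place opinion overrides and committed agents on the hubs.
#'
#' @param graph An igraph object.
#' @param count How many nodes to return.
#' @return Integer vector of vertex ids, length `count`.
#' @export
top_degree_nodes <- function(graph, count) {
  n <- igraph::vcount(graph)
  count <- assert_scalar_int(count, "count", lower = 1)
  if (count > n) stop("`count` exceeds the number of nodes", call. = FALSE)
  deg <- igraph::degree(graph)
  order(-deg, seq_len(n))[seq_len(count)]
}

#' Attach degree-product edge weights
#'
#' Sets every edge weight to `(k_u * k_v)^theta`, the deterministic mean form
#' of empirically observed degree-correlated tie strengths (fluctuations are
#' neglected). With `theta = 0` all weights are 1. Weighted neighbour sampling
#' on such a graph is distributionally identical to unweighted sampling with
#' fitness proportional to `k^theta`.
#'
#' @param graph An igraph object.
#' @param theta Non-negative exponent.
#' @return The graph with an edge attribute `weight` and graph attribute `theta`.
#' @export
attach_edge_weights <- function(graph, theta) {
  validate_network(graph)
  if (length(theta) != 1L || !is.numeric(theta) || is.na(theta) || theta < 0) {
    stop("`theta` must be a single non-negative number", call. = FALSE)
  }
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  igraph::E(graph)$weight <- (deg[el[, 1L]] * deg[el[, 2L]])^theta
  graph$theta <- theta
  graph
}

#' Read and write plain-text edge lists
#'
#' The on-disk format is two whitespace-separated integer columns, one edge
#' per line, 0-based node ids, each undirected edge listed once. An optional
#' third real column carries edge weights. `read_edge_list()` rejects
#' self-loops and duplicate edges with the offending line number.
#'
#' @param path File path.
#' @param on_disconnected `"error"` (default) or `"warn"` when the graph is
#'   not connected.
#' @return `read_edge_list()` returns an igraph object; `write_edge_list()`
#'   returns `path` invisibly.
#' @export
read_edge_list <- function(path, on_disconnected = c("error", "warn")) {
  on_disconnected <- match.arg(on_disconnected)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L)) {
    bad <- lineno[which(nf < 2L | nf > 3L)[1L]]
    stop(sprintf("malformed line %d in %s: expected 2 or 3 columns", bad, path), call. = FALSE)
  }
  u <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(u) || anyNA(v)) {
    bad <- lineno[which(is.na(u) | is.na(v))[1L]]
    stop(sprintf("malformed line %d in %s: non-integer node id", bad, path), call. = FALSE)
  }
  w <- NULL
  if (any(nf == 3L)) {
    if (!all(nf == 3L)) stop("mixed weighted/unweighted lines in ", path, call. = FALSE)
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(w)) stop("malformed weight column in ", path, call. = FALSE)
  }
  loops <- u == v
  if (any(loops)) {
    stop(sprintf("self-loop at line %d in %s", lineno[which(loops)[1L]], path), call. = FALSE)
  }
  key <- paste(pmin(u, v), pmax(u, v))
  dups <- duplicated(key)
  if (any(dups)) {
    stop(sprintf("duplicate edge at line %d in %s", lineno[which(dups)[1L]], path), call. = FALSE)
  }
  n <- max(u, v) + 1L
  g <- igraph::graph_from_edgelist(cbind(u, v) + 1L, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (!is.null(w)) igraph::E(g)$weight <- w
  if (!igraph::is_connected(g)) {
    msg <- "edge list describes a disconnected graph"
    if (on_disconnected == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  g
}

#' @rdname read_edge_list
#' @param graph An igraph object to serialize.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  if ("weight" %in% igraph::edge_attr_names(graph)) {
    out <- sprintf("%d %d %.17g", el[, 1L], el[, 2L], igraph::E(graph)$weight)
  } else {
    out <- sprintf("%d %d", el[, 1L], el[, 2L])
  }
  writeLines(out, path)
  invisible(path)
}
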