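# Small graphs and an exact Markov-chain absorption oracle used across tests.

path4 <- function() igraph::make_ring(4, circular = FALSE)        # degrees 1,2,2,1
k3 <- function() igraph::make_full_graph(3)
star4 <- function() igraph::make_star(4, mode = "undirected")      # centre = node 1

# two stars joined by an edge: node 1 has degree 4, node 2 degree 9
two_hub_graph <- function() {
  el <- rbind(c(1, 2),
              cbind(1, 3:5),       # 3 extra leaves on node 1
              cbind(2, 6:13))      # 8 leaves on node 2
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Exact absorption probability of opinion 2 for the two-opinion update
# process on a small graph (state = bitmask of opinion-2 nodes; linear solve
# of the 2^n-state chain). `weights[[v]]` are the selection weights of v's
# neighbours `adj[[v]]`.
absorb_exact <- function(graph, fitness, opinions) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 12, all(opinions %in% 1:2))
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(graph, v)))
  S <- 2^n
  Tm <- matrix(0, S, S)
  for (st in 0:(S - 1)) {
    is2 <- bitwAnd(st, 2^(0:(n - 1))) > 0
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      ww <- fitness[nb] / sum(fitness[nb])
      for (j in seq_along(nb)) {
        new_st <- if (is2[nb[j]]) bitwOr(st, 2^(v - 1)) else bitwAnd(st, bitwNot(2^(v - 1)))
        Tm[st + 1, new_st + 1] <- Tm[st + 1, new_st + 1] + ww[j] / n
      }
    }
  }
  full <- S - 1
  trans <- setdiff(0:(S - 1), c(0, full))
  Q <- Tm[trans + 1, trans + 1, drop = FALSE]
  r <- Tm[trans + 1, full + 1, drop = FALSE]
  h <- solve(diag(length(trans)) - Q, r)
  init <- sum(2^(which(opinions == 2) - 1))
  if (init == 0) 0 else if (init == full) 1 else h[match(init, trans)]
}

# state helper: opinions vector (+ optional committed ids) on a graph
make_state <- function(opinions, committed_ids = integer(0), n_opinions = max(2, max(opinions))) {
  committed <- rep(FALSE, length(opinions))
  committed[committed_ids] <- TRUE
  opinion_state(opinions, committed, n_opinions)
}

# random class state for property checks
random_class_state <- function(I, K, seed, committed = FALSE) {
  withr::with_seed(seed, {
    degs <- sort(sample(1:30, K))
    p <- stats::runif(K); p <- p / sum(p)
    q <- matrix(stats::runif(I * K), I, K)
    q <- sweep(q, 2, colSums(q), "/")
    s <- if (committed) q * matrix(stats::runif(I * K, 0, 0.5), I, K) else NULL
    degree_class_state(degs, p, q, s, fitness = stats::runif(K, 0.2, 2))
  })
}
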