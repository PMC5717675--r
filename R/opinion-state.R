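#' Opinion state of a population
#'
#' Holds one opinion id in `1..n_opinions` per node plus a committed flag.
#' Committed (zealot) nodes never change opinion under the dynamics but keep
#' influencing their neighbours.
#'
#' @param opinions Integer vector of opinion ids, one per node.
#' @param committed Logical vector, same length (default: none committed).
#' @param n_opinions Total number of opinions `I >= 2`.
#' @return An object of class `opinion_state`.
#' @export
opinion_state <- function(opinions, committed = NULL, n_opinions = max(opinions)) {
  opinions <- as.integer(opinions)
  n_opinions <- assert_scalar_int(n_opinions, "n_opinions", lower = 2)
  if (anyNA(opinions) || any(opinions < 1L) || any(opinions > n_opinions)) {
    stop("opinions must be integers in 1..n_opinions", call. = FALSE)
  }
  if (is.null(committed)) committed <- rep(FALSE, length(opinions))
  if (length(committed) != length(opinions) || !is.logical(committed)) {
    stop("`committed` must be a logical vector aligned with `opinions`", call. = FALSE)
  }
  structure(list(opinions = opinions, committed = committed,
                 n_opinions = n_opinions),
            class = "opinion_state")
}

#' @export
print.opinion_state <- function(x, ...) {
  cat(sprintf("<opinion_state> %d nodes, %d opinions, %d committed\n",
              length(x$opinions), x$n_opinions, sum(x$committed)))
  invisible(x)
}

#' Mass-media field
#'
#' A global broadcast of opinion `opinion` that an updating regular node
#' adopts with probability `strength` instead of imitating a neighbour.
#' `strength = 0` (or a `NULL` opinion) means no media.
#'
#' @param opinion Media opinion id, or `NULL` for no media.
#' @param strength Media intensity `P` in `[0, 1]`.
#' @return An object of class `media_field`.
#' @export
media_field <- function(opinion = NULL, strength = 0) {
  strength <- assert_probability(strength, "strength")
  if (strength > 0 && is.null(opinion)) {
    stop("a media opinion is required when `strength` > 0", call. = FALSE)
  }
  if (!is.null(opinion)) opinion <- assert_scalar_int(opinion, "opinion", lower = 1)
  structure(list(opinion = opinion, strength = strength), class = "media_field")
}

media_is_active <- function(media) {
  !is.null(media) && inherits(media, "media_field") && media$strength > 0
}

#' Randomly initialize opinions
#'
#' Assigns each node an independent uniform draw over `1..n_opinions`, then
#' applies explicit overrides (e.g. forcing the hubs onto one opinion so that
#' the weighted fraction visibly differs from the plain fraction).
#'
#' @param graph An igraph object.
#' @param n_opinions Number of opinions `I >= 2`.
#' @param overrides Named integer vector: names are node ids, values opinions.
#' @param seed Integer seed for the random assignment.
#' @return An [opinion_state()] with no committed nodes.
#' @export
initialize_opinions <- function(graph, n_opinions, overrides = NULL, seed = NULL) {
  n <- igraph::vcount(graph)
  n_opinions <- assert_scalar_int(n_opinions, "n_opinions", lower = 2)
  ops <- with_seed(seed, sample.int(n_opinions, n, replace = TRUE))
  if (!is.null(overrides)) {
    ids <- as.integer(names(overrides))
    vals <- as.integer(overrides)
    if (anyNA(ids) || any(ids < 1L) || any(ids > n)) {
      stop("override node ids must be in 1..n_nodes", call. = FALSE)
    }
    if (any(vals < 1L) || any(vals > n_opinions)) {
      stop("override opinions must be in 1..n_opinions", call. = FALSE)
    }
    ops[ids] <- vals
  }
  opinion_state(ops, n_opinions = n_opinions)
}

#' Designate committed (zealot) agents
#'
#' For each requested opinion, commits the `hub_count` highest-degree
#' still-uncommitted nodes (degree descending, ties by ascending id) and then
#' uniformly random uncommitted nodes until `round(fraction * N)` nodes are
#' committed to that opinion. Committed nodes have their opinion set to the
#' committed opinion; the committed sets are disjoint.
#'
#' @param state An [opinion_state()].
#' @param graph The igraph the state lives on.
#' @param spec Data frame with columns `opinion`, `fraction` and optionally
#'   `hub_count` (default 0).
#' @param seed Integer seed for the random fill.
#' @return The updated [opinion_state()].
#' @export
designate_committed <- function(state, graph, spec, seed = NULL) {
  stopifnot(inherits(state, "opinion_state"))
  spec <- as.data.frame(spec)
  if (!all(c("opinion", "fraction") %in% names(spec))) {
    stop("`spec` needs columns `opinion` and `fraction`", call. = FALSE)
  }
  if (is.null(spec$hub_count)) spec$hub_count <- 0L
  if (any(spec$fraction < 0) || sum(spec$fraction) > 1 + 1e-12) {
    stop("committed fractions must be non-negative and sum to at most 1", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  if (length(state$opinions) != n) stop("state and graph sizes differ", call. = FALSE)
  deg <- igraph::degree(graph)
  rank_all <- order(-deg, seq_len(n))
  opinions <- state$opinions
  committed <- state$committed

  seeds <- derive_seeds(seed, nrow(spec))
  for (r in seq_len(nrow(spec))) {
    i <- as.integer(spec$opinion[r])
    target <- round(spec$fraction[r] * n)
    h <- as.integer(spec$hub_count[r])
    if (h > target) stop("hub_count exceeds the committed count for opinion ", i, call. = FALSE)
    if (target == 0L) next
    # hubs first, skipping nodes already committed to an earlier opinion
    hubs <- rank_all[!committed[rank_all]][seq_len(h)]
    free <- which(!committed)
    free <- setdiff(free, hubs)
    n_fill <- target - h
    if (n_fill > length(free)) {
      stop("not enough uncommitted nodes to commit ", target, " to opinion ", i,
           call. = FALSE)
    }
    fill <- if (n_fill > 0L) with_seed(seeds[r], free[sample.int(length(free), n_fill)]) else integer(0)
    sel <- c(hubs, fill)
    committed[sel] <- TRUE
    opinions[sel] <- i
  }
  opinion_state(opinions, committed, state$n_opinions)
}

#' Per-opinion population fractions
#'
#' `q_i`: the plain fraction of nodes holding each opinion. Sums to 1.
#'
#' @param state An [opinion_state()].
#' @return Numeric vector of length `n_opinions`, named by opinion id.
#' @export
opinion_fractions <- function(state) {
  stopifnot(inherits(state, "opinion_state"))
  q <- tabulate(state$opinions, nbins = state$n_opinions) / length(state$opinions)
  names(q) <- seq_len(state$n_opinions)
  q
}

#' Per-opinion committed fractions
#'
#' `s_i`: the fraction of all nodes committed to each opinion; their sum is
#' the overall committed fraction `s`.
#'
#' @param state An [opinion_state()].
#' @return Numeric vector of length `n_opinions`, named by opinion id.
#' @export
committed_fractions <- function(state) {
  stopifnot(inherits(state, "opinion_state"))
  s <- tabulate(state$opinions[state$committed], nbins = state$n_opinions) /
    length(state$opinions)
  names(s) <- seq_len(state$n_opinions)
  s
}
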