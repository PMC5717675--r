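#' @useDynLib opinionet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# CSR adjacency plus per-node cumulative neighbour-selection weights for the
# compiled kernel. `weighting` decides what a neighbour's selection weight is:
# its fitness (unweighted networks), the connecting edge's weight, or their
# product. qf_weight is k_v * f_v, the node weight entering q_i^f.
build_kernel_inputs <- function(graph, fitness_node,
                                weighting = c("fitness", "edge_weight",
                                              "edge_weight_fitness")) {
  weighting <- match.arg(weighting)
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  has_w <- "weight" %in% igraph::edge_attr_names(graph)
  if (weighting != "fitness" && !has_w) {
    stop("edge-weight sampling requested but the graph has no edge weights",
         call. = FALSE)
  }
  ew <- if (has_w) igraph::E(graph)$weight else rep(1, nrow(el))
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  eww <- c(ew, ew)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; eww <- eww[ord]
  deg <- tabulate(from, nbins = n)
  offsets <- c(0L, cumsum(deg))
  sw <- switch(weighting,
    fitness = fitness_node[to],
    edge_weight = eww,
    edge_weight_fitness = eww * fitness_node[to]
  )
  csg <- cumsum(sw)
  before <- c(0, csg)[offsets[seq_len(n)] + 1L]
  cumw <- csg - rep(before, deg)
  list(adj = as.integer(to - 1L), offsets = as.integer(offsets), cumw = cumw,
       qf_weight = igraph::degree(graph) * fitness_node)
}

#' Scenario specification
#'
#' Bundles everything needed to realize and run one experiment: the network
#' (a prebuilt igraph, or BA parameters), the opinion count, the fitness
#' model, initial-opinion overrides, the committed-agent allocation, the media
#' field, the horizon and recording cadence (both in time units), and a master
#' seed from which all randomness is derived. One time unit is `N` elementary
#' steps without committed agents and `N / (1 - s)` steps with committed
#' fraction `s`, so a unit always corresponds to about `N` regular-node
#' updates.
#'
#' @param network An igraph object, or `list(n_nodes =, n_attach =)` for a BA
#'   network generated at realization time.
#' @param n_opinions Number of opinions `I >= 2`.
#' @param fitness A [fitness_model()].
#' @param hub_override Optional `list(count =, opinion =)`: force the
#'   `count` highest-degree nodes onto `opinion` initially.
#' @param overrides Optional named integer vector of per-node initial opinions.
#' @param committed Optional data frame for [designate_committed()].
#' @param media Optional [media_field()].
#' @param horizon Run length in time units.
#' @param cadence Recording interval in time units.
#' @param seed Master integer seed.
#' @param theta Optional non-negative exponent: attach `(k_u k_v)^theta` edge
#'   weights at realization time.
#' @param weighting Neighbour-selection rule: `"fitness"` (default),
#'   `"edge_weight"`, or `"edge_weight_fitness"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(network, n_opinions = 2, fitness = fitness_model("constant"),
                          hub_override = NULL, overrides = NULL, committed = NULL,
                          media = NULL, horizon = 50, cadence = 1, seed = 1,
                          theta = NULL,
                          weighting = c("fitness", "edge_weight",
                                        "edge_weight_fitness")) {
  weighting <- match.arg(weighting)
  if (!igraph::is_igraph(network)) {
    ok <- is.list(network) &&
      (all(c("n_nodes", "n_attach") %in% names(network)) || !is.null(network$path))
    if (!ok) {
      stop("`network` must be an igraph, list(n_nodes =, n_attach =), or list(path =)",
           call. = FALSE)
    }
    if (is.null(network$path)) {
      network <- list(n_nodes = as.integer(network$n_nodes),
                      n_attach = as.integer(network$n_attach))
    }
  }
  if (!is.null(media)) stopifnot(inherits(media, "media_field"))
  stopifnot(inherits(fitness, "fitness_model"))
  if (horizon < 0) stop("`horizon` must be non-negative", call. = FALSE)
  if (cadence <= 0) stop("`cadence` must be positive", call. = FALSE)
  # normalize storage types so that config round-trips are the identity
  if (!is.null(committed)) {
    committed <- data.frame(opinion = as.integer(committed$opinion),
                            fraction = as.numeric(committed$fraction),
                            hub_count = as.integer(committed$hub_count %||% 0L))
  }
  if (!is.null(hub_override)) {
    hub_override <- list(count = as.integer(hub_override$count),
                         opinion = as.integer(hub_override$opinion))
  }
  structure(list(network = network, n_opinions = as.integer(n_opinions),
                 fitness = fitness, hub_override = hub_override,
                 overrides = overrides, committed = committed, media = media,
                 horizon = as.numeric(horizon), cadence = as.numeric(cadence),
                 seed = as.integer(seed),
                 theta = if (!is.null(theta)) as.numeric(theta),
                 weighting = weighting),
            class = "scenario_spec")
}

#' Realize a scenario
#'
#' Materializes the network, per-node fitness, initial opinions and committed
#' flags from a [scenario_spec()], all deterministically from the spec's
#' master seed. Ensemble runs share one realization and differ only in the
#' dynamical random stream.
#'
#' @param spec A [scenario_spec()].
#' @return A list with `graph`, `state`, `fitness` (as from
#'   [resolve_fitness()]), `media`, `steps_per_unit` and `kernel` inputs.
#' @export
realize_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  seeds <- derive_seeds(spec$seed, 4L)  # network, fitness, init, committed
  graph <- if (igraph::is_igraph(spec$network)) {
    spec$network
  } else if (!is.null(spec$network$path)) {
    read_edge_list(spec$network$path)
  } else {
    generate_ba_network(spec$network$n_nodes, spec$network$n_attach, seed = seeds[1])
  }
  if (!is.null(spec$theta)) graph <- attach_edge_weights(graph, spec$theta)
  fmodel <- spec$fitness
  if (fmodel$kind == "uniform_random" && is.null(fmodel$seed)) fmodel$seed <- seeds[2]
  fitness <- resolve_fitness(fmodel, graph)

  overrides <- spec$overrides
  if (!is.null(spec$hub_override)) {
    hubs <- top_degree_nodes(graph, spec$hub_override$count)
    ho <- rep(as.integer(spec$hub_override$opinion), length(hubs))
    names(ho) <- hubs
    overrides <- c(overrides, ho)
  }
  state <- initialize_opinions(graph, spec$n_opinions, overrides = overrides,
                               seed = seeds[3])
  if (!is.null(spec$committed)) {
    state <- designate_committed(state, graph, spec$committed, seed = seeds[4])
  }
  s <- mean(state$committed)
  steps_per_unit <- if (s > 0) round(igraph::vcount(graph) / (1 - s)) else igraph::vcount(graph)
  kernel <- build_kernel_inputs(graph, fitness$node, spec$weighting)
  list(graph = graph, state = state, fitness = fitness, media = spec$media,
       steps_per_unit = steps_per_unit, kernel = kernel)
}

#' One elementary update step
#'
#' Reference R implementation of the update rule, mainly for inspection and
#' testing (the bulk loop runs in compiled code): pick a node uniformly at
#' random (or the given `node`); a committed node does nothing; otherwise with
#' probability `P` the node adopts the media opinion, and with probability
#' `1 - P` it imitates a neighbour chosen with probability proportional to
#' that neighbour's selection weight (fitness, edge weight, or both).
#'
#' @param state An [opinion_state()].
#' @param graph The igraph the state lives on.
#' @param fitness Numeric per-node fitness.
#' @param media Optional [media_field()].
#' @param node Optional node id to update (default: uniform random).
#' @param weighting Neighbour-selection rule, as in [scenario_spec()].
#' @return The updated [opinion_state()].
#' @export
update_step <- function(state, graph, fitness, media = NULL, node = NULL,
                        weighting = c("fitness", "edge_weight",
                                      "edge_weight_fitness")) {
  weighting <- match.arg(weighting)
  n <- length(state$opinions)
  v <- if (is.null(node)) sample.int(n, 1L) else as.integer(node)
  if (state$committed[v]) return(state)
  p <- if (media_is_active(media)) media$strength else 0
  if (p > 0 && stats::runif(1) < p) {
    state$opinions[v] <- media$opinion
    return(state)
  }
  nbr <- as.integer(igraph::neighbors(graph, v))
  if (weighting == "fitness") {
    w <- fitness[nbr]
  } else {
    eids <- igraph::incident(graph, v)
    ends <- igraph::ends(graph, eids, names = FALSE)
    other <- ifelse(ends[, 1L] == v, ends[, 2L], ends[, 1L])
    ew <- igraph::E(graph)$weight[as.integer(eids)][match(nbr, other)]
    w <- if (weighting == "edge_weight") ew else ew * fitness[nbr]
  }
  pick <- nbr[sample.int(length(nbr), 1L, prob = w)]
  state$opinions[v] <- state$opinions[pick]
  state
}

run_kernel <- function(real, horizon, cadence, dyn_seed) {
  media <- real$media
  m_op <- if (media_is_active(media)) media$opinion else 0L
  m_p <- if (media_is_active(media)) media$strength else 0
  spu <- real$steps_per_unit
  res <- with_seed(dyn_seed, run_dynamics_cpp(
    real$kernel$adj, real$kernel$offsets, real$kernel$cumw,
    real$state$opinions, real$state$committed, real$state$n_opinions,
    as.integer(m_op), m_p, real$kernel$qf_weight,
    round(horizon * spu), max(1, round(cadence * spu))
  ))
  res$times <- res$steps / spu
  res
}

#' Run a single stochastic trajectory
#'
#' Realizes the scenario and runs the update dynamics for `horizon` time
#' units, recording the per-opinion fraction `q_i` and weighted fraction
#' `q_i^f` every `cadence` units (including t = 0).
#'
#' @param spec A [scenario_spec()].
#' @param realization Optional pre-built [realize_scenario()] output to reuse.
#' @param dyn_seed Optional seed for the dynamical stream (defaults to one
#'   derived from the spec seed).
#' @return An `opinion_trajectory`: a tibble with columns `time`, `opinion`,
#'   `q`, `qf`, carrying the final [opinion_state()] as attribute
#'   `final_state`.
#' @export
run_trajectory <- function(spec, realization = NULL, dyn_seed = NULL) {
  real <- realization %||% realize_scenario(spec)
  if (is.null(dyn_seed)) dyn_seed <- derive_seeds(spec$seed + 1L, 1L)
  res <- run_kernel(real, spec$horizon, spec$cadence, dyn_seed)
  I <- real$state$n_opinions
  out <- tibble::tibble(
    time = rep(res$times, times = I),
    opinion = rep(seq_len(I), each = length(res$times)),
    q = as.vector(res$q),
    qf = as.vector(res$qf)
  )
  final <- opinion_state(res$opinions, real$state$committed, I)
  structure(out, class = c("opinion_trajectory", class(out)),
            final_state = final, spec = spec)
}

#' Run an ensemble of trajectories
#'
#' All realizations share the identical initial condition (network, fitness,
#' opinions, committed flags) and differ only in the dynamical random stream;
#' returns the pointwise ensemble mean and standard deviation of `q_i` and
#' `q_i^f`.
#'
#' @param spec A [scenario_spec()].
#' @param n_realizations Number of independent runs.
#' @return An `opinion_ensemble`: a tibble with columns `time`, `opinion`,
#'   `q_mean`, `q_sd`, `qf_mean`, `qf_sd`.
#' @export
run_ensemble <- function(spec, n_realizations = 100) {
  n_realizations <- assert_scalar_int(n_realizations, "n_realizations", lower = 1)
  real <- realize_scenario(spec)
  seeds <- derive_seeds(spec$seed + 1L, n_realizations)
  acc_q <- acc_q2 <- acc_f <- acc_f2 <- NULL
  times <- NULL
  for (r in seq_len(n_realizations)) {
    res <- run_kernel(real, spec$horizon, spec$cadence, seeds[r])
    if (is.null(acc_q)) {
      times <- res$times
      acc_q <- res$q; acc_q2 <- res$q^2
      acc_f <- res$qf; acc_f2 <- res$qf^2
    } else {
      acc_q <- acc_q + res$q; acc_q2 <- acc_q2 + res$q^2
      acc_f <- acc_f + res$qf; acc_f2 <- acc_f2 + res$qf^2
    }
  }
  n <- n_realizations
  mq <- acc_q / n
  mf <- acc_f / n
  vq <- pmax(acc_q2 / n - mq^2, 0) * n / max(n - 1, 1)
  vf <- pmax(acc_f2 / n - mf^2, 0) * n / max(n - 1, 1)
  I <- real$state$n_opinions
  out <- tibble::tibble(
    time = rep(times, times = I),
    opinion = rep(seq_len(I), each = length(times)),
    q_mean = as.vector(mq), q_sd = as.vector(sqrt(vq)),
    qf_mean = as.vector(mf), qf_sd = as.vector(sqrt(vf))
  )
  structure(out, class = c("opinion_ensemble", class(out)),
            spec = spec, n_realizations = n, realization = real)
}

#' Run to fixation
#'
#' Iterates the dynamics until consensus. Requires no committed nodes and no
#' media, otherwise fixation on non-media opinions is not guaranteed.
#'
#' @param spec A [scenario_spec()] without committed agents or media.
#' @param realization Optional pre-built realization to reuse.
#' @param dyn_seed Optional dynamical seed.
#' @param max_units Guard on the run length, in time units.
#' @return A list with `opinion` (the winner) and `time` (units to absorption).
#' @export
run_to_fixation <- function(spec, realization = NULL, dyn_seed = NULL,
                            max_units = 1e6) {
  real <- realization %||% realize_scenario(spec)
  if (any(real$state$committed)) {
    stop("fixation requires a scenario without committed nodes", call. = FALSE)
  }
  if (media_is_active(real$media)) {
    stop("fixation requires no active media field", call. = FALSE)
  }
  if (is.null(dyn_seed)) dyn_seed <- derive_seeds(spec$seed + 1L, 1L)
  spu <- real$steps_per_unit
  res <- with_seed(dyn_seed, run_fixation_cpp(
    real$kernel$adj, real$kernel$offsets, real$kernel$cumw,
    real$state$opinions, real$state$n_opinions, max_units * spu
  ))
  list(opinion = res$opinion, time = res$steps / spu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
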