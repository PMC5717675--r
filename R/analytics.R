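#' Degree-and-fitness-weighted opinion fractions
#'
#' The normalized weighted fraction of opinion `i`,
#' `q_i^f = sum_{v: opinion(v) = i} k_v f_v / sum_v k_v f_v`,
#' evaluated on the realized network by node sums. Without committed agents
#' or media this quantity is conserved (exactly in expectation for constant
#' fitness, in mean field otherwise) and equals opinion `i`'s fixation
#' probability. With fitness proportional to `1/k` it reduces to the plain
#' fraction `q_i`.
#'
#' @param state An [opinion_state()].
#' @param graph The igraph the state lives on.
#' @param fitness Numeric per-node fitness.
#' @return Numeric vector of length `n_opinions`, named by opinion id.
#' @export
weighted_fraction <- function(state, graph, fitness) {
  stopifnot(inherits(state, "opinion_state"))
  if (any(fitness <= 0)) stop("fitness must be positive", call. = FALSE)
  w <- igraph::degree(graph) * fitness
  qf <- vapply(seq_len(state$n_opinions),
               function(i) sum(w[state$opinions == i]), numeric(1)) / sum(w)
  names(qf) <- seq_len(state$n_opinions)
  qf
}

#' Committed weighted fractions
#'
#' `s_i^f`: the same degree-and-fitness weights restricted to nodes committed
#' to opinion `i`. These are the only quantities (with the plain committed
#' fractions `s_i`) that the steady-state shares depend on.
#'
#' @inheritParams weighted_fraction
#' @return Numeric vector of length `n_opinions`, named by opinion id.
#' @export
committed_weighted_fraction <- function(state, graph, fitness) {
  stopifnot(inherits(state, "opinion_state"))
  if (any(fitness <= 0)) stop("fitness must be positive", call. = FALSE)
  w <- igraph::degree(graph) * fitness
  sf <- vapply(seq_len(state$n_opinions),
               function(i) sum(w[state$committed & state$opinions == i]),
               numeric(1)) / sum(w)
  names(sf) <- seq_len(state$n_opinions)
  sf
}

#' Fixation (exit) probabilities
#'
#' Without committed agents or media the process is absorbed at consensus;
#' the probability that opinion `i` takes over the whole network equals its
#' initial weighted fraction `q_i^f(0)` (exact for constant fitness on any
#' graph, mean-field otherwise).
#'
#' @inheritParams weighted_fraction
#' @param media Optional [media_field()]; must be inactive.
#' @return Numeric vector of absorption probabilities, summing to 1.
#' @export
fixation_probabilities <- function(state, graph, fitness, media = NULL) {
  if (any(state$committed)) {
    stop("fixation probabilities require no committed nodes; use steady_state_committed()",
         call. = FALSE)
  }
  if (media_is_active(media)) {
    stop("fixation probabilities require no active media field", call. = FALSE)
  }
  weighted_fraction(state, graph, fitness)
}

# Shared steady-state algebra on plain fraction vectors.
# i != m:  q_i(inf) = s_i + (1-s) (1-P) s_i^f / D
#          qf_i(inf) = s_i^f / D               with D = P + (1-P) sum_j s_j^f
# i == m:  q_m(inf) = s_m + (1-s)(1-P) s_m^f / D + (1-s)[P + (1-P) P (1-sum_j s_j^f)/D]
#          qf_m(inf) = (s_m^f + P (1-sum_j s_j^f)) / D
# P = 0 reduces to the committed-only forms q_i = s_i + (1-s) s_i^f / sum_j s_j^f.
steady_state_formula <- function(s, sf, P = 0, media_opinion = NULL) {
  ssum <- sum(s)
  sfsum <- sum(sf)
  if (P > 0 && is.null(media_opinion)) {
    stop("a media opinion is required when P > 0", call. = FALSE)
  }
  if (P + sfsum <= 0) {
    stop("no committed nodes and no media: the steady state is the consensus lottery; use fixation_probabilities()",
         call. = FALSE)
  }
  D <- P + (1 - P) * sfsum
  q <- s + (1 - ssum) * (1 - P) * sf / D
  qf <- sf / D
  if (!is.null(media_opinion) && P > 0) {
    m <- media_opinion
    q[m] <- q[m] + (1 - ssum) * (P + (1 - P) * P * (1 - sfsum) / D)
    qf[m] <- (sf[m] + P * (1 - sfsum)) / D
  }
  list(q = q, qf = qf)
}

#' Steady-state shares from committed fractions
#'
#' Direct evaluation of the closed forms on plain fraction vectors, without a
#' realized network: `q_i(inf) = s_i + (1-s)(1-P) s_i^f / D` for non-media
#' opinions and `q_m(inf) = s_m + (1-s)(1-P) s_m^f / D + (1-s)[P + (1-P) P
#' (1 - sum_j s_j^f)/D]` for the media opinion, with
#' `D = P + (1-P) sum_j s_j^f`. At `P = 0` these are the committed-only
#' limits `s_i + (1-s) s_i^f / sum_j s_j^f`.
#'
#' @param s Per-opinion committed fractions `s_i`.
#' @param sf Per-opinion committed weighted fractions `s_i^f`.
#' @param P Media strength in `[0, 1]`.
#' @param media_opinion Media opinion id (required when `P > 0`).
#' @return An `opinion_prediction` tibble with columns `opinion`, `q_inf`,
#'   `qf_inf`.
#' @export
predict_steady_state <- function(s, sf, P = 0, media_opinion = NULL) {
  P <- assert_probability(P, "P")
  res <- steady_state_formula(s, sf, P = P, media_opinion = media_opinion)
  new_prediction(res$q, res$qf, if (P > 0) "media" else "committed")
}

new_prediction <- function(q, qf, regime) {
  out <- tibble::tibble(opinion = seq_along(q), q_inf = unname(q),
                        qf_inf = unname(qf))
  structure(out, class = c("opinion_prediction", class(out)), regime = regime)
}

#' Steady-state shares with committed agents
#'
#' With committed agents and no media, the weighted fraction converges to
#' `s_i^f / sum_j s_j^f` and the population fraction to
#' `s_i + (1 - s) s_i^f / sum_j s_j^f`: only opinions with committed holders
#' survive, each amplified by the network in proportion to its committed
#' weighted fraction.
#'
#' @inheritParams weighted_fraction
#' @return An `opinion_prediction` tibble with columns `opinion`, `q_inf`,
#'   `qf_inf`.
#' @export
steady_state_committed <- function(state, graph, fitness) {
  s <- committed_fractions(state)
  sf <- committed_weighted_fraction(state, graph, fitness)
  if (sum(sf) <= 0) {
    stop("no committed nodes: use fixation_probabilities()", call. = FALSE)
  }
  res <- steady_state_formula(s, sf, P = 0)
  new_prediction(res$q, res$qf, "committed")
}

#' Steady-state shares with committed agents and media
#'
#' Evaluates the media-regime closed forms for all opinions: non-media
#' opinions keep only their committed core plus a network-amplified share
#' damped by `(1 - P)`; the media opinion additionally gains the direct and
#' network-mediated media influence. At `P = 0` this coincides exactly with
#' [steady_state_committed()].
#'
#' @inheritParams weighted_fraction
#' @param media A [media_field()].
#' @return An `opinion_prediction` tibble with columns `opinion`, `q_inf`,
#'   `qf_inf`.
#' @export
steady_state_media <- function(state, graph, fitness, media) {
  stopifnot(inherits(media, "media_field"))
  s <- committed_fractions(state)
  sf <- committed_weighted_fraction(state, graph, fitness)
  res <- steady_state_formula(s, sf, P = media$strength, media_opinion = media$opinion)
  new_prediction(res$q, res$qf, if (media$strength > 0) "media" else "committed")
}

#' Decompose the media opinion's final share
#'
#' The media opinion's steady-state share splits into four non-negative
#' parts: its committed core `s_m`; the network amplification of that core,
#' `(1-s)(1-P) s_m^f / D`; the direct media influence `(1-s) P`; and the
#' media influence relayed through social ties,
#' `(1-s)(1-P) P (1 - sum_j s_j^f) / D`, with `D = P + (1-P) sum_j s_j^f`.
#'
#' @inheritParams steady_state_media
#' @return A `media_decomposition` tibble with columns `part`, `value`.
#' @export
media_decomposition <- function(state, graph, fitness, media) {
  stopifnot(inherits(media, "media_field"))
  if (!media_is_active(media)) {
    stop("media decomposition requires an active media field", call. = FALSE)
  }
  s <- committed_fractions(state)
  sf <- committed_weighted_fraction(state, graph, fitness)
  decompose_media_share(s, sf, media$strength, media$opinion)
}

#' @rdname media_decomposition
#' @param s,sf Per-opinion committed fractions and committed weighted
#'   fractions (plain numeric vectors), for direct evaluation of the formula
#'   without a realized network.
#' @param P Media strength in `[0, 1]`.
#' @param media_opinion Media opinion id.
#' @export
decompose_media_share <- function(s, sf, P, media_opinion) {
  m <- media_opinion
  ssum <- sum(s)
  sfsum <- sum(sf)
  D <- P + (1 - P) * sfsum
  parts <- c(
    committed = unname(s[m]),
    network_amplification = if (D > 0) unname((1 - ssum) * (1 - P) * sf[m] / D) else 0,
    media_direct = (1 - ssum) * P,
    media_via_network = if (D > 0) (1 - ssum) * (1 - P) * P * (1 - sfsum) / D else 0
  )
  out <- tibble::tibble(part = names(parts), value = unname(parts))
  structure(out, class = c("media_decomposition", class(out)),
            media_opinion = m, strength = P)
}

#' Network amplification factor
#'
#' The multiplier `s_i^f / sum_j s_j^f` by which social diffusion expands
#' each committed minority into the regular population:
#' `q_i(inf) - s_i = (1 - s) * factor_i`. Opinions without committed holders
#' get factor 0.
#'
#' @inheritParams weighted_fraction
#' @return Numeric vector of length `n_opinions`.
#' @export
amplification_factor <- function(state, graph, fitness) {
  sf <- committed_weighted_fraction(state, graph, fitness)
  if (sum(sf) <= 0) stop("no committed nodes", call. = FALSE)
  out <- ifelse(sf > 0, sf / sum(sf), 0)
  names(out) <- seq_along(sf)
  out
}

#' Weighted-network weighted fractions
#'
#' On a network with edge weights `(k_u k_v)^theta` the conserved weighted
#' fraction takes node weights `k^(theta+1)` (times fitness, if neighbour
#' selection also uses fitness): diffusion on such a weighted network is the
#' special case of unweighted diffusion with fitness `f_k` proportional to
#' `k^theta`.
#'
#' @inheritParams weighted_fraction
#' @param theta Non-negative weight exponent.
#' @param fitness Optional per-node fitness entering on top of the edge
#'   weights; default 1.
#' @return Numeric vector of length `n_opinions`.
#' @export
weighted_equivalence_qf <- function(state, graph, theta, fitness = NULL) {
  if (theta < 0) stop("`theta` must be non-negative", call. = FALSE)
  deg <- igraph::degree(graph)
  f <- if (is.null(fitness)) rep(1, length(deg)) else fitness
  weighted_fraction(state, graph, deg^theta * f)
}

#' Critical media strength
#'
#' The media intensity `P*` at which the media opinion's steady-state share
#' equals the rival's: below it the rival dominates, above it the media
#' opinion does. Found by bisection of
#' `g(P) = q_m(inf; P) - q_rival(inf; P)` to interval and residual 1e-9.
#'
#' @inheritParams weighted_fraction
#' @param media_opinion Media opinion id.
#' @param rival_opinion A different opinion id to compare against.
#' @return The crossing point `P*` in `[0, 1]`.
#' @export
critical_media_strength <- function(state, graph, fitness, media_opinion,
                                    rival_opinion) {
  s <- committed_fractions(state)
  sf <- committed_weighted_fraction(state, graph, fitness)
  critical_strength(s, sf, media_opinion, rival_opinion)
}

#' @rdname critical_media_strength
#' @param s,sf Per-opinion committed fractions and committed weighted
#'   fractions, for direct evaluation without a realized network.
#' @export
critical_strength <- function(s, sf, media_opinion, rival_opinion) {
  if (media_opinion == rival_opinion) {
    stop("`rival_opinion` must differ from `media_opinion`", call. = FALSE)
  }
  g <- function(P) {
    res <- steady_state_formula(s, sf, P = P, media_opinion = media_opinion)
    unname(res$q[media_opinion] - res$q[rival_opinion])
  }
  g0 <- g(1e-15)  # P = 0 with no committed support would be the conserved regime
  g1 <- g(1)
  if (abs(g0) < 1e-12) return(0)
  if (g0 > 0) {
    stop("no crossing in (0, 1): the media opinion dominates for every P > 0",
         call. = FALSE)
  }
  if (g1 < 0) {
    stop("no crossing in (0, 1): the rival opinion dominates for every P",
         call. = FALSE)
  }
  lo <- 0; hi <- 1
  repeat {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-9 && abs(gm) < 1e-9) return(mid)
    if (hi - lo < 1e-15) return((lo + hi) / 2)
  }
}
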