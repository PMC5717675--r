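#' Degree-class state for the heterogeneous mean field
#'
#' The mean-field mirror of a population state on a degree-uncorrelated
#' network: the degree distribution `p_k`, the per-class opinion fractions
#' `q_{i,k}`, the per-class committed fractions `s_{i,k}` and the per-class
#' fitness `f_k`.
#'
#' @param degrees Sorted distinct degrees present.
#' @param p Numeric vector `p_k`, summing to 1.
#' @param q Matrix `I x K` of `q_{i,k}`; each column sums to 1.
#' @param s Matrix `I x K` of committed fractions `s_{i,k}` (default 0).
#' @param fitness Numeric vector `f_k > 0`.
#' @return An object of class `degree_class_state`.
#' @export
degree_class_state <- function(degrees, p, q, s = NULL, fitness = rep(1, length(degrees))) {
  degrees <- as.integer(degrees)
  K <- length(degrees)
  q <- as.matrix(q)
  if (is.null(s)) s <- matrix(0, nrow(q), K)
  s <- as.matrix(s)
  stopifnot(length(p) == K, ncol(q) == K, all(dim(s) == dim(q)),
            length(fitness) == K)
  if (abs(sum(p) - 1) > 1e-8) stop("`p` must sum to 1", call. = FALSE)
  if (any(abs(colSums(q) - 1) > 1e-8)) stop("each column of `q` must sum to 1", call. = FALSE)
  if (any(s > q + 1e-12)) stop("s_{i,k} cannot exceed q_{i,k}", call. = FALSE)
  if (any(fitness <= 0)) stop("fitness must be positive", call. = FALSE)
  structure(list(degrees = degrees, p = as.numeric(p), q = q, s = s,
                 fitness = as.numeric(fitness)),
            class = "degree_class_state")
}

#' @export
print.degree_class_state <- function(x, ...) {
  cat(sprintf("<degree_class_state> %d opinions x %d degree classes\n",
              nrow(x$q), length(x$degrees)))
  invisible(x)
}

#' Degree-class tables of a realized population
#'
#' Groups a realized [opinion_state()] by node degree: `p_k = n_k / N`,
#' `q_{i,k} = m_{i,k} / n_k` and `s_{i,k}`, with the per-class fitness taken
#' from the resolved per-node fitness (constant within a class for all
#' degree-based fitness models).
#'
#' @param state An [opinion_state()].
#' @param graph The igraph the state lives on.
#' @param fitness Numeric per-node fitness.
#' @return A [degree_class_state()].
#' @export
degree_class_tables <- function(state, graph, fitness) {
  stopifnot(inherits(state, "opinion_state"))
  deg <- igraph::degree(graph)
  ks <- sort(unique(deg))
  K <- length(ks)
  I <- state$n_opinions
  cls <- match(deg, ks)
  nk <- tabulate(cls, nbins = K)
  q <- matrix(0, I, K)
  s <- matrix(0, I, K)
  for (k in seq_len(K)) {
    sel <- cls == k
    q[, k] <- tabulate(state$opinions[sel], nbins = I) / nk[k]
    s[, k] <- tabulate(state$opinions[sel & state$committed], nbins = I) / nk[k]
  }
  fk <- vapply(seq_len(K), function(k) mean(fitness[cls == k]), numeric(1))
  degree_class_state(ks, nk / length(deg), q, s, fk)
}

#' Weighted fractions from degree classes
#'
#' `q_i^f = sum_k k f_k p_k q_{i,k} / sum_k k f_k p_k`, the degree-class form
#' of the weighted fraction; identical to the node-sum form on the realized
#' network it was derived from.
#'
#' @param cls A [degree_class_state()].
#' @return Numeric vector of length `I`.
#' @export
qf_from_classes <- function(cls) {
  stopifnot(inherits(cls, "degree_class_state"))
  w <- cls$degrees * cls$fitness * cls$p
  as.numeric(cls$q %*% w) / sum(w)
}

#' Per-class transition probabilities
#'
#' The probability that a randomly selected node turns out to have degree `k`
#' and switches into (gain) or out of (loss) opinion `i` in one elementary
#' step, in the applicable regime: pure
#' (`gain = p_k (1 - q_{i,k}) q_i^f`), committed
#' (`gain = p_k (1 - q_{i,k} - sum_{j != i} s_{j,k}) q_i^f`,
#' `loss = p_k (q_{i,k} - s_{i,k})(1 - q_i^f)`), or media, where for a
#' non-media opinion the network pull is damped by `1 - P` and the loss gains
#' a direct-media term `P`, and for the media opinion the gain gains `+ P`.
#'
#' @param cls A [degree_class_state()].
#' @param k A degree present in `cls`.
#' @param opinion Opinion id.
#' @param media Optional [media_field()].
#' @return A list with elements `gain` and `loss`.
#' @export
transition_probabilities <- function(cls, k, opinion, media = NULL) {
  ki <- match(as.integer(k), cls$degrees)
  if (is.na(ki)) stop("degree ", k, " not present", call. = FALSE)
  i <- opinion
  qf <- qf_from_classes(cls)[i]
  pk <- cls$p[ki]
  qik <- cls$q[i, ki]
  sik <- cls$s[i, ki]
  s_other <- sum(cls$s[, ki]) - sik
  P <- if (media_is_active(media)) media$strength else 0
  m <- if (media_is_active(media)) media$opinion else 0L
  if (P == 0) {
    gain <- pk * (1 - qik - s_other) * qf
    loss <- pk * (qik - sik) * (1 - qf)
  } else if (i != m) {
    gain <- pk * (1 - qik - s_other) * (1 - P) * qf
    loss <- pk * (qik - sik) * ((1 - P) * (1 - qf) + P)
  } else {
    gain <- pk * (1 - qik - s_other) * ((1 - P) * qf + P)
    loss <- pk * (qik - sik) * (1 - P) * (1 - qf)
  }
  list(gain = gain, loss = loss)
}

# Vectorized RHS of the degree-class ODEs in units of ~N regular updates:
# dq_{i,k}/dt = (gain - loss) / p_k for the applicable regime. For P = 0 this
# is (1 - sum_j s_{j,k}) q_i^f - q_{i,k} + s_{i,k}.
meanfield_rhs_matrix <- function(cls, media = NULL) {
  qf <- qf_from_classes(cls)
  I <- nrow(cls$q); K <- ncol(cls$q)
  stot <- colSums(cls$s)                       # sum_j s_{j,k} per class
  P <- if (media_is_active(media)) media$strength else 0
  m <- if (media_is_active(media)) media$opinion else 0L
  free <- matrix(1 - stot, I, K, byrow = TRUE) - cls$q + cls$s  # 1 - q_{i,k} - sum_{j!=i} s_{j,k}
  mob <- cls$q - cls$s                                          # q_{i,k} - s_{i,k}
  if (P == 0) {
    gain <- free * qf
    loss <- mob * (1 - qf)
  } else {
    gain <- free * (1 - P) * qf
    loss <- mob * ((1 - P) * (1 - qf) + P)
    gain[m, ] <- free[m, ] * ((1 - P) * qf[m] + P)
    loss[m, ] <- mob[m, ] * (1 - P) * (1 - qf[m])
  }
  gain - loss
}

#' Right-hand side of the degree-class ODEs
#'
#' `dq_{i,k}/dt = (gain - loss) / p_k` in the applicable regime. Within every
#' degree class the derivatives sum to zero, so class-level normalization is
#' preserved by the flow.
#'
#' @param cls A [degree_class_state()].
#' @param media Optional [media_field()].
#' @return A matrix `I x K` of derivatives.
#' @export
meanfield_rhs <- function(cls, media = NULL) {
  stopifnot(inherits(cls, "degree_class_state"))
  meanfield_rhs_matrix(cls, media)
}

#' Integrate the degree-class mean field
#'
#' Numerically integrates the degree-class ODEs with `deSolve`, recording the
#' full class state and the aggregated `q_i(t)`, `q_i^f(t)` at each output
#' time. Time is measured in the simulator's units — one unit is about `N`
#' regular-node updates, i.e. `N / (1 - s)` elementary selections when a
#' fraction `s` is committed — so trajectories overlay directly on ensemble
#' output. (The printed per-selection rates of [meanfield_rhs()] are
#' accordingly multiplied by `1 / (1 - s)` during integration.)
#'
#' @param cls A [degree_class_state()] initial condition.
#' @param media Optional [media_field()].
#' @param t_end Integration horizon in time units.
#' @param step Output (and fixed-step) interval.
#' @param method A `deSolve` method; default `"rk4"`.
#' @return A `meanfield_trajectory`: a tibble with columns `time`, `opinion`,
#'   `q`, `qf`, carrying the full class trajectory as attribute `class_array`.
#' @export
integrate_meanfield <- function(cls, media = NULL, t_end = 50, step = 0.05,
                                method = "rk4") {
  stopifnot(inherits(cls, "degree_class_state"))
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (t_end < 0) stop("`t_end` must be non-negative", call. = FALSE)
  I <- nrow(cls$q); K <- ncol(cls$q)
  times <- unique(c(seq(0, t_end, by = step), t_end))
  s_total <- sum(colSums(cls$s) * cls$p)
  clock <- if (s_total < 1 - 1e-12) 1 / (1 - s_total) else 1
  rhs <- function(t, y, parms) {
    c2 <- cls
    c2$q <- matrix(y, I, K)
    list(as.vector(clock * meanfield_rhs_matrix(c2, media)))
  }
  y <- if (t_end == 0) {
    matrix(as.vector(cls$q), nrow = 1)
  } else {
    sol <- deSolve::ode(y = as.vector(cls$q), times = times, func = rhs,
                        parms = NULL, method = method)
    sol[, -1, drop = FALSE]
  }
  if (any(y < -1e-6) || any(y > 1 + 1e-6)) {
    stop("integration left [0, 1]; reduce `step`", call. = FALSE)
  }
  wk <- cls$degrees * cls$fitness * cls$p
  qmat <- matrix(0, length(times), I)
  qfmat <- matrix(0, length(times), I)
  for (r in seq_along(times)) {
    qk <- matrix(y[r, ], I, K)
    qmat[r, ] <- as.numeric(qk %*% cls$p)
    qfmat[r, ] <- as.numeric(qk %*% wk) / sum(wk)
  }
  out <- tibble::tibble(
    time = rep(times, times = I),
    opinion = rep(seq_len(I), each = length(times)),
    q = as.vector(qmat), qf = as.vector(qfmat)
  )
  arr <- array(t(y), dim = c(I, K, length(times)),
               dimnames = list(NULL, cls$degrees, NULL))
  structure(out, class = c("meanfield_trajectory", class(out)),
            class_array = arr, times = times, cls0 = cls)
}

#' Closed-form mean-field steady state
#'
#' Per-class fixed points of the degree-class ODEs and their aggregates. With
#' committed agents only, `q_{i,k}(inf) = (1 - sum_j s_{j,k}) q_i^f(inf) + s_{i,k}`
#' with `q_i^f(inf) = s_i^f / sum_j s_j^f`. With media, the network pull on
#' non-media opinions is damped by `1 - P` and the media opinion picks up the
#' direct term `P`; the aggregates reproduce the same closed forms as the
#' realized-network analytics exactly.
#'
#' @param cls A [degree_class_state()].
#' @param media Optional [media_field()].
#' @return A list with `q_class` (matrix `I x K` of per-class limits) and
#'   `prediction` (an `opinion_prediction` tibble).
#' @export
meanfield_steady_state <- function(cls, media = NULL) {
  stopifnot(inherits(cls, "degree_class_state"))
  P <- if (media_is_active(media)) media$strength else 0
  m <- if (media_is_active(media)) media$opinion else 0L
  wk <- cls$degrees * cls$fitness * cls$p
  sf <- as.numeric(cls$s %*% wk) / sum(wk)
  s_i <- as.numeric(cls$s %*% cls$p)
  if (P + sum(sf) <= 0) {
    stop("conserved regime (no committed agents, no media): use fixation_probabilities()",
         call. = FALSE)
  }
  ss <- steady_state_formula(s_i, sf, P = P,
                             media_opinion = if (P > 0) m else NULL)
  I <- nrow(cls$q); K <- ncol(cls$q)
  stot <- colSums(cls$s)
  pull <- (1 - P) * ss$qf            # per-opinion network pull at the fixed point
  if (P > 0) pull[m] <- (1 - P) * ss$qf[m] + P
  q_class <- matrix(1 - stot, I, K, byrow = TRUE) * pull + cls$s
  list(q_class = q_class, prediction = new_prediction(ss$q, ss$qf,
       if (P > 0) "media" else "committed"))
}
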