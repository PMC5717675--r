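#' Fitness (persuasiveness) models
#'
#' A fitness model maps node degree to a positive persuasiveness value
#' `f_k`: when a node updates, each neighbour is imitated with probability
#' proportional to its fitness. Available kinds:
#'
#' * `power`: `f_k = k^exponent` (degree-boosting for `exponent > 0`);
#' * `uniform_random`: one Uniform(0,1) draw per degree class, seeded,
#'   redrawn until positive;
#' * `inverse_degree`: `f_k = 1/k`, which exactly cancels the voter model's
#'   built-in advantage of high-degree nodes;
#' * `constant`: `f_k = 1` for all degrees (the classical voter model);
#' * `table`: an explicit degree -> fitness lookup.
#'
#' @param kind One of `"power"`, `"uniform_random"`, `"inverse_degree"`,
#'   `"constant"`, `"table"`.
#' @param exponent Exponent for `kind = "power"`.
#' @param table Named numeric vector (names = degrees) for `kind = "table"`.
#' @param seed Integer seed for `kind = "uniform_random"`.
#' @return An object of class `fitness_model`.
#' @examples
#' fitness_model("power", exponent = 0.5)
#' @export
fitness_model <- function(kind = c("constant", "power", "uniform_random",
                                   "inverse_degree", "table"),
                          exponent = NULL, table = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.null(exponent) || !is.numeric(exponent) || length(exponent) != 1L) {
      stop("`exponent` is required for kind = \"power\"", call. = FALSE)
    }
  }
  # uniform_random may leave `seed` NULL here; a seed must be supplied (or
  # derived from the scenario master seed) by resolution time.
  if (kind == "table") {
    if (is.null(table) || is.null(names(table)) || any(table <= 0)) {
      stop("`table` must be a named numeric vector with positive values", call. = FALSE)
    }
  }
  structure(list(kind = kind, exponent = exponent, table = table, seed = seed),
            class = "fitness_model")
}

#' Resolve a fitness model on a network
#'
#' Evaluates `f_k` for every degree class present in the graph and assigns
#' each node the fitness of its class. Uniform-random fitness is drawn once
#' per degree class (not per node), reproducibly under the model's seed, and
#' any zero draw is redrawn so that all fitnesses are strictly positive.
#'
#' @param model A [fitness_model()].
#' @param graph An igraph object.
#' @return A list with `node` (numeric fitness per node) and `table`
#'   (a tibble with columns `degree`, `fitness`).
#' @export
resolve_fitness <- function(model, graph) {
  stopifnot(inherits(model, "fitness_model"))
  if (model$kind == "uniform_random" && is.null(model$seed)) {
    stop("uniform_random fitness needs a seed to be resolved reproducibly",
         call. = FALSE)
  }
  deg <- igraph::degree(graph)
  ks <- sort(unique(deg))
  fk <- switch(model$kind,
    constant = rep(1, length(ks)),
    power = as.numeric(ks)^model$exponent,
    inverse_degree = 1 / as.numeric(ks),
    uniform_random = with_seed(model$seed, {
      x <- stats::runif(length(ks))
      while (any(x <= 0)) x[x <= 0] <- stats::runif(sum(x <= 0))
      x
    }),
    table = {
      idx <- match(as.character(ks), names(model$table))
      if (anyNA(idx)) {
        stop("fitness table is missing degrees: ",
             paste(ks[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      as.numeric(model$table[idx])
    }
  )
  if (any(!is.finite(fk)) || any(fk <= 0)) {
    stop("resolved fitness must be finite and positive for every degree class",
         call. = FALSE)
  }
  tbl <- tibble::tibble(degree = ks, fitness = fk)
  list(node = fk[match(deg, ks)], table = tbl)
}
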