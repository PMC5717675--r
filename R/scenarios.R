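#' Built-in study scenarios
#'
#' Returns a fully populated [scenario_spec()] for each of the twelve shipped
#' study setups. All live on a BA network with `N = 10^4` nodes and mean
#' degree 6, with `I = 5` opinions assigned uniformly at random:
#'
#' * `fig1a` / `fig1b`: no committed agents, no media; the 100 highest-degree
#'   nodes start with opinion 5; fitness `k^0.5` (a) or Uniform(0,1) per
#'   degree class (b). Shows conservation of `q_i^f`.
#' * `fig2a` / `fig2b`: committed agents, no media; the 100 top hubs plus
#'   random fill to fraction 0.3 committed to opinion 1, random fraction 0.2
#'   committed to opinion 2 (total `s = 0.5`); same two fitness models.
#' * `fig3a` / `fig3b`: the fig2 allocation plus media strength `P = 0.7`
#'   with media opinion 2 (a) or 3 (b); fitness `k^0.5`.
#' * `fig4a` / `fig4b`: as fig3 with Uniform(0,1) fitness.
#' * `fig5a` / `fig5b`: hubs committed to opinion 1, `s_1 = s_2 = 0.2`
#'   (total 0.4); media opinion 2 (a) or 3 (b); fitness `k^0.5`. Media
#'   strength is meant to be swept with [sweep_media_strength()] (the stored
#'   strength, 0.5, is a nominal placeholder).
#' * `fig6a` / `fig6b`: as fig5 with Uniform(0,1) fitness.
#'
#' @param name One of the names above.
#' @param scale Shrinks the setup for desk-scale work: `N` and the hub count
#'   scale proportionally (`round(1e4 * scale)` nodes, `round(100 * scale)`
#'   hubs) while all fractions, the mean degree and media parameters stay
#'   fixed — every closed form depends only on fractions and realized
#'   degree/fitness sums.
#' @param seed Master seed stored in the spec.
#' @return A [scenario_spec()].
#' @export
study_scenario <- function(name, scale = 1, seed = 1) {
  valid <- paste0("fig", rep(1:6, each = 2), c("a", "b"))
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown scenario; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  n <- round(1e4 * scale)
  hubs <- round(100 * scale)
  fig <- as.integer(substr(name, 4, 4))
  panel <- substr(name, 5, 5)

  power_fit <- fitness_model("power", exponent = 0.5)
  unif_fit <- fitness_model("uniform_random", seed = NULL)  # seeded at realization
  fitness <- switch(as.character(fig),
    "1" = if (panel == "a") power_fit else unif_fit,
    "2" = if (panel == "a") power_fit else unif_fit,
    "3" = power_fit, "4" = unif_fit,
    "5" = power_fit, "6" = unif_fit
  )
  hub_override <- if (fig == 1) list(count = hubs, opinion = 5L) else NULL
  committed <- if (fig == 2 || fig == 3 || fig == 4) {
    data.frame(opinion = c(1L, 2L), fraction = c(0.3, 0.2), hub_count = c(hubs, 0L))
  } else if (fig >= 5) {
    data.frame(opinion = c(1L, 2L), fraction = c(0.2, 0.2), hub_count = c(hubs, 0L))
  } else NULL
  media <- if (fig == 3 || fig == 4) {
    media_field(opinion = if (panel == "a") 2L else 3L, strength = 0.7)
  } else if (fig >= 5) {
    media_field(opinion = if (panel == "a") 2L else 3L, strength = 0.5)
  } else NULL

  scenario_spec(network = list(n_nodes = n, n_attach = 3L), n_opinions = 5L,
                fitness = fitness, hub_override = hub_override,
                committed = committed, media = media,
                horizon = if (fig == 1) 50 else 100, cadence = 1, seed = seed)
}

scenario_schema <- list(
  network = c("type", "n_nodes", "n_attach", "path"),
  opinions = c("count", "hub_override", "overrides"),
  fitness = c("kind", "exponent", "seed", "table"),
  committed = c("opinion", "fraction", "hub_count"),
  media = c("opinion", "strength"),
  run = c("horizon", "cadence", "seed", "theta", "weighting")
)

check_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key `%s` in config section `%s`", bad[1], section),
         call. = FALSE)
  }
}

#' Load and dump scenario configuration files
#'
#' Scenarios serialize to a YAML file with sections `network`, `opinions`,
#' `fitness`, `committed`, `media` and `run`; unknown keys are rejected with
#' the offending key named, and `load(dump(spec))` is the identity. A config
#' whose network is a prebuilt igraph object cannot be dumped — write it with
#' [write_edge_list()] and reference it as `network: {type: edge_list, path:}`.
#'
#' @param path File path.
#' @return `load_scenario()` returns a [scenario_spec()]; `dump_scenario()`
#'   returns `path` invisibly.
#' @export
load_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, names(scenario_schema), "<top level>")
  for (sec in intersect(names(cfg), c("network", "opinions", "fitness", "media", "run"))) {
    check_keys(cfg[[sec]], scenario_schema[[sec]], sec)
  }
  net <- cfg$network
  if (is.null(net)) stop("config must have a `network` section", call. = FALSE)
  network <- if (identical(net$type, "edge_list")) {
    list(path = net$path)
  } else {
    list(n_nodes = as.integer(net$n_nodes), n_attach = as.integer(net$n_attach %||% 3L))
  }
  fit_cfg <- cfg$fitness %||% list(kind = "constant")
  fitness <- fitness_model(fit_cfg$kind %||% "constant",
                           exponent = fit_cfg$exponent,
                           table = if (!is.null(fit_cfg$table)) unlist(fit_cfg$table),
                           seed = fit_cfg$seed)
  committed <- NULL
  if (!is.null(cfg$committed)) {
    rows <- lapply(cfg$committed, function(r) {
      check_keys(r, scenario_schema$committed, "committed")
      data.frame(opinion = as.integer(r$opinion), fraction = as.numeric(r$fraction),
                 hub_count = as.integer(r$hub_count %||% 0L))
    })
    committed <- do.call(rbind, rows)
  }
  media <- if (!is.null(cfg$media)) {
    media_field(opinion = cfg$media$opinion, strength = cfg$media$strength %||% 0)
  }
  ops <- cfg$opinions %||% list()
  overrides <- NULL
  if (!is.null(ops$overrides)) {
    overrides <- vapply(ops$overrides, as.integer, integer(1))
  }
  run <- cfg$run %||% list()
  scenario_spec(network = network,
                n_opinions = as.integer(ops$count %||% 2L),
                fitness = fitness,
                hub_override = ops$hub_override,
                overrides = overrides,
                committed = committed, media = media,
                horizon = run$horizon %||% 50, cadence = run$cadence %||% 1,
                seed = run$seed %||% 1L, theta = run$theta,
                weighting = run$weighting %||% "fitness")
}

#' @rdname load_scenario
#' @param spec A [scenario_spec()] to serialize.
#' @export
dump_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (igraph::is_igraph(spec$network)) {
    stop("cannot dump a prebuilt igraph network; write it with write_edge_list() first",
         call. = FALSE)
  }
  net <- if (!is.null(spec$network$path)) {
    list(type = "edge_list", path = spec$network$path)
  } else {
    list(type = "ba", n_nodes = spec$network$n_nodes, n_attach = spec$network$n_attach)
  }
  cfg <- list(
    network = net,
    opinions = Filter(Negate(is.null), list(
      count = spec$n_opinions,
      hub_override = spec$hub_override,
      overrides = if (!is.null(spec$overrides)) as.list(spec$overrides)
    )),
    fitness = Filter(Negate(is.null), list(
      kind = spec$fitness$kind, exponent = spec$fitness$exponent,
      seed = spec$fitness$seed,
      table = if (!is.null(spec$fitness$table)) as.list(spec$fitness$table)
    )),
    committed = if (!is.null(spec$committed)) {
      lapply(seq_len(nrow(spec$committed)), function(r) as.list(spec$committed[r, ]))
    },
    media = if (!is.null(spec$media)) {
      list(opinion = spec$media$opinion, strength = spec$media$strength)
    },
    run = Filter(Negate(is.null), list(
      horizon = spec$horizon, cadence = spec$cadence, seed = spec$seed,
      theta = spec$theta, weighting = spec$weighting
    ))
  )
  yaml::write_yaml(Filter(Negate(is.null), cfg), path)
  invisible(path)
}

#' Sweep the media strength
#'
#' Realizes the scenario once, then evaluates the closed-form steady-state
#' shares over a grid of media strengths `P`, locating the critical point
#' against each rival opinion with committed support by bisection.
#'
#' @param spec A [scenario_spec()] with a media opinion set.
#' @param P_grid Numeric vector of media strengths in `[0, 1]`.
#' @return A `media_sweep`: a tibble with columns `P`, `opinion`, `q_inf`,
#'   `qf_inf`; crossings are in attribute `crossings` (a tibble with columns
#'   `rival`, `P_star`).
#' @export
sweep_media_strength <- function(spec, P_grid = seq(0, 1, by = 0.02)) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$media) || is.null(spec$media$opinion)) {
    stop("the scenario must define a media opinion", call. = FALSE)
  }
  if (any(P_grid < 0 | P_grid > 1)) stop("P values must lie in [0, 1]", call. = FALSE)
  real <- realize_scenario(spec)
  s <- committed_fractions(real$state)
  sf <- committed_weighted_fraction(real$state, real$graph, real$fitness$node)
  m <- spec$media$opinion
  rows <- lapply(P_grid, function(P) {
    res <- steady_state_formula(s, sf, P = P, media_opinion = if (P > 0) m else NULL)
    tibble::tibble(P = P, opinion = seq_along(res$q),
                   q_inf = unname(res$q), qf_inf = unname(res$qf))
  })
  out <- dplyr::bind_rows(rows)
  rivals <- setdiff(which(sf > 0), m)
  crossings <- purrr::map_dfr(rivals, function(r) {
    ps <- tryCatch(critical_strength(s, sf, m, r), error = function(e) NA_real_)
    tibble::tibble(rival = r, P_star = ps)
  })
  structure(out, class = c("media_sweep", class(out)),
            crossings = crossings, media_opinion = m, spec = spec)
}

#' Export results to plain text
#'
#' Writes any of the package's tabular results (trajectories, ensembles,
#' predictions, sweeps, decompositions) as a tab-separated file with a
#' provenance header recording the scenario hash and master seed, so
#' identical (scenario, seed) pairs produce byte-identical files.
#'
#' @param x A result tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_results <- function(x, path) {
  spec <- attr(x, "spec")
  header <- c("# opinionet export",
              sprintf("# class: %s", class(x)[1]))
  if (!is.null(spec)) {
    header <- c(header,
                sprintf("# scenario_hash: %s", rlang::hash(unclass(spec))),
                sprintf("# seed: %d", spec$seed))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  df <- as.data.frame(x)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(names(df), collapse = "\t"), con)
  }
  invisible(path)
}

#' Re-read an exported results file
#'
#' @param path File written by [export_results()].
#' @return A tibble of the tabular content (header comments dropped).
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}
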