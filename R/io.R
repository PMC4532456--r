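#' Run configurations
#'
#' A run configuration is a YAML document describing one system and the
#' analyses to perform on it.  Top-level keys (unknown keys are
#' rejected):
#'
#' \describe{
#'   \item{\code{graph}}{either \code{template:} (a mapping of
#'     [make_template()] arguments, e.g. \code{\{name: circle, n: 4,
#'     self_loops: true\}}) or \code{edge_list:} (a path), with optional
#'     \code{directed:} (default true) and \code{default_weight:}.}
#'   \item{\code{r}}{state set size, default 2.}
#'   \item{\code{functions}}{\code{default:} one function spec
#'     (\code{family:} plus its parameters) applied to all vertices, and
#'     optional \code{overrides:}, a list of specs each carrying a
#'     \code{vertex:}.}
#'   \item{\code{scheme}}{\code{synchronous}, or one of
#'     \code{\{sequential: [1,2,3,4]\}}, \code{\{blocks: [[1,2],[3],[4]]\}},
#'     \code{\{word: [1,2,1,3]\}}.}
#'   \item{\code{analyses}}{subset of \code{phase_space},
#'     \code{attractors}, \code{basins}, \code{attractor_graph};
#'     default all but \code{attractor_graph}.}
#'   \item{\code{cap}, \code{seed}}{enumeration cap (default \code{2^24})
#'     and RNG seed recorded in the output.}
#' }
#'
#' @param path YAML file path.
#' @return a validated config object (class \code{gds_config}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file `%s` does not exist", path))
  }
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a raw config list (as parsed from YAML).
#' @export
validate_config <- function(config) {
  known <- c("graph", "r", "functions", "scheme", "analyses", "cap", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    rlang::abort(sprintf("unknown config key `%s`", extra[1]))
  }
  if (is.null(config$graph)) rlang::abort("config key `graph` is required")
  gkeys <- setdiff(names(config$graph),
                   c("template", "edge_list", "directed", "default_weight"))
  if (length(gkeys) > 0) {
    rlang::abort(sprintf("unknown config key `graph.%s`", gkeys[1]))
  }
  if (is.null(config$graph$template) && is.null(config$graph$edge_list)) {
    rlang::abort("`graph` needs either `template` or `edge_list`")
  }
  config$r <- if (is.null(config$r)) 2L else check_r(config$r)
  if (is.null(config$functions$default)) {
    rlang::abort("config key `functions.default` is required")
  }
  parse_function_spec(config$functions$default, config$r)  # validates family
  for (ov in config$functions$overrides) {
    if (is.null(ov$vertex)) rlang::abort("function override needs `vertex`")
    parse_function_spec(ov, config$r)
  }
  if (is.null(config$scheme)) rlang::abort("config key `scheme` is required")
  config$analyses <- config$analyses %||%
    c("phase_space", "attractors", "basins")
  bad <- setdiff(config$analyses,
                 c("phase_space", "attractors", "basins", "attractor_graph"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown analysis `%s`", bad[1]))
  }
  config$cap <- config$cap %||% 2^24
  structure(config, class = "gds_config")
}

#' @rdname load_config
#' @param config a validated config.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

parse_function_spec <- function(spec, r) {
  fam <- spec$family
  if (is.null(fam)) rlang::abort("function spec needs `family`")
  switch(fam,
    nor = vf_nor(),
    threshold = vf_threshold(spec$k),
    bithreshold = vf_bithreshold(spec$k01, spec$k10),
    multithreshold = vf_multithreshold(unlist(spec$k), r = r),
    linear_threshold = vf_linear_threshold(spec$k),
    truth_table = vf_truth_table(unlist(spec$outputs), r = r),
    rlang::abort(sprintf("unknown function family `%s` in config", fam)))
}

#' Build the system a config describes
#'
#' @param config a [load_config()] result (or a path to one).
#' @return a [gds].
#' @export
config_to_gds <- function(config) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "gds_config")) config <- validate_config(config)
  graph <- if (!is.null(config$graph$template)) {
    do.call(make_template, config$graph$template)
  } else {
    read_edge_list(config$graph$edge_list,
                   directed = config$graph$directed %||% TRUE,
                   default_weight = config$graph$default_weight %||% 1)
  }
  fns <- rep(list(parse_function_spec(config$functions$default, config$r)),
             graph$n)
  for (ov in config$functions$overrides) {
    fns[[ov$vertex]] <- parse_function_spec(ov, config$r)
  }
  sch <- config$scheme
  scheme <- if (identical(sch, "synchronous")) {
    scheme_synchronous(graph$n)
  } else if (!is.null(sch$sequential)) {
    scheme_sequential(unlist(sch$sequential))
  } else if (!is.null(sch$blocks)) {
    scheme_block(lapply(sch$blocks, unlist))
  } else if (!is.null(sch$word)) {
    scheme_word(unlist(sch$word))
  } else {
    rlang::abort("`scheme` must be synchronous / sequential / blocks / word")
  }
  gds(graph, fns, scheme, r = config$r)
}

#' Run the analyses a config requests
#'
#' @param config a config object or YAML path.
#' @return a \code{gds_results} list: \code{summary}, \code{transitions}
#'   (per-state tibble from [tidy()]), \code{attractors}, \code{basins},
#'   and when requested \code{attractor_graph} plus \code{ergodic_sets}.
#' @export
run_gds <- function(config) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "gds_config")) config <- validate_config(config)
  sys <- config_to_gds(config)
  ps <- enumerate_phase_space(sys, cap = config$cap)
  res <- list(n = sys$n, r = sys$r, seed = config$seed,
              summary = summarize_phase_space(ps),
              transitions = tidy(ps),
              attractors = find_attractors(ps),
              basins = basins(ps)$sizes)
  if ("attractor_graph" %in% config$analyses) {
    ag <- build_attractor_graph(ps)
    res$attractor_graph <- ag$edges
    res$ergodic_sets <- ergodic_sets(ag)
  }
  structure(res, class = "gds_results")
}

#' Serialize analysis results
#'
#' Writes the complete state-transition list, attractors, transients and
#' basins (and, when computed, the attractor graph and its ergodic sets)
#' as JSON (primary) or XML.  States appear both as integer codes and as
#' printed 1-based tuples \code{(x1,...,xn)}.
#'
#' @param results a [run_gds()] result.
#' @param path output file.
#' @param format \code{"json"} or \code{"xml"}.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("json", "xml")) {
  format <- match.arg(format)
  stopifnot(inherits(results, "gds_results"))
  payload <- results_payload(results)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    doc <- xml2::xml_new_root("gds_results")
    as_xml(doc, payload)
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

results_payload <- function(results) {
  atts <- results$attractors
  list(
    n = results$n, r = results$r, seed = results$seed,
    summary = list(
      n_states = results$summary$n_states,
      n_attractors = results$summary$n_attractors,
      fixed_points = results$summary$fixed_points,
      cycle_lengths = as.list(results$summary$cycle_lengths),
      max_cycle = results$summary$max_cycle,
      max_transient = results$summary$max_transient),
    transitions = lapply(seq_len(nrow(results$transitions)), function(i) {
      tr <- results$transitions[i, ]
      list(code = tr$code, state = tr$state, successor = tr$successor,
           attractor = tr$attractor, transient = tr$transient)
    }),
    attractors = lapply(seq_len(nrow(atts)), function(i) {
      list(id = atts$attractor[i], period = atts$period[i],
           basin_size = atts$basin_size[i],
           states = as.list(atts$states[[i]]),
           state_tuples = as.list(atts$state_tuples[[i]]))
    }),
    attractor_graph = if (!is.null(results$attractor_graph)) {
      lapply(seq_len(nrow(results$attractor_graph)), function(i) {
        e <- results$attractor_graph[i, ]
        list(from = e$from, to = e$to, witness_state = e$state,
             witness_vertex = e$vertex, witness_symbol = e$new_symbol)
      })
    },
    ergodic_sets = if (!is.null(results$ergodic_sets)) {
      lapply(seq_len(nrow(results$ergodic_sets)), function(i) {
        s <- results$ergodic_sets[i, ]
        list(set = s$set, size = s$size, closed = s$closed,
             attractors = as.list(s$attractors[[1]]))
      })
    })
}

# recursive list -> XML: scalars become text nodes, lists become children
as_xml <- function(node, x) {
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.null(val)) next
    child <- xml2::xml_add_child(node, nm)
    if (is.list(val)) {
      if (is.null(names(val))) {
        for (item in val) {
          sub <- xml2::xml_add_child(child, "item")
          if (is.list(item)) as_xml(sub, item) else xml2::xml_set_text(sub, format(item))
        }
      } else {
        as_xml(child, val)
      }
    } else {
      xml2::xml_set_text(child, format(val))
    }
  }
  node
}

#' Export phase spaces and attractor graphs as Graphviz DOT
#'
#' Phase spaces get one node per state (periodic states drawn as boxes)
#' and one edge per transition; attractor graphs get one node per
#' attractor with witness annotations on the perturbation edges.  Output
#' is deterministic: nodes in code order.
#'
#' @param x a phase space or attractor graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_dot <- function(x, path) UseMethod("export_dot")

#' @export
export_dot.gds_phase_space <- function(x, path) {
  M <- state_matrix(x$n, x$r)
  lab <- apply(M, 1, format_state)
  nodes <- sprintf("  s%d [label=\"%s\"%s];", seq_len(nrow(M)) - 1L, lab,
                   ifelse(x$transient == 0L, " shape=box", ""))
  edges <- sprintf("  s%d -> s%d;", seq_len(nrow(M)) - 1L, x$successor)
  writeLines(c("digraph phase_space {", nodes, edges, "}"), path)
  invisible(path)
}

#' @export
export_dot.attractor_graph <- function(x, path) {
  nodes <- sprintf("  A%d;", seq_len(x$n_attractors))
  e <- x$edges
  edges <- sprintf("  A%d -> A%d [label=\"state %d: x%d:=%d\"];",
                   e$from, e$to, e$state, e$vertex, e$new_symbol)
  writeLines(c("digraph attractor_graph {", nodes, edges, "}"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
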