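#' Assemble a graph dynamical system
#'
#' A graph dynamical system (GDS) couples a dependency graph \code{X}, a
#' vertex state set \code{K = \{0, ..., r-1\}}, one vertex function per
#' vertex, and an update scheme.  The resulting system map
#' \code{F : K^n -> K^n} advances the whole system by one time step.
#'
#' @param graph a [dependency_graph].
#' @param functions a single [vertex_function] applied to every vertex, or
#'   a list of length \code{n} with one function per vertex.
#' @param scheme an [update_scheme].
#' @param r vertex state set size (default 2, Boolean).
#' @return an object of class \code{gds}.
#' @examples
#' g <- make_template("circle", n = 4, self_loops = TRUE)
#' sys <- gds(g, vf_nor(), scheme_synchronous(4))
#' gds_map(sys, c(0, 0, 0, 0))  # (1,1,1,1)
#' @export
gds <- function(graph, functions, scheme, r = 2) {
  stopifnot(inherits(graph, "dependency_graph"),
            inherits(scheme, "update_scheme"))
  r <- check_r(r)
  n <- graph$n
  if (n < 1) rlang::abort("the dependency graph has no vertices")
  if (inherits(functions, "vertex_function")) {
    functions <- rep(list(functions), n)
  }
  if (!is.list(functions) || length(functions) != n ||
      !all(vapply(functions, inherits, logical(1), "vertex_function"))) {
    rlang::abort("`functions` must be a vertex_function or a list of n of them")
  }
  for (v in seq_len(n)) {
    fam <- functions[[v]]$family
    if (fam %in% c("nor", "threshold", "bithreshold", "linear_threshold") &&
        r != 2L) {
      rlang::abort(sprintf("family `%s` requires r = 2", fam))
    }
    if (fam == "multithreshold" && functions[[v]]$r != r) {
      rlang::abort("multithreshold function r does not match system r")
    }
  }
  validate_scheme(scheme, n)
  structure(list(graph = graph, functions = functions, scheme = scheme,
                 r = r, n = n),
            class = "gds")
}

#' @export
print.gds <- function(x, ...) {
  fams <- unique(vapply(x$functions, `[[`, character(1), "family"))
  cat(sprintf("<gds> n = %d, r = %d, functions: %s, scheme: %s (%g states)\n",
              x$n, x$r, paste(fams, collapse = "/"), x$scheme$kind,
              x$r^x$n))
  invisible(x)
}

# One block application over a batch of states (rows of M): block vertices
# are recomputed simultaneously from the incoming M, all others kept.
step_block <- function(sys, M, block) {
  new_cols <- lapply(block, function(v) {
    eval_vertex(sys$functions[[v]], v, M, sys$graph, sys$r)
  })
  for (i in seq_along(block)) M[, block[[i]]] <- new_cols[[i]]
  M
}

# Full system map over a batch of states: blocks left to right.
step_states <- function(sys, M) {
  for (b in sys$scheme$blocks) M <- step_block(sys, M, b)
  M
}

#' Apply a single update block
#'
#' Replaces the coordinates in \code{block} by their vertex-function
#' values, all computed simultaneously from the incoming state; the other
#' coordinates are untouched.  The composite of the scheme's blocks, left
#' to right, is one application of [gds_map()].
#'
#' @param sys a [gds].
#' @param state integer state tuple of length \code{n}.
#' @param block non-empty vector of vertex ids.
#' @return the updated state tuple.
#' @export
apply_block <- function(sys, state, block) {
  stopifnot(inherits(sys, "gds"))
  check_state(sys, state)
  block <- as.integer(block)
  if (length(block) == 0) rlang::abort("`block` must be non-empty")
  if (any(block < 1L) || any(block > sys$n)) {
    rlang::abort("`block` contains an unknown vertex")
  }
  as.integer(step_block(sys, matrix(as.integer(state), 1), block))
}

#' Advance a system state by one time step
#'
#' @param sys a [gds].
#' @param state integer state tuple of length \code{n}.
#' @return the image state tuple \code{F(state)}.
#' @export
gds_map <- function(sys, state) {
  stopifnot(inherits(sys, "gds"))
  check_state(sys, state)
  as.integer(step_states(sys, matrix(as.integer(state), 1)))
}

check_state <- function(sys, state) {
  if (length(state) != sys$n || any(state < 0) || any(state >= sys$r) ||
      any(state != round(state))) {
    rlang::abort(sprintf("`state` must be %d symbols in 0..%d",
                         sys$n, sys$r - 1L))
  }
  invisible(state)
}

#' Forward trajectory from a state
#'
#' Iterates the system map from \code{start} until a previously visited
#' state recurs, splitting the visit sequence into the transient prefix
#' and the limit cycle that follows it.
#'
#' @param sys a [gds].
#' @param start initial state tuple.
#' @param max_steps maximum number of map applications before giving up.
#' @return a list with \code{prefix} and \code{cycle}, matrices with one
#'   state per row (prefix may have zero rows), and \code{period}, the
#'   cycle length.
#' @examples
#' g <- make_template("circle", n = 4, self_loops = TRUE)
#' sys <- gds(g, vf_nor(), scheme_sequential(1:4))
#' forward_trajectory(sys, c(0, 0, 1, 1))$period  # 7
#' @export
forward_trajectory <- function(sys, start, max_steps = 10^6) {
  stopifnot(inherits(sys, "gds"))
  check_state(sys, start)
  if (max_steps < 1) rlang::abort("`max_steps` must be >= 1")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- list(as.integer(start))
  assign(format_state(start), 1L, envir = seen)
  x <- as.integer(start)
  for (step in seq_len(max_steps)) {
    x <- gds_map(sys, x)
    key <- format_state(x)
    if (exists(key, envir = seen, inherits = FALSE)) {
      at <- get(key, envir = seen)
      all_states <- do.call(rbind, path)
      return(list(
        prefix = all_states[seq_len(at - 1L), , drop = FALSE],
        cycle = all_states[seq(at, length(path)), , drop = FALSE],
        period = length(path) - at + 1L))
    }
    path[[length(path) + 1L]] <- x
    assign(key, length(path), envir = seen)
  }
  rlang::abort(sprintf("no recurrence within %d steps", max_steps))
}
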