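#' Functional and cycle equivalence of two systems
#'
#' Two GDS maps are functionally equivalent when they produce the same
#' image for every one of the \eqn{r^n} system states, i.e. they are the
#' same map.  They are cycle equivalent when their limit-cycle structures
#' are isomorphic; for functional digraphs this reduces to equality of
#' the multisets of cycle lengths.  Functional equivalence implies cycle
#' equivalence, never the converse.
#'
#' @param sys_a,sys_b two [gds] objects with the same \code{n} and
#'   \code{r}.
#' @param cap enumeration cap, as in [enumerate_phase_space()].
#' @return a logical verdict.
#' @examples
#' g <- make_template("circle", n = 4, self_loops = TRUE)
#' a <- gds(g, vf_nor(), scheme_synchronous(4))
#' b <- gds(g, vf_nor(), scheme_sequential(1:4))
#' functional_equivalence(a, b)  # FALSE
#' @export
functional_equivalence <- function(sys_a, sys_b, cap = 2^24) {
  stopifnot(inherits(sys_a, "gds"), inherits(sys_b, "gds"))
  if (sys_a$n != sys_b$n || sys_a$r != sys_b$r) {
    rlang::abort("systems must share n and r to be compared")
  }
  N <- sys_a$r^sys_a$n
  if (N > cap) rlang::abort("state space exceeds the enumeration cap")
  M <- state_matrix(sys_a$n, sys_a$r)
  identical(step_states(sys_a, M), step_states(sys_b, M))
}

#' @rdname functional_equivalence
#' @export
cycle_equivalence <- function(sys_a, sys_b, cap = 2^24) {
  stopifnot(inherits(sys_a, "gds"), inherits(sys_b, "gds"))
  if (sys_a$r != sys_b$r || sys_a$n != sys_b$n) {
    rlang::abort("systems must share n and r to be compared")
  }
  identical(cycle_length_multiset(sys_a, cap), cycle_length_multiset(sys_b, cap))
}

cycle_length_multiset <- function(sys, cap = 2^24) {
  ps <- enumerate_phase_space(sys, cap = cap)
  sort(vapply(ps$attractors, `[[`, integer(1), "period"))
}

#' Compare two systems
#'
#' Convenience wrapper reporting both equivalence verdicts and the two
#' cycle-length multisets.
#'
#' @inheritParams functional_equivalence
#' @return a one-row tibble: \code{functional}, \code{cycle},
#'   \code{cycles_a}, \code{cycles_b} (list columns).
#' @export
compare_gds <- function(sys_a, sys_b, cap = 2^24) {
  tibble::tibble(
    functional = functional_equivalence(sys_a, sys_b, cap),
    cycle = cycle_equivalence(sys_a, sys_b, cap),
    cycles_a = list(cycle_length_multiset(sys_a, cap)),
    cycles_b = list(cycle_length_multiset(sys_b, cap)))
}

#' Attractor graph under single-vertex perturbations
#'
#' Stability analysis for regulatory networks asks where the system ends
#' up when a single vertex state of a limit-cycle state is perturbed.
#' The attractor graph has one node per attractor; a directed edge
#' \eqn{(A_i, A_j)} records that changing one coordinate of some cycle
#' state of \eqn{A_i} (to any of the \eqn{r - 1} other symbols) produces
#' a state in the basin of \eqn{A_j}.  Each edge keeps one witness
#' perturbation.
#'
#' @param ps an enumerated phase space ([enumerate_phase_space()]).
#' @return an object of class \code{attractor_graph}: \code{n_attractors}
#'   and \code{edges}, a tibble with \code{from}, \code{to} and witness
#'   columns \code{state} (cycle state code), \code{vertex},
#'   \code{new_symbol}.
#' @examples
#' g <- make_template("circle", n = 4, self_loops = TRUE)
#' sys <- gds(g, vf_bithreshold(1, 3), scheme_sequential(c(1, 2, 4, 3)))
#' ag <- build_attractor_graph(enumerate_phase_space(sys))
#' ergodic_sets(ag)
#' @export
build_attractor_graph <- function(ps) {
  stopifnot(inherits(ps, "gds_phase_space"))
  n <- ps$n; r <- ps$r
  rows <- list()
  for (i in seq_along(ps$attractors)) {
    for (code in ps$attractors[[i]]$states) {
      x <- decode_state(code, n, r)
      for (v in seq_len(n)) {
        for (sym in setdiff(0:(r - 1L), x[v])) {
          pert <- x
          pert[v] <- sym
          j <- ps$attractor_id[encode_state(pert, r) + 1L]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            from = i, to = j, state = code, vertex = v, new_symbol = sym)
        }
      }
    }
  }
  edges <- dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE) |>
    dplyr::arrange(.data$from, .data$to)
  structure(list(n_attractors = length(ps$attractors), edges = edges, ps = ps),
            class = "attractor_graph")
}

#' @export
print.attractor_graph <- function(x, ...) {
  cat(sprintf("<attractor_graph> %d attractors, %d perturbation edges\n",
              x$n_attractors, nrow(x$edges)))
  invisible(x)
}

#' Ergodic sets of an attractor graph
#'
#' An ergodic set is a strongly connected component of the attractor
#' graph: a set of attractors that are mutually reachable through
#' single-vertex perturbations, a proxy for the diversity of states a
#' system can visit under mutation.  A component is \emph{closed} when no
#' perturbation leads out of it (a recurrent class); self-edges never
#' affect the decomposition.
#'
#' @param ag a [build_attractor_graph()] result.
#' @return a tibble with one row per strongly connected component:
#'   \code{set}, \code{size}, \code{closed}, \code{attractors} (list of
#'   member attractor ids).  Every attractor belongs to exactly one row.
#' @export
ergodic_sets <- function(ag) {
  stopifnot(inherits(ag, "attractor_graph"))
  g <- igraph::graph_from_data_frame(
    ag$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = seq_len(ag$n_attractors)))
  comp <- igraph::components(g, mode = "strong")$membership
  e <- ag$edges[ag$edges$from != ag$edges$to, ]
  leaving <- unique(comp[e$from][comp[e$from] != comp[e$to]])
  tibble::tibble(set = sort(unique(comp))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      attractors = list(as.integer(names(comp)[comp == .data$set])),
      size = length(.data$attractors),
      closed = !.data$set %in% leaving) |>
    dplyr::ungroup() |>
    dplyr::select("set", "size", "closed", "attractors")
}

#' Fixed-point conditions for three-state threshold systems
#'
#' For sequential multi-threshold systems with \code{r = 3}, four
#' inequalities on the six thresholds guarantee that every limit set is a
#' fixed point.  With \eqn{\Delta_{01} = k_{10} - k_{01}} and
#' \eqn{\Delta_{12} = k_{21} - k_{12}} and free constants \eqn{C_1, C_2}:
#' \enumerate{
#'   \item \eqn{\Delta_{01} \le \min(-C_1 - 1,\; C_1 + 3)}
#'   \item \eqn{\Delta_{12} \le \min(C_1 - C_2 - 3,\; -C_1 + C_2 + 5)}
#'   \item \eqn{(k_{21}+k_{12}) + (k_{10}+k_{01}) - 4 k_{02} \le -C_2 - 1}
#'   \item \eqn{-(k_{21}+k_{12}) - (k_{10}+k_{01}) + 4 k_{20} \le C_2 + 11}
#' }
#' The defaults \eqn{C_1 = -2}, \eqn{C_2 = -6} maximize the right-hand
#' sides of conditions 1 and 2 (both become \eqn{\Delta \le 1}).
#' Violating any single condition minimally is enough to let cycle
#' lengths grow without bound (a bifurcation).
#'
#' @param k thresholds \code{(k01, k10, k12, k21, k02, k20)} in this
#'   order, or named, or a 3 x 3 matrix.
#' @param C1,C2 the free constants.
#' @return a one-row tibble with \code{delta01}, \code{delta12},
#'   \code{cond1}..\code{cond4} and \code{all_hold}.
#' @examples
#' check_fixed_point_conditions(c(2, 3, 6, 6, 4, 5))$all_hold  # TRUE
#' check_fixed_point_conditions(c(1, 3, 6, 6, 4, 5))$cond1     # FALSE
#' @export
check_fixed_point_conditions <- function(k, C1 = -2, C2 = -6) {
  K <- multithreshold_matrix(k, 3L)
  k01 <- K[1, 2]; k10 <- K[2, 1]; k12 <- K[2, 3]
  k21 <- K[3, 2]; k02 <- K[1, 3]; k20 <- K[3, 1]
  d01 <- k10 - k01
  d12 <- k21 - k12
  c1 <- d01 <= min(-C1 - 1, C1 + 3)
  c2 <- d12 <= min(C1 - C2 - 3, -C1 + C2 + 5)
  c3 <- (k21 + k12) + (k10 + k01) - 4 * k02 <= -C2 - 1
  c4 <- -(k21 + k12) - (k10 + k01) + 4 * k20 <= C2 + 11
  tibble::tibble(delta01 = d01, delta12 = d12,
                 cond1 = c1, cond2 = c2, cond3 = c3, cond4 = c4,
                 all_hold = c1 && c2 && c3 && c4)
}

#' Count fixed points by factorization over components
#'
#' A state is fixed iff every vertex is locally fixed, so for a fair
#' update scheme the fixed-point count of a system whose influence graph
#' splits into independent (weakly disconnected) components is the
#' product of the per-component counts.  Each component is enumerated on
#' its own, which reaches systems far beyond the global enumeration cap.
#'
#' @param sys a [gds] with a fair update scheme.
#' @param cap per-component enumeration cap.
#' @return the fixed-point count (a double; counts can exceed integer
#'   range).
#' @examples
#' g <- make_template("disjoint_cliques", sizes = rep(6, 9), self_loops = TRUE)
#' sys <- gds(g, vf_bithreshold(5, 5), scheme_sequential(1:54))
#' count_fixed_points_factorized(sys)  # 512
#' @export
count_fixed_points_factorized <- function(sys, cap = 2^24) {
  stopifnot(inherits(sys, "gds"))
  if (!sys$scheme$fair) {
    rlang::abort("factorized counting requires a fair update scheme")
  }
  comp <- igraph::components(as_igraph_undirected(sys$graph))$membership
  counts <- vapply(sort(unique(comp)), function(ci) {
    verts <- which(comp == ci)
    sub <- subsystem(sys, verts)
    if (sub$r^sub$n > cap) {
      rlang::abort(sprintf("component of %d vertices exceeds the cap", sub$n))
    }
    ps <- enumerate_phase_space(sub, cap = cap)
    sum(vapply(ps$attractors, `[[`, integer(1), "period") == 1L)
  }, numeric(1))
  prod(counts)
}

# Induced subsystem on a vertex subset (used by factorized counting).
# Vertices are relabeled 1..length(verts) preserving order; the scheme is
# restricted to the subset in its original firing order.  Valid only when
# no edges cross the subset boundary.
subsystem <- function(sys, verts) {
  verts <- sort(as.integer(verts))
  relab <- integer(sys$n)
  relab[verts] <- seq_along(verts)
  e <- sys$graph$edges
  crossing <- xor(e$from %in% verts, e$to %in% verts)
  if (any(crossing)) rlang::abort("subset is not a union of components")
  keep <- e$from %in% verts & e$to %in% verts
  sub_edges <- tibble::tibble(from = relab[e$from[keep]],
                              to = relab[e$to[keep]],
                              weight = e$weight[keep])
  g <- dependency_graph(sub_edges, n_vertices = length(verts))
  blocks <- lapply(sys$scheme$blocks, function(b) relab[b[b %in% verts]])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0]
  gds(g, sys$functions[verts], new_scheme(sys$scheme$kind, blocks), r = sys$r)
}

#' Sweep maximum cycle length across system sizes
#'
#' Builds one system per size in \code{n_range} (a template graph, a
#' shared vertex-function spec and a scheme derived from \code{n}),
#' enumerates it, and records the maximum limit-cycle length.  Used to
#' expose bifurcations, e.g. three-state threshold circles switching from
#' all-fixed-point behavior to cycles of length \eqn{n - 1} when a single
#' fixed-point condition is minimally violated.
#'
#' @param template template name passed to [make_template()] (sized by
#'   \code{n}).
#' @param vf a [vertex_function] applied to every vertex.
#' @param n_range integer vector of sizes.
#' @param scheme_fn function \code{n -> update_scheme}; default sequential
#'   \code{(1, ..., n)}.
#' @param r state set size.
#' @param self_loops closed 1-neighborhoods (default TRUE, the threshold
#'   convention).
#' @param cap enumeration cap per size.
#' @return a tibble with columns \code{n}, \code{n_states},
#'   \code{max_cycle}.
#' @export
sweep_max_cycle <- function(template, vf, n_range,
                            scheme_fn = function(n) scheme_sequential(seq_len(n)),
                            r = 2, self_loops = TRUE, cap = 2^24) {
  purrr::map_dfr(n_range, function(n) {
    g <- make_template(template, n = n, self_loops = self_loops)
    sys <- gds(g, vf, scheme_fn(n), r = r)
    ps <- enumerate_phase_space(sys, cap = cap)
    tibble::tibble(n = n, n_states = r^n,
                   max_cycle = max(vapply(ps$attractors, `[[`,
                                          integer(1), "period")))
  })
}
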