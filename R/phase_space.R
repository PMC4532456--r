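#' Enumerate the phase space of a system
#'
#' The phase space \eqn{\Gamma(F)} is the functional digraph on all
#' \eqn{r^n} system states whose single out-edge from each state points to
#' its image under the system map.  Enumeration computes the successor of
#' every state in one vectorized pass, then derives the limit cycles
#' (attractors), per-state transient lengths (steps to the first periodic
#' state) and basins of attraction.
#'
#' @param sys a [gds].
#' @param cap refuse to enumerate more than this many states (default
#'   \code{2^24}); beyond the cap use [forward_trajectory()] instead.
#' @return an object of class \code{gds_phase_space} with elements
#'   \code{n}, \code{r}, \code{successor} (0-based image code per state
#'   code), \code{attractors} (list; each has \code{states} — cycle codes
#'   in transition order starting at the minimum code — and \code{period}),
#'   \code{attractor_id} (basin label per state), \code{transient}
#'   (integer per state) and \code{sys}.
#' @examples
#' g <- make_template("circle", n = 4, self_loops = TRUE)
#' ps <- enumerate_phase_space(gds(g, vf_nor(), scheme_sequential(1:4)))
#' glance(ps)
#' @export
enumerate_phase_space <- function(sys, cap = 2^24) {
  stopifnot(inherits(sys, "gds"))
  N <- sys$r^sys$n
  if (N > cap) {
    rlang::abort(sprintf(
      "phase space has %g states, above the cap of %g; use forward_trajectory()",
      N, cap))
  }
  M <- state_matrix(sys$n, sys$r)
  succ <- as.integer(encode_rows(step_states(sys, M), sys$r)) + 1L  # 1-based
  ps <- derive_structure(succ, N)
  structure(list(n = sys$n, r = sys$r, successor = succ - 1L,
                 attractors = ps$attractors, attractor_id = ps$attractor_id,
                 transient = ps$transient, sys = sys),
            class = "gds_phase_space")
}

# Cycle detection + reverse BFS on a functional digraph given the 1-based
# successor index vector.  O(N) total.
derive_structure <- function(succ, N) {
  # status: 0 = unseen, -t = on the current walk at position t, 1 = settled
  status <- integer(N)
  cyc_id <- integer(N)             # attractor id for periodic states
  cycles <- list()
  for (s in seq_len(N)) {
    if (status[s] != 0L) next
    walk <- integer(0)
    x <- s
    while (status[x] == 0L) {
      walk[length(walk) + 1L] <- x
      status[x] <- -length(walk)
      x <- succ[x]
    }
    if (status[x] < 0L) {          # closed a new cycle within this walk
      at <- -status[x]
      cyc <- walk[seq(at, length(walk))]
      cycles[[length(cycles) + 1L]] <- cyc
      cyc_id[cyc] <- length(cycles)
    }
    status[walk] <- 1L
  }
  # canonical order: rotate each cycle to start at its minimum code,
  # sort attractors by that code
  cycles <- lapply(cycles, function(cyc) {
    i <- which.min(cyc)
    if (i > 1L) cyc <- c(cyc[i:length(cyc)], cyc[seq_len(i - 1L)])
    cyc
  })
  ord <- order(vapply(cycles, `[[`, integer(1), 1L))
  cycles <- cycles[ord]
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  periodic <- unlist(cycles)
  cyc_id[periodic] <- remap[cyc_id[periodic]]

  # reverse BFS from the periodic states: transient length and basin label
  preds <- split(seq_len(N), factor(succ, levels = seq_len(N)))
  transient <- rep(NA_integer_, N)
  basin <- integer(N)
  transient[periodic] <- 0L
  basin[periodic] <- cyc_id[periodic]
  frontier <- periodic
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unlist(preds[frontier], use.names = FALSE)
    nxt <- nxt[is.na(transient[nxt])]
    if (length(nxt) == 0) break
    transient[nxt] <- d
    basin[nxt] <- basin[succ[nxt]]
    frontier <- nxt
  }
  attractors <- lapply(cycles, function(cyc) {
    list(states = cyc - 1L, period = length(cyc))   # 0-based codes
  })
  list(attractors = attractors, attractor_id = basin, transient = transient)
}

#' @export
print.gds_phase_space <- function(x, ...) {
  periods <- vapply(x$attractors, `[[`, integer(1), "period")
  cat(sprintf(
    "<gds_phase_space> %g states (n = %d, r = %d), %d attractor(s)\n",
    x$r^x$n, x$n, x$r, length(x$attractors)))
  cat(sprintf("  cycle lengths: {%s}; max transient: %d\n",
              paste(sort(periods), collapse = ","), max(x$transient)))
  invisible(x)
}

#' Attractors of an enumerated phase space
#'
#' One row per limit cycle, ordered by the minimum state code on the
#' cycle; \code{states} holds the cycle's codes in transition order
#' starting from that minimum.
#'
#' @param ps a [enumerate_phase_space()] result.
#' @return a tibble with columns \code{attractor}, \code{period},
#'   \code{basin_size}, \code{states} (list of 0-based code vectors) and
#'   \code{state_tuples} (list of character vectors, printed 1-based
#'   tuples).
#' @export
find_attractors <- function(ps) {
  stopifnot(inherits(ps, "gds_phase_space"))
  sizes <- tabulate(ps$attractor_id, nbins = length(ps$attractors))
  tibble::tibble(
    attractor = seq_along(ps$attractors),
    period = vapply(ps$attractors, `[[`, integer(1), "period"),
    basin_size = sizes,
    states = lapply(ps$attractors, `[[`, "states"),
    state_tuples = lapply(ps$attractors, function(a) {
      vapply(a$states, function(cd) format_state(decode_state(cd, ps$n, ps$r)),
             character(1))
    }))
}

#' Per-state transient lengths
#'
#' The transient length of a state is its distance in time steps to the
#' first periodic state on its trajectory; it is 0 exactly on limit
#' cycles.
#'
#' @param ps a [enumerate_phase_space()] result.
#' @return integer vector indexed by state code + 1.
#' @export
transient_lengths <- function(ps) {
  stopifnot(inherits(ps, "gds_phase_space"))
  ps$transient
}

#' @rdname transient_lengths
#' @export
max_transient <- function(ps) max(transient_lengths(ps))

#' Basins of attraction
#'
#' @param ps a [enumerate_phase_space()] result.
#' @return a list with \code{label} (attractor id per state code + 1) and
#'   \code{sizes} (tibble of basin sizes; they partition the \eqn{r^n}
#'   states).
#' @export
basins <- function(ps) {
  stopifnot(inherits(ps, "gds_phase_space"))
  list(label = ps$attractor_id,
       sizes = tibble::tibble(
         attractor = seq_along(ps$attractors),
         size = tabulate(ps$attractor_id, nbins = length(ps$attractors))))
}

#' Summary statistics of a phase space
#'
#' @param ps a [enumerate_phase_space()] result.
#' @return a list: \code{n_states}, \code{n_attractors},
#'   \code{fixed_points}, \code{cycle_lengths} (sorted multiset),
#'   \code{max_cycle}, \code{max_transient}, \code{basin_sizes}.
#' @export
summarize_phase_space <- function(ps) {
  stopifnot(inherits(ps, "gds_phase_space"))
  periods <- vapply(ps$attractors, `[[`, integer(1), "period")
  list(n_states = ps$r^ps$n,
       n_attractors = length(ps$attractors),
       fixed_points = sum(periods == 1L),
       cycle_lengths = sort(periods),
       max_cycle = max(periods),
       max_transient = max(ps$transient),
       basin_sizes = basins(ps)$sizes$size)
}

#' Tidy a phase space into a per-state table
#'
#' @param x a [enumerate_phase_space()] result.
#' @param ... unused.
#' @return a tibble with one row per system state: \code{code},
#'   \code{state} (printed tuple), \code{successor}, \code{attractor},
#'   \code{transient}, \code{periodic}.
#' @method tidy gds_phase_space
#' @export
tidy.gds_phase_space <- function(x, ...) {
  M <- state_matrix(x$n, x$r)
  tibble::tibble(
    code = seq_len(x$r^x$n) - 1,
    state = apply(M, 1, format_state),
    successor = x$successor,
    attractor = x$attractor_id,
    transient = x$transient,
    periodic = x$transient == 0L)
}

#' One-row summary of a phase space
#'
#' @param x a [enumerate_phase_space()] result.
#' @param ... unused.
#' @return a one-row tibble: state count, attractor count, fixed points,
#'   maximum cycle length and maximum transient length.
#' @method glance gds_phase_space
#' @export
glance.gds_phase_space <- function(x, ...) {
  s <- summarize_phase_space(x)
  tibble::tibble(n_states = s$n_states, n_attractors = s$n_attractors,
                 fixed_points = s$fixed_points, max_cycle = s$max_cycle,
                 max_transient = s$max_transient)
}
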