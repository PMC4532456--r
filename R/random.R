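#' Seeded random test systems
#'
#' Draws a small random GDS instance for property sweeps: an
#' Erdos–Renyi-style bidirected influence graph (edge probability
#' \code{p}, optionally with self-loops at every vertex), one random
#' function spec per vertex from the requested family with parameters in
#' their valid ranges, and a random fair scheme (synchronous, a random
#' sequential permutation, or a random block partition).  Identical seeds
#' give identical instances; the generator never touches the global RNG
#' stream outside the call.
#'
#' @param n vertex count; \code{r^n} must stay within \code{cap}.
#' @param r state set size.
#' @param family one of \code{"nor"}, \code{"threshold"},
#'   \code{"bithreshold"}, \code{"multithreshold"},
#'   \code{"linear_threshold"}.
#' @param seed integer seed.
#' @param p edge probability between distinct vertex pairs.
#' @param self_loops closed neighborhoods for every vertex (default TRUE,
#'   the threshold convention).
#' @param scheme_kind \code{"random"} (default: any fair kind) or one of
#'   \code{"synchronous"}, \code{"sequential"}, \code{"block_sequential"}.
#' @param delta_max for bithreshold, restrict \code{k10 - k01} to at most
#'   this value (\code{NULL}: unrestricted).
#' @param cap state-count cap.
#' @return a [gds].
#' @export
random_gds_instance <- function(n, r = 2, family = "bithreshold", seed,
                                p = 0.5, self_loops = TRUE,
                                scheme_kind = "random", delta_max = NULL,
                                cap = 2^24) {
  r <- check_r(r)
  if (r^n > cap) rlang::abort("r^n exceeds the enumeration cap")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  # keep the graph connected enough to be interesting: guarantee a spine
  spine <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  und <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  edges <- tibble::tibble(from = und[, 1], to = und[, 2], weight = 1)
  if (self_loops) {
    edges <- dplyr::bind_rows(edges,
      tibble::tibble(from = seq_len(n), to = seq_len(n), weight = 1))
  }
  if (family == "linear_threshold") {
    edges$weight <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  }
  g <- dependency_graph(edges, n_vertices = n, directed = FALSE)

  fns <- lapply(seq_len(n), function(v) {
    d <- length(g$nbr[[v]])
    switch(family,
      nor = vf_nor(),
      threshold = vf_threshold(sample(0:(d + 1L), 1)),
      bithreshold = {
        k01 <- sample(0:(d + 1L), 1)
        hi <- if (is.null(delta_max)) d + 2L else min(d + 2L, k01 + delta_max)
        vf_bithreshold(k01, sample(seq(1L, max(1L, hi)), 1))
      },
      multithreshold = {
        smax <- length(g$nbr[[v]]) * (r - 1L)
        K <- matrix(NA_real_, r, r)
        for (i in 0:(r - 1)) for (j in 0:(r - 1)) {
          if (i != j) K[i + 1, j + 1] <- sample(0:(smax + 1L), 1)
        }
        vf_multithreshold(K, r = r)
      },
      linear_threshold = vf_linear_threshold(sample(-1:2, 1)),
      rlang::abort(sprintf("unknown family `%s`", family)))
  })

  kind <- if (scheme_kind == "random") {
    sample(c("synchronous", "sequential", "block_sequential"), 1)
  } else scheme_kind
  scheme <- switch(kind,
    synchronous = scheme_synchronous(n),
    sequential = scheme_sequential(sample(n)),
    block_sequential = {
      perm <- sample(n)
      cuts <- sort(sample(seq_len(n - 1), sample(0:(n - 1L), 1)))
      scheme_block(unname(split(perm, cumsum(seq_len(n) %in% (cuts + 1L)))))
    })
  gds(g, fns, scheme, r = r)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
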