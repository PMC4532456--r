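#' Canonical worked-example systems
#'
#' A registry of small, fully specified systems that exercise every part
#' of the toolkit and whose statistics are known exactly.  All are built
#' from templates; nor/threshold/bithreshold systems use closed
#' 1-neighborhoods (self-loops), the convention under which those
#' functions are defined.
#'
#' \describe{
#'   \item{\code{circle4_nor_sync}}{bidirected Circle_4, nor functions,
#'     synchronous update.  Three 2-cycles, three basins; the 2-cycle
#'     \{(0,1,0,0),(0,0,0,1)\} is its own basin.}
#'   \item{\code{circle4_nor_seq}}{same graph and functions, sequential
#'     permutation (1,2,3,4).  One 7-cycle, max transient 1.}
#'   \item{\code{circle4_nor_block}}{same, block-sequential
#'     ([1,2],3,4).  One 2-cycle, max transient 3 with ten states at
#'     transient length 3.}
#'   \item{\code{circle4_bithreshold}}{bidirected Circle_4, bithreshold
#'     \code{(k01, k10) = (1, 3)}, sequential permutation (1,2,4,3).
#'     Four attractors whose attractor graph is a single ergodic set of
#'     size 4.}
#'   \item{\code{multistate_circle}}{Circle_n, \code{r = 3},
#'     multi-threshold vector \code{(k01,k10,k12,k21,k02,k20) =
#'     (2,3,6,6,4,5)} (override \code{k01} to 1 to violate the first
#'     fixed-point condition minimally), sequential (1,...,n).  Takes
#'     \code{n} (default 4) and \code{k01}.}
#'   \item{\code{clique_chain}}{\code{count} disjoint cliques of size
#'     \code{q} (defaults 9 and 6), bithreshold \code{(q-1, q-1)},
#'     sequential update.  Each clique contributes an independent factor
#'     of 2 fixed points.}
#' }
#'
#' @param name registry key.
#' @param n,k01,q,count size and threshold parameters for the
#'   parameterized entries (see above).
#' @return a [gds].
#' @examples
#' glance(enumerate_phase_space(gds_example("circle4_nor_seq")))
#' @export
gds_example <- function(name, n = 4, k01 = 2, q = 6, count = 9) {
  circle4 <- function() make_template("circle", n = 4, self_loops = TRUE)
  switch(name,
    circle4_nor_sync = gds(circle4(), vf_nor(), scheme_synchronous(4)),
    circle4_nor_seq = gds(circle4(), vf_nor(), scheme_sequential(1:4)),
    circle4_nor_block = gds(circle4(), vf_nor(),
                            scheme_block(list(c(1, 2), 3, 4))),
    circle4_bithreshold = gds(circle4(), vf_bithreshold(1, 3),
                              scheme_sequential(c(1, 2, 4, 3))),
    multistate_circle = {
      k <- c(k01, 3, 6, 6, 4, 5)
      gds(make_template("circle", n = n, self_loops = TRUE),
          vf_multithreshold(k, r = 3), scheme_sequential(seq_len(n)), r = 3)
    },
    clique_chain = {
      g <- make_template("disjoint_cliques", sizes = rep(q, count),
                         self_loops = TRUE)
      gds(g, vf_bithreshold(q - 1, q - 1), scheme_sequential(seq_len(q * count)))
    },
    rlang::abort(sprintf(
      "unknown example `%s`; available: %s", name,
      paste(c("circle4_nor_sync", "circle4_nor_seq", "circle4_nor_block",
              "circle4_bithreshold", "multistate_circle", "clique_chain"),
            collapse = ", ")))
  )
}
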