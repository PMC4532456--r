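#' Vertex function families
#'
#' A vertex function maps the restricted state \code{x[v]} (the states of
#' the in-neighbors of \code{v}, in ascending vertex order) to the next
#' state of \code{v}.  Five families are supported, plus an explicit
#' truth-table escape hatch:
#'
#' \describe{
#'   \item{\code{vf_nor()}}{Boolean nor: 1 iff every input is 0.}
#'   \item{\code{vf_threshold(k)}}{Boolean threshold: 1 iff the number of
#'     1s among the inputs is at least \code{k}.}
#'   \item{\code{vf_bithreshold(k01, k10)}}{Boolean bithreshold with an
#'     up-threshold \code{k01} (a vertex in state 0 moves to 1 iff at
#'     least \code{k01} neighborhood vertices are in state 1) and a
#'     down-threshold \code{k10} (a vertex in state 1 moves to 0 iff
#'     fewer than \code{k10} are in state 1).  With \code{k01 = k10} it
#'     coincides with the plain threshold function.  The effective ranges
#'     are \code{k01} in \code{[0, d_in + 1]} and \code{k10} in
#'     \code{[1, d_in + 2]}, but any natural number is accepted so one
#'     parameter value can pin a whole vertex class.}
#'   \item{\code{vf_multithreshold(k, r)}}{Multi-state generalization: for
#'     an \code{r}-state system, each ordered pair \code{(i, j)} of
#'     distinct states carries a threshold \code{k_ij} on the sum \code{s}
#'     of neighborhood states.  From state \code{i}, an up-move to
#'     \code{j > i} is enabled iff \code{s >= k_ij}; a down-move to
#'     \code{j < i} is enabled iff \code{s < k_ij}.  The enabled target
#'     farthest from \code{i} is taken (up-moves first), else the vertex
#'     keeps its state.}
#'   \item{\code{vf_linear_threshold(k)}}{Weighted linear threshold for
#'     Boolean regulatory networks: the next state is 1 iff
#'     \code{sum_u w_uv * x_u - k > 0}, using the dependency-graph edge
#'     weights (negative weights inhibit).}
#'   \item{\code{vf_truth_table(outputs, r)}}{Explicit lookup: output
#'     symbol per restricted state, indexed by its mixed-radix code.}
#' }
#'
#' The boolean families require \code{r = 2}.  Bithreshold and
#' multi-threshold functions also consult the vertex's own state, which is
#' passed alongside the restricted state even when the 1-neighborhood is
#' open (no self-loop); the neighborhood count/sum includes the vertex
#' itself exactly when a self-loop is present.
#'
#' @param k threshold (plain threshold: count of 1s; linear threshold: the
#'   vertex threshold subtracted from the weighted input sum).
#' @param k01,k10 up- and down-thresholds.
#' @param r vertex state set size.
#' @param outputs integer vector of length \code{r^d_in}, values in
#'   \code{0..r-1}.
#' @return an object of class \code{vertex_function}.
#' @name vertex_function
NULL

new_vf <- function(family, params) {
  structure(c(list(family = family), params), class = "vertex_function")
}

#' @export
print.vertex_function <- function(x, ...) {
  ps <- x[setdiff(names(x), "family")]
  ps <- ps[!vapply(ps, is.null, logical(1))]
  cat(sprintf("<vertex_function> %s(%s)\n", x$family,
              paste(names(ps), vapply(ps, function(p) paste(p, collapse = " "),
                                      character(1)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @rdname vertex_function
#' @export
vf_nor <- function() new_vf("nor", list())

#' @rdname vertex_function
#' @export
vf_threshold <- function(k) {
  stopifnot(length(k) == 1, k >= 0, k == round(k))
  new_vf("threshold", list(k = as.integer(k)))
}

#' @rdname vertex_function
#' @export
vf_bithreshold <- function(k01, k10) {
  stopifnot(length(k01) == 1, k01 >= 0, k01 == round(k01),
            length(k10) == 1, k10 == round(k10))
  if (k10 < 1) rlang::abort("down-threshold `k10` must be >= 1")
  new_vf("bithreshold", list(k01 = as.integer(k01), k10 = as.integer(k10)))
}

#' @rdname vertex_function
#' @export
vf_multithreshold <- function(k, r = 3) {
  r <- check_r(r)
  K <- multithreshold_matrix(k, r)
  new_vf("multithreshold", list(k = K, r = r))
}

#' @rdname vertex_function
#' @export
vf_linear_threshold <- function(k) {
  stopifnot(length(k) == 1, is.numeric(k))
  new_vf("linear_threshold", list(k = k))
}

#' @rdname vertex_function
#' @export
vf_truth_table <- function(outputs, r = 2) {
  r <- check_r(r)
  outputs <- as.integer(outputs)
  if (any(outputs < 0L) || any(outputs >= r)) {
    rlang::abort(sprintf("truth table outputs must lie in 0..%d", r - 1L))
  }
  d <- log(length(outputs), base = r)
  if (abs(d - round(d)) > 1e-9) {
    rlang::abort("truth table length must be r^d_in for integer d_in")
  }
  new_vf("truth_table", list(outputs = outputs, r = r))
}

# Normalize a multi-threshold spec to an r x r matrix K with K[i+1, j+1]
# = k_ij.  Accepts a matrix, a fully named vector (k01, k10, ...), or for
# r = 3 the conventional ordering (k01, k10, k12, k21, k02, k20).
multithreshold_matrix <- function(k, r) {
  if (is.matrix(k)) {
    if (!all(dim(k) == c(r, r))) rlang::abort("threshold matrix must be r x r")
    return(k)
  }
  K <- matrix(NA_real_, r, r)
  if (!is.null(names(k)) && all(names(k) != "")) {
    for (nm in names(k)) {
      ij <- suppressWarnings(as.integer(strsplit(sub("^k", "", nm), "")[[1]]))
      if (length(ij) != 2 || any(is.na(ij)) || any(ij >= r) || ij[1] == ij[2]) {
        rlang::abort(sprintf("bad threshold name `%s`", nm))
      }
      K[ij[1] + 1, ij[2] + 1] <- k[[nm]]
    }
  } else if (r == 3 && length(k) == 6) {
    ord <- list(c(0, 1), c(1, 0), c(1, 2), c(2, 1), c(0, 2), c(2, 0))
    for (i in seq_along(ord)) K[ord[[i]][1] + 1, ord[[i]][2] + 1] <- k[i]
  } else {
    rlang::abort("`k` must be an r x r matrix or a named k_ij vector")
  }
  miss <- which(is.na(K) & row(K) != col(K), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    rlang::abort(sprintf("missing threshold k%d%d", miss[1, 1] - 1, miss[1, 2] - 1))
  }
  K
}

#' Evaluate single vertex functions
#'
#' Scalar entry points for the function families, convenient for desk
#' checks; the dynamics engine evaluates whole state batches internally.
#' \code{inputs} is the restricted state (neighbor states in ascending
#' vertex order, the vertex's own state included iff it has a self-loop).
#'
#' @param inputs integer vector of 0/1 input states.
#' @param x_v the vertex's own current state.
#' @param k,k01,k10 thresholds as in [vf_threshold()] and
#'   [vf_bithreshold()].
#' @param s sum of neighborhood states (multi-threshold).
#' @param thresholds multi-threshold spec as in [vf_multithreshold()].
#' @param r state set size for the multi-threshold family.
#' @param states,weights neighbor states and matching edge weights
#'   (linear threshold).
#' @param k_v vertex threshold (linear threshold).
#' @return the next state symbol.
#' @examples
#' nor_fn(c(0, 0, 0))               # 1
#' threshold_fn(c(1, 1, 0), k = 2)  # 1
#' bithreshold_fn(1, c(1, 0, 0), k01 = 1, k10 = 3)  # 0
#' @export
nor_fn <- function(inputs) {
  check_binary(inputs)
  as.integer(all(inputs == 0))
}

#' @rdname nor_fn
#' @export
threshold_fn <- function(inputs, k) {
  check_binary(inputs)
  as.integer(sum(inputs == 1) >= k)
}

#' @rdname nor_fn
#' @export
bithreshold_fn <- function(x_v, inputs, k01, k10) {
  check_binary(c(x_v, inputs))
  if (k10 < 1) rlang::abort("`k10` must be >= 1")
  sigma <- sum(inputs == 1)
  if (x_v == 0) as.integer(sigma >= k01) else as.integer(!(sigma < k10))
}

#' @rdname nor_fn
#' @export
multithreshold_fn <- function(x_v, s, thresholds, r = 3) {
  r <- check_r(r)
  K <- multithreshold_matrix(thresholds, r)
  if (s < 0) rlang::abort("`s` must be a non-negative state sum")
  stopifnot(x_v >= 0, x_v < r)
  i <- as.integer(x_v)
  if (i < r - 1L) for (j in (r - 1L):(i + 1L)) {   # farthest up-move first
    if (s >= K[i + 1, j + 1]) return(as.integer(j))
  }
  if (i > 0L) for (j in 0:(i - 1L)) {              # farthest down-move first
    if (s < K[i + 1, j + 1]) return(as.integer(j))
  }
  i
}

#' @rdname nor_fn
#' @export
linear_threshold_fn <- function(states, weights, k_v) {
  check_binary(states)
  if (length(states) != length(weights)) {
    rlang::abort("`states` and `weights` must have equal length")
  }
  as.integer(sum(weights * states) - k_v > 0)
}

check_binary <- function(x) {
  if (any(!x %in% c(0L, 1L))) rlang::abort("inputs must be binary (0/1)")
  invisible(x)
}

# Vectorized evaluation over a batch of system states: M is an N x n state
# matrix; returns the N next states of vertex v computed from M.
eval_vertex <- function(vf, v, M, graph, r) {
  nbr <- graph$nbr[[v]]
  sub <- M[, nbr, drop = FALSE]
  switch(vf$family,
    nor = as.integer(rowSums(sub) == 0),
    threshold = as.integer(rowSums(sub == 1L) >= vf$k),
    bithreshold = {
      sigma <- rowSums(sub == 1L)
      xv <- M[, v]
      as.integer(ifelse(xv == 0L, sigma >= vf$k01, !(sigma < vf$k10)))
    },
    multithreshold = {
      s <- rowSums(sub)
      xv <- M[, v]
      out <- xv
      K <- vf$k
      for (i in 0:(r - 1L)) {
        remaining <- which(xv == i)
        if (i < r - 1L) for (j in (r - 1L):(i + 1L)) {       # farthest up first
          hit <- remaining[s[remaining] >= K[i + 1, j + 1]]
          out[hit] <- j
          remaining <- setdiff(remaining, hit)
        }
        if (i > 0L) for (j in 0:(i - 1L)) {                  # farthest down first
          hit <- remaining[s[remaining] < K[i + 1, j + 1]]
          out[hit] <- j
          remaining <- setdiff(remaining, hit)
        }
      }
      out
    },
    linear_threshold = {
      w <- graph$wts[[v]]
      as.integer(as.vector(sub %*% w) - vf$k > 0)
    },
    truth_table = {
      codes <- if (length(nbr) == 0) rep(0, nrow(M)) else encode_rows(sub, r)
      if (length(vf$outputs) != r^length(nbr)) {
        rlang::abort(sprintf("truth table for vertex %d has %d entries, need %g",
                             v, length(vf$outputs), r^length(nbr)))
      }
      vf$outputs[codes + 1]
    },
    rlang::abort(sprintf("unknown vertex function family `%s`", vf$family))
  )
}
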