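#' Encode and decode system states
#'
#' A system state is a tuple \code{(x_1, ..., x_n)} with each symbol in
#' \code{0..r-1}.  States are numbered by a mixed-radix code with
#' \code{x_1} as the most significant digit, so that tuples sort
#' lexicographically by code:
#' \code{code = sum_v x_v * r^(n - v)}, an integer in \code{[0, r^n)}.
#'
#' @param values integer vector of vertex states, each in \code{0..r-1}.
#' @param r vertex state set size (\code{r >= 2}).
#' @return `encode_state()` returns the code; `decode_state()` the tuple.
#' @examples
#' encode_state(c(1, 1, 1, 1), r = 2)  # 15
#' decode_state(6, n = 4, r = 2)       # c(0, 1, 1, 0)
#' @export
encode_state <- function(values, r) {
  r <- check_r(r)
  values <- as.integer(values)
  if (any(values < 0L) || any(values >= r)) {
    rlang::abort(sprintf("state symbols must lie in 0..%d", r - 1L))
  }
  n <- length(values)
  sum(values * r^(n - seq_len(n)))
}

#' @param code state code in \code{[0, r^n)}.
#' @param n number of vertices.
#' @rdname encode_state
#' @export
decode_state <- function(code, n, r) {
  r <- check_r(r)
  if (length(code) != 1 || code < 0 || code >= r^n || code != round(code)) {
    rlang::abort(sprintf("`code` must be an integer in [0, %g)", r^n))
  }
  (code %/% r^(n - seq_len(n))) %% r
}

check_r <- function(r) {
  if (length(r) != 1 || r < 2 || r != round(r)) {
    rlang::abort("`r` must be a single integer >= 2")
  }
  as.integer(r)
}

# All r^n states as an r^n x n integer matrix, row i = decode(i - 1).
state_matrix <- function(n, r) {
  N <- r^n
  codes <- seq_len(N) - 1
  m <- matrix(0L, N, n)
  for (v in seq_len(n)) m[, v] <- as.integer((codes %/% r^(n - v)) %% r)
  m
}

# Codes for the rows of a state matrix (vectorized encode).
encode_rows <- function(m, r) {
  n <- ncol(m)
  as.vector(m %*% r^(n - seq_len(n)))
}

# "(x1,x2,...,xn)" rendering used in printed output and result files.
format_state <- function(values) {
  paste0("(", paste(values, collapse = ","), ")")
}
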