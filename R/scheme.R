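#' Update schemes
#'
#' An update scheme is a "block word": an ordered sequence of non-empty
#' vertex blocks \code{(B_1, ..., B_m)}.  Within a block all vertex
#' functions read the same pre-block state and fire simultaneously;
#' blocks are applied left to right, and one application of the whole
#' word is one time step of the system map.
#'
#' The classical schemes are special block words:
#' \describe{
#'   \item{\code{scheme_synchronous(n)}}{one block holding all vertices.}
#'   \item{\code{scheme_sequential(perm)}}{singleton blocks in permutation
#'     order (\code{perm} must be a permutation of \code{1..n}).}
#'   \item{\code{scheme_block(blocks)}}{arbitrary block sequence; fair iff
#'     the blocks partition the vertex set.}
#'   \item{\code{scheme_word(word)}}{singleton blocks with repeats and
#'     omissions allowed (an unfair word order).}
#' }
#'
#' @param n number of vertices.
#' @param perm integer permutation of \code{1..n}.
#' @param blocks list of non-empty integer vectors.
#' @param word integer vector of vertex ids, repeats allowed.
#' @return an object of class \code{update_scheme}.
#' @examples
#' scheme_sequential(c(1, 2, 4, 3))
#' scheme_block(list(c(1, 2), 3, 4))
#' @name update_scheme
NULL

new_scheme <- function(kind, blocks) {
  blocks <- lapply(blocks, function(b) {
    b <- as.integer(b)
    if (length(b) == 0) rlang::abort("update blocks must be non-empty")
    if (anyDuplicated(b)) rlang::abort("a block may not repeat a vertex")
    b
  })
  ids <- unlist(blocks)
  fair <- !anyDuplicated(ids) && setequal(ids, seq_len(max(ids)))
  structure(list(kind = kind, blocks = blocks, fair = fair),
            class = "update_scheme")
}

#' @rdname update_scheme
#' @export
scheme_synchronous <- function(n) {
  stopifnot(n >= 1)
  new_scheme("synchronous", list(seq_len(n)))
}

#' @rdname update_scheme
#' @export
scheme_sequential <- function(perm) {
  perm <- as.integer(perm)
  if (!setequal(perm, seq_along(perm)) || anyDuplicated(perm)) {
    rlang::abort("`perm` must be a permutation of 1..n")
  }
  new_scheme("sequential", as.list(perm))
}

#' @rdname update_scheme
#' @export
scheme_block <- function(blocks) new_scheme("block_sequential", blocks)

#' @rdname update_scheme
#' @export
scheme_word <- function(word) {
  word <- as.integer(word)
  if (length(word) == 0) rlang::abort("`word` must be non-empty")
  new_scheme("word", as.list(word))
}

#' @export
print.update_scheme <- function(x, ...) {
  cat(sprintf("<update_scheme> %s: %s%s\n", x$kind,
              paste(vapply(x$blocks, function(b) {
                if (length(b) == 1) as.character(b)
                else paste0("[", paste(b, collapse = ","), "]")
              }, character(1)), collapse = " "),
              if (x$fair) "" else " (unfair)"))
  invisible(x)
}

# check a scheme against a vertex count
validate_scheme <- function(scheme, n) {
  ids <- unlist(scheme$blocks)
  if (any(ids < 1L) || any(ids > n)) {
    rlang::abort(sprintf("scheme refers to vertex outside 1..%d", n))
  }
  if (scheme$kind %in% c("synchronous", "sequential", "block_sequential")) {
    if (!setequal(ids, seq_len(n)) || anyDuplicated(ids)) {
      rlang::abort(sprintf("a fair %s scheme must cover each of 1..%d exactly once",
                           scheme$kind, n))
    }
  }
  invisible(scheme)
}
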