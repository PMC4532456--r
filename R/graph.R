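#' Dependency graphs
#'
#' A dependency graph is the directed influence structure of a graph
#' dynamical system: an edge \code{(u, v)} means the state of vertex
#' \code{u} is an input to the vertex function of \code{v}.  Vertices are
#' the integers \code{1..n}.  A self-loop \code{(v, v)} is an ordinary
#' edge and makes the 1-neighborhood of \code{v} closed, i.e. \code{v}
#' reads its own state through its restricted state.
#'
#' @param edges a data frame with columns \code{from}, \code{to} and
#'   optionally \code{weight} (default 1).  With \code{directed = FALSE}
#'   each row \code{\{u, v\}} expands to both \code{(u, v)} and
#'   \code{(v, u)} with equal weight; self-loops expand to a single edge.
#' @param n_vertices number of vertices; defaults to the largest vertex id
#'   seen in \code{edges}.
#' @param directed are the rows of \code{edges} directed pairs?
#' @param default_weight weight used where \code{edges} has no
#'   \code{weight} column.
#'
#' @return an object of class \code{dependency_graph} with elements
#'   \code{n} (vertex count), \code{edges} (tibble of directed edges with
#'   weights), \code{nbr} (per-vertex in-neighbor sequence, sorted by
#'   ascending vertex id) and \code{wts} (in-edge weights aligned with
#'   \code{nbr}).
#' @examples
#' g <- dependency_graph(data.frame(from = c(1, 2), to = c(2, 1)))
#' in_neighbors(g, 2)
#' @export
dependency_graph <- function(edges, n_vertices = NULL, directed = TRUE,
                             default_weight = 1) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    rlang::abort("`edges` must have columns `from` and `to`.")
  }
  if (!"weight" %in% names(edges)) edges$weight <- default_weight
  edges <- edges[c("from", "to", "weight")]
  if (nrow(edges) > 0 &&
      (any(edges$from != round(edges$from)) || any(edges$to != round(edges$to)))) {
    rlang::abort("vertex ids must be integers")
  }
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (nrow(edges) > 0 && (any(edges$from < 1L) || any(edges$to < 1L))) {
    rlang::abort("vertex ids must be >= 1")
  }
  if (!directed) {
    rev <- edges[edges$from != edges$to, c("to", "from", "weight")]
    names(rev) <- c("from", "to", "weight")
    edges <- dplyr::bind_rows(edges, rev)
  }
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  n <- if (is.null(n_vertices)) {
    if (nrow(edges) == 0) 0L else max(edges$from, edges$to)
  } else {
    as.integer(n_vertices)
  }
  if (nrow(edges) > 0 && max(edges$from, edges$to) > n) {
    rlang::abort("edge references a vertex id beyond `n_vertices`")
  }
  edges <- dplyr::arrange(edges, .data$to, .data$from)
  nbr <- vector("list", n)
  wts <- vector("list", n)
  sp <- split(seq_len(nrow(edges)), factor(edges$to, levels = seq_len(n)))
  for (v in seq_len(n)) {
    i <- sp[[v]]
    nbr[[v]] <- edges$from[i]   # already ascending from the arrange()
    wts[[v]] <- edges$weight[i]
  }
  structure(list(n = n, edges = edges, nbr = nbr, wts = wts),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat(sprintf("<dependency_graph> %d vertices, %d directed edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' In-neighbor sequence of a vertex
#'
#' The sorted sequence \code{n[v]} of in-neighbors of \code{v}; its states,
#' taken in this order, form the restricted state \code{x[v]} that the
#' vertex function of \code{v} consumes.
#'
#' @param graph a [dependency_graph].
#' @param v vertex id.
#' @return integer vector of in-neighbor ids, ascending.
#' @export
in_neighbors <- function(graph, v) {
  stopifnot(inherits(graph, "dependency_graph"), v >= 1, v <= graph$n)
  graph$nbr[[v]]
}

#' Graph templates
#'
#' Deterministic generators for the standard dependency-graph families:
#' circles (cycles), paths, cliques, bicliques, stars, rectangular grid
#' lattices, balanced trees and disjoint unions of cliques.  All templates
#' produce bidirected edges by default (each undirected edge becomes two
#' directed edges of equal weight), since threshold-type dynamics are
#' usually posed on undirected graphs.  Self-loops (closed
#' 1-neighborhoods) are added only on request: threshold and bithreshold
#' functions are conventionally defined over closed neighborhoods, while
#' drawings of the underlying graphs omit the loops.
#'
#' @param name one of \code{"circle"}, \code{"path"}, \code{"clique"},
#'   \code{"biclique"}, \code{"star"}, \code{"grid"},
#'   \code{"balanced_tree"}, \code{"disjoint_cliques"}.
#' @param n vertex count (circle, path, star: total including the hub).
#' @param q clique size for \code{"clique"}.
#' @param m,k part sizes for \code{"biclique"} (vertices \code{1..m} vs
#'   \code{m+1..m+k}).
#' @param rows,cols grid dimensions.
#' @param branching,depth balanced tree shape: every internal vertex has
#'   \code{branching} children, leaves at distance \code{depth} from the
#'   root.
#' @param sizes integer vector of clique sizes for
#'   \code{"disjoint_cliques"}.
#' @param bidirected expand undirected edges to both directions (default
#'   \code{TRUE}); with \code{FALSE}, circles and paths are oriented
#'   \code{v -> v+1} and trees parent -> child.
#' @param self_loops add a self-loop at every vertex.
#'
#' @return a [dependency_graph].
#' @examples
#' make_template("circle", n = 4)                      # 8 directed edges
#' make_template("clique", q = 6, self_loops = TRUE)   # closed K_6
#' @export
make_template <- function(name, n = NULL, q = NULL, m = NULL, k = NULL,
                          rows = NULL, cols = NULL, branching = NULL,
                          depth = NULL, sizes = NULL,
                          bidirected = TRUE, self_loops = FALSE) {
  pos <- function(x, what) {
    if (is.null(x) || length(x) == 0 || any(x < 1) || any(x != round(x))) {
      rlang::abort(sprintf("template `%s` needs positive integer %s", name, what))
    }
    as.integer(x)
  }
  und <- switch(name,
    circle = {
      n <- pos(n, "`n`")
      if (n < 3) rlang::abort("a circle needs n >= 3")
      cbind(seq_len(n), c(seq_len(n)[-1], 1L))
    },
    path = {
      n <- pos(n, "`n`")
      if (n < 2) rlang::abort("a path needs n >= 2")
      cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    },
    clique = {
      q <- pos(q, "`q`")
      n <- q
      if (q == 1) matrix(integer(), 0, 2) else t(utils::combn(q, 2))
    },
    biclique = {
      m <- pos(m, "`m`"); k <- pos(k, "`k`")
      n <- m + k
      as.matrix(expand.grid(seq_len(m), m + seq_len(k)))
    },
    star = {
      n <- pos(n, "`n`")
      if (n < 2) rlang::abort("a star needs n >= 2")
      cbind(1L, 1L + seq_len(n - 1))
    },
    grid = {
      rows <- pos(rows, "`rows`"); cols <- pos(cols, "`cols`")
      n <- rows * cols
      id <- function(r, c) (r - 1L) * cols + c
      horiz <- if (cols > 1) {
        eg <- expand.grid(r = seq_len(rows), c = seq_len(cols - 1))
        cbind(id(eg$r, eg$c), id(eg$r, eg$c + 1L))
      } else matrix(integer(), 0, 2)
      vert <- if (rows > 1) {
        eg <- expand.grid(r = seq_len(rows - 1), c = seq_len(cols))
        cbind(id(eg$r, eg$c), id(eg$r + 1L, eg$c))
      } else matrix(integer(), 0, 2)
      rbind(horiz, vert)
    },
    balanced_tree = {
      branching <- pos(branching, "`branching`")
      depth <- pos(depth, "`depth`")
      n <- as.integer(sum(branching^(0:depth)))
      child <- seq(2L, n)
      parent <- (child - 2L) %/% branching + 1L
      cbind(parent, child)
    },
    disjoint_cliques = {
      sizes <- pos(sizes, "`sizes`")
      n <- sum(sizes)
      off <- cumsum(c(0L, sizes[-length(sizes)]))
      do.call(rbind, lapply(seq_along(sizes), function(i) {
        qi <- sizes[i]
        if (qi == 1) matrix(integer(), 0, 2) else off[i] + t(utils::combn(qi, 2))
      }))
    },
    rlang::abort(sprintf("unknown template `%s`", name))
  )
  edges <- tibble::tibble(from = as.integer(und[, 1]),
                          to = as.integer(und[, 2]), weight = 1)
  if (self_loops) {
    edges <- dplyr::bind_rows(
      edges, tibble::tibble(from = seq_len(n), to = seq_len(n), weight = 1))
  }
  dependency_graph(edges, n_vertices = n, directed = !bidirected)
}

#' Read a dependency graph from an edge-list file
#'
#' One edge per line, \code{u v [weight]}, separated by tabs or spaces;
#' blank lines and lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @param directed treat lines as directed pairs (default) or expand each
#'   to both directions.
#' @param default_weight weight for lines without a third field.
#' @param n_vertices optional vertex count (isolated trailing vertices).
#' @return a [dependency_graph].
#' @export
read_edge_list <- function(path, directed = TRUE, default_weight = 1,
                           n_vertices = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("edge list `%s` does not exist", path))
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 2 || length(f) > 3) {
      rlang::abort(sprintf("%s: malformed edge at line %d", path, i))
    }
    uv <- suppressWarnings(as.integer(f[1:2]))
    if (any(is.na(uv))) {
      rlang::abort(sprintf("%s: non-integer vertex id at line %d", path, i))
    }
    w <- if (length(f) == 3) suppressWarnings(as.numeric(f[3])) else default_weight
    if (is.na(w)) rlang::abort(sprintf("%s: bad weight at line %d", path, i))
    tibble::tibble(from = uv[1], to = uv[2], weight = w)
  })
  edges <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(from = integer(), to = integer(), weight = numeric())
  }
  dependency_graph(edges, n_vertices = n_vertices, directed = directed)
}

#' Write a dependency graph as an edge-list file
#'
#' @param graph a [dependency_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "dependency_graph"))
  e <- graph$edges
  writeLines(sprintf("%d\t%d\t%g", e$from, e$to, e$weight), path)
  invisible(path)
}

# igraph view of the symmetrized influence structure (used for components)
as_igraph_undirected <- function(graph) {
  e <- graph$edges[graph$edges$from != graph$edges$to, ]
  igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = seq_len(graph$n)))
}
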