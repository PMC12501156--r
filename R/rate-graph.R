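#' Build a linear-framework rate graph
#'
#' A rate graph encodes a continuous-time Markov process over molecular
#' states of a regulatory system: vertices are states, directed edges are
#' transitions.  Each edge label is affine in the transcription-factor (TF)
#' concentration \code{x}: the effective rate is
#' \code{rate + x_coeff * x}, so TF-binding edges carry their
#' concentration dependence in \code{x_coeff} while all other transitions
#' are constant.  Vertices may carry a transcription weight \code{q}
#' (transcripts/time emitted while the system occupies that state).
#'
#' @param vertices character vector of unique state identifiers.
#' @param edges data frame with columns \code{from}, \code{to},
#'   \code{rate} (1/time) and \code{x_coeff} (1/(time*concentration));
#'   \code{x_coeff} defaults to 0 if absent.  At most one edge per ordered
#'   vertex pair.
#' @param q named numeric vector of per-vertex transcription rates;
#'   vertices not named default to 0.
#'
#' @return An object of class \code{rate_graph}.
#' @examples
#' g <- rate_graph(c("off", "on"),
#'                 data.frame(from = c("off", "on"), to = c("on", "off"),
#'                            rate = c(0, 2), x_coeff = c(1, 0)),
#'                 q = c(on = 1))
#' graph_rates(g, x = 4)
#' @export
rate_graph <- function(vertices, edges, q = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices))
    stop("duplicate vertex identifiers")
  if (length(vertices) < 2L)
    stop("a rate graph needs at least two vertices")
  edges <- as.data.frame(edges)
  if (is.null(edges$x_coeff)) edges$x_coeff <- 0
  edges <- edges[, c("from", "to", "rate", "x_coeff")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(edges$from %in% vertices) || !all(edges$to %in% vertices))
    stop("edge endpoints must be declared vertices")
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed")
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key))
    stop("at most one edge per ordered vertex pair: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(edges$rate < 0) || any(edges$x_coeff < 0))
    stop("edge labels must be nonnegative (rates are nonnegative for all x >= 0)")
  qv <- stats::setNames(numeric(length(vertices)), vertices)
  if (!is.null(q)) {
    if (is.null(names(q)) || !all(names(q) %in% vertices))
      stop("q must be named by vertex")
    if (any(q < 0)) stop("transcription weights must be nonnegative")
    qv[names(q)] <- q
  }
  structure(list(vertices = vertices, edges = edges, q = qv),
            class = "rate_graph")
}

#' @export
print.rate_graph <- function(x, ...) {
  cat("rate_graph:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  cat("  vertices:", paste(x$vertices, collapse = ", "), "\n")
  nb <- sum(x$edges$x_coeff > 0)
  cat("  ", nb, " concentration-dependent edge(s), ",
      sum(x$q > 0), " transcribing state(s)\n", sep = "")
  invisible(x)
}

vertex_index <- function(graph, v) match(v, graph$vertices)

#' Effective transition-rate matrix at a TF concentration
#'
#' Evaluates every edge label at concentration \code{x} and arranges the
#' effective rates in a matrix whose \code{[i, j]} entry is the rate of
#' the transition \code{i -> j}.  No diagonal convention is imposed; the
#' Laplacian used by the master equation is assembled by callers (see
#' \code{\link{laplacian_matrix}}).
#'
#' @param graph a \code{\link{rate_graph}}.
#' @param x TF concentration (scalar, \code{x >= 0}).
#' @return numeric matrix with vertex labels on both dimensions;
#'   off-diagonal entries are effective rates, absent edges are 0.
#' @export
graph_rates <- function(graph, x) {
  stopifnot(inherits(graph, "rate_graph"), length(x) == 1L, x >= 0)
  eff <- graph$edges$rate + graph$edges$x_coeff * x
  if (any(eff < 0)) {
    bad <- which(eff < 0)[1L]
    stop("negative effective rate on edge ", graph$edges$from[bad],
         " -> ", graph$edges$to[bad], " at x = ", x)
  }
  n <- length(graph$vertices)
  m <- matrix(0, n, n, dimnames = list(graph$vertices, graph$vertices))
  m[cbind(vertex_index(graph, graph$edges$from),
          vertex_index(graph, graph$edges$to))] <- eff
  m
}

#' Column-based Laplacian of the master equation
#'
#' Returns \code{L} such that the master equation reads
#' \code{dP/dt = L \%*\% P}: \code{L[i, j]} for \code{i != j} is the rate
#' of \code{j -> i}, and each column sums to zero.
#'
#' @inheritParams graph_rates
#' @return numeric matrix with zero column sums.
#' @export
laplacian_matrix <- function(graph, x) {
  A <- graph_rates(graph, x)
  L <- t(A)
  diag(L) <- -rowSums(A)   # total exit rate of each state
  L
}

# adjacency on declared structure (an edge counts even where its effective
# rate vanishes at a particular x, e.g. binding edges at x = 0)
structural_adjacency <- function(graph) {
  n <- length(graph$vertices)
  m <- matrix(FALSE, n, n, dimnames = list(graph$vertices, graph$vertices))
  m[cbind(vertex_index(graph, graph$edges$from),
          vertex_index(graph, graph$edges$to))] <- TRUE
  m
}

reachable_from <- function(adj, start) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- start
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] & !seen))
  }
  seen
}

#' Test strong connectivity of the declared graph structure
#'
#' @inheritParams graph_rates
#' @return logical scalar; attribute \code{"unreachable"} lists vertices
#'   not reachable from the first vertex when \code{FALSE}.
#' @export
is_strongly_connected <- function(graph) {
  adj <- structural_adjacency(graph)
  fwd <- reachable_from(adj, 1L)
  bwd <- reachable_from(t(adj), 1L)
  ok <- all(fwd) && all(bwd)
  structure(ok, unreachable = graph$vertices[!(fwd & bwd)])
}

#' Serialize a rate graph to JSON
#'
#' Round-trip exact: \code{graph_from_json(graph_to_json(g))} reproduces
#' the graph, including transcription weights.
#'
#' @param graph a \code{\link{rate_graph}}.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return \code{path} (invisibly) if given, else a JSON string.
#' @export
graph_to_json <- function(graph, path = NULL) {
  obj <- list(
    vertices = graph$vertices,
    edges = lapply(seq_len(nrow(graph$edges)), function(i)
      list(from = graph$edges$from[i], to = graph$edges$to[i],
           rate = graph$edges$rate[i], x_coeff = graph$edges$x_coeff[i])),
    q = as.list(graph$q[graph$q > 0]))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname graph_to_json
#' @param json a JSON string or path to a JSON file written by
#'   \code{graph_to_json}.
#' @export
graph_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  q <- unlist(obj$q)
  rate_graph(obj$vertices, as.data.frame(obj$edges),
             q = if (length(q)) q else NULL)
}
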