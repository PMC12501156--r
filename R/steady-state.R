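# Steady states of linear-framework graphs.
#
# Two production routes: the equilibrium path-product construction (valid
# when the Kolmogorov cycle condition holds) and the spanning-tree
# (Matrix-Tree) construction, valid for any strongly connected graph.
# Two independent oracle routes (Laplacian nullspace, master-equation ODE)
# exist for cross-validation and are used in tests only.

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# stand-in for log(0) that survives summation over <= 12 edges without
# overflow and still underflows to probability 0 after exponentiation
LOG_ZERO <- -1e7

new_steady_state <- function(p, rho, method) {
  structure(list(probabilities = p, rho = rho, method = method),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady_state (", x$method, ")\n", sep = "")
  print(round(x$probabilities, 6))
  invisible(x)
}

# ---- cycle condition ------------------------------------------------------

# path from v to the BFS root, as a vertex index sequence (v first)
path_to_root <- function(parent, v) {
  p <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    p <- c(p, v)
  }
  p
}

# undirected spanning tree (BFS parents) + list of non-tree vertex pairs
undirected_support <- function(graph) {
  n <- length(graph$vertices)
  i <- vertex_index(graph, graph$edges$from)
  j <- vertex_index(graph, graph$edges$to)
  pairs <- unique(t(apply(cbind(i, j), 1, sort)))
  adj <- vector("list", n)
  for (r in seq_len(nrow(pairs))) {
    adj[[pairs[r, 1]]] <- c(adj[[pairs[r, 1]]], pairs[r, 2])
    adj[[pairs[r, 2]]] <- c(adj[[pairs[r, 2]]], pairs[r, 1])
  }
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  seen[1] <- TRUE
  queue <- 1L
  tree_pairs <- matrix(integer(0), 0, 2)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        tree_pairs <- rbind(tree_pairs, sort(c(v, w)))
        queue <- c(queue, w)
      }
    }
  }
  tree_keys <- if (nrow(tree_pairs)) paste(tree_pairs[, 1], tree_pairs[, 2])
               else character(0)
  in_tree <- paste(pairs[, 1], pairs[, 2]) %in% tree_keys
  list(parent = parent, chords = pairs[!in_tree, , drop = FALSE],
       connected = all(seen))
}

#' Test the Kolmogorov cycle condition (detailed balance)
#'
#' A strongly connected, reversible graph admits an equilibrium steady
#' state exactly when, around every cycle, the product of forward
#' effective rates equals the product of reverse effective rates.  It is
#' sufficient to test a cycle basis derived from a spanning tree of the
#' undirected support.
#'
#' @inheritParams graph_rates
#' @param rtol relative tolerance on the forward/backward product ratio.
#' @return logical scalar; attributes \code{"report"} (data frame with one
#'   row per basis cycle: the cycle, forward and backward products) and
#'   \code{"missing_reverse"} (edges with no structural reverse, which
#'   alone force \code{FALSE}).
#' @export
check_cycle_condition <- function(graph, x, rtol = 1e-9) {
  adj <- structural_adjacency(graph)
  i <- vertex_index(graph, graph$edges$from)
  j <- vertex_index(graph, graph$edges$to)
  no_rev <- !adj[cbind(j, i)]
  if (any(no_rev)) {
    miss <- paste0(graph$edges$from[no_rev], " -> ", graph$edges$to[no_rev],
                   " (no reverse)")
    return(structure(FALSE, report = NULL, missing_reverse = miss))
  }
  A <- graph_rates(graph, x)
  sup <- undirected_support(graph)
  if (!sup$connected) stop("graph support is not connected")
  cyc_prod <- function(vseq) {
    nx <- c(vseq[-1], vseq[1])
    c(fwd = prod(A[cbind(vseq, nx)]), bwd = prod(A[cbind(nx, vseq)]))
  }
  rows <- lapply(seq_len(nrow(sup$chords)), function(r) {
    u <- sup$chords[r, 1]; v <- sup$chords[r, 2]
    pu <- path_to_root(sup$parent, u)
    pv <- path_to_root(sup$parent, v)
    lca <- pu[pu %in% pv][1]
    # closed walk: chord u -> v, tree path v .. lca, tree path lca .. u
    vseq <- c(u, pv[seq_len(which(pv == lca))],
              rev(pu[seq_len(which(pu == lca))]))
    vseq <- vseq[c(TRUE, diff(vseq) != 0)]        # drop adjacent repeats
    if (vseq[length(vseq)] == vseq[1]) vseq <- vseq[-length(vseq)]
    pr <- cyc_prod(vseq)
    data.frame(cycle = paste(graph$vertices[vseq], collapse = " -> "),
               forward = pr["fwd"], backward = pr["bwd"],
               row.names = NULL)
  })
  report <- do.call(rbind, rows)
  if (is.null(report)) {          # tree graph: no cycles, trivially balanced
    return(structure(TRUE, report = data.frame(), missing_reverse = NULL))
  }
  scale <- pmax(report$forward, report$backward)
  bal <- abs(report$forward - report$backward) <= rtol * pmax(scale, 1e-300)
  bal[scale == 0] <- TRUE
  report$balanced <- bal
  structure(all(bal), report = report, missing_reverse = NULL)
}

# ---- equilibrium path products -------------------------------------------

#' Equilibrium steady state by path products
#'
#' When the cycle condition holds, the steady-state probability of state i
#' is proportional to the product of forward/backward rate ratios along
#' any path from a reference state to i; the cycle condition guarantees
#' path independence.
#'
#' @inheritParams check_cycle_condition
#' @param reference reference state assigned unnormalized weight 1.
#' @return a \code{steady_state} with method \code{"equilibrium_path_product"}.
#' @export
steady_state_equilibrium <- function(graph, x,
                                     reference = graph$vertices[1]) {
  cc <- check_cycle_condition(graph, x)
  if (!isTRUE(cc))
    stop("cycle condition fails at x = ", x,
         "; the steady state is not an equilibrium -- ",
         "use steady_state_spanning_tree()")
  A <- graph_rates(graph, x)
  n <- length(graph$vertices)
  ref <- vertex_index(graph, reference)
  if (is.na(ref)) stop("unknown reference vertex: ", reference)
  logmu <- rep(NA_real_, n)
  logmu[ref] <- 0
  queue <- ref
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in which((A[v, ] > 0 | A[, v] > 0) & is.na(logmu))) {
      if (A[v, w] <= 0 || A[w, v] <= 0)
        stop("zero transition rate between ", graph$vertices[v], " and ",
             graph$vertices[w], " at x = ", x,
             ": equilibrium ratios undefined")
      logmu[w] <- logmu[v] + log(A[v, w]) - log(A[w, v])
      queue <- c(queue, w)
    }
  }
  if (anyNA(logmu))
    stop("vertices unreachable from reference at x = ", x, ": ",
         paste(graph$vertices[is.na(logmu)], collapse = ", "))
  p <- exp(logmu - logsumexp(logmu))
  names(p) <- graph$vertices
  new_steady_state(p, rho = exp(logmu - max(logmu)),
                   method = "equilibrium_path_product")
}

# ---- spanning trees -------------------------------------------------------

# enumerate spanning in-trees rooted at each vertex: a tree rooted at r
# assigns every other vertex exactly one outgoing edge such that iterating
# the assignment always reaches r.  Returns, per root, a matrix of edge
# indices (one row per tree).
enumerate_rooted_trees <- function(graph) {
  n <- length(graph$vertices)
  if (n > 12L)
    stop("exhaustive spanning-tree enumeration is limited to 12 vertices; ",
         "use steady_state_oracle(method = 'nullspace') for larger graphs")
  from <- vertex_index(graph, graph$edges$from)
  to <- vertex_index(graph, graph$edges$to)
  out_edges <- split(seq_along(from), factor(from, levels = seq_len(n)))
  lapply(seq_len(n), function(root) {
    others <- setdiff(seq_len(n), root)
    trees <- list()
    choice <- integer(n)    # edge index chosen per vertex (0 = unassigned)
    recurse <- function(k) {
      if (k > length(others)) {
        trees[[length(trees) + 1L]] <<- choice[others]
        return(invisible())
      }
      v <- others[k]
      for (e in out_edges[[v]]) {
        # walk the partial assignment from the edge target; a return to v
        # would close a cycle avoiding the root
        w <- to[e]
        ok <- TRUE
        while (w != root && choice[w] != 0L) {
          if (w == v) { ok <- FALSE; break }
          w <- to[choice[w]]
        }
        if (w == v) ok <- FALSE
        if (ok) {
          choice[v] <<- e
          recurse(k + 1L)
          choice[v] <<- 0L
        }
      }
    }
    recurse(1L)
    if (!length(trees))
      matrix(integer(0), 0, n - 1L)
    else
      do.call(rbind, trees)
  })
}

# vectorized spanning-tree probabilities over a concentration grid.
# Returns list(P = n x length(xs) matrix, log_rho = n x length(xs)).
spanning_probs <- function(graph, xs, log_space = TRUE, trees = NULL) {
  stopifnot(all(xs >= 0))
  sc <- is_strongly_connected(graph)
  if (!sc)
    stop("graph is not strongly connected; unreachable: ",
         paste(attr(sc, "unreachable"), collapse = ", "))
  n <- length(graph$vertices)
  if (n > 12L) {
    warning("graph exceeds 12 vertices; using the Laplacian nullspace ",
            "instead of spanning-tree enumeration")
    P <- vapply(xs, function(xx)
      steady_state_oracle(graph, xx, "nullspace")$probabilities,
      numeric(n))
    P <- matrix(P, n, length(xs), dimnames = list(graph$vertices, NULL))
    return(list(P = P, log_rho = log(P)))
  }
  if (is.null(trees)) trees <- enumerate_rooted_trees(graph)
  eff <- outer(graph$edges$x_coeff, xs) + graph$edges$rate   # E x nx
  if (log_space) {
    lr <- log(eff)
    lr[!is.finite(lr)] <- LOG_ZERO
    logrho <- matrix(NA_real_, n, length(xs),
                     dimnames = list(graph$vertices, NULL))
    for (r in seq_len(n)) {
      Tm <- trees[[r]]
      if (nrow(Tm) == 0L) { logrho[r, ] <- -Inf; next }
      ind <- matrix(0, nrow(Tm), nrow(graph$edges))
      ind[cbind(rep(seq_len(nrow(Tm)), ncol(Tm)), as.vector(Tm))] <- 1
      tl <- ind %*% lr                                      # trees x nx
      m <- apply(tl, 2, max)
      logrho[r, ] <- m + log(colSums(exp(sweep(tl, 2, m))))
    }
  } else {
    logrho <- matrix(NA_real_, n, length(xs),
                     dimnames = list(graph$vertices, NULL))
    for (r in seq_len(n)) {
      Tm <- trees[[r]]
      if (nrow(Tm) == 0L) { logrho[r, ] <- -Inf; next }
      rho_r <- vapply(seq_along(xs), function(k) {
        sum(apply(Tm, 1, function(es) prod(eff[es, k])))
      }, numeric(1))
      logrho[r, ] <- log(rho_r)
    }
  }
  # vertices with only zero-weight trees (e.g. unreachable closed class at
  # this x) fall far below the leading weight and must come out exactly 0
  mx <- apply(logrho, 2, max)
  if (any(!is.finite(mx)))
    stop("all spanning-tree weights vanished (numeric underflow); ",
         "rescale rates or use log_space = TRUE")
  lZ <- vapply(seq_along(xs), function(k)
    logsumexp(logrho[, k]), numeric(1))
  P <- exp(sweep(logrho, 2, lZ))
  P[logrho - rep(mx, each = n) < -600] <- 0
  P <- sweep(P, 2, colSums(P), "/")
  list(P = P, log_rho = logrho)
}

#' Nonequilibrium steady state by spanning-tree (Matrix-Tree) summation
#'
#' The unnormalized steady-state weight of state i is the sum, over all
#' spanning trees rooted at i (edges directed toward the root), of the
#' product of the tree's edge rates; probabilities follow by
#' normalization.  Valid for any strongly connected graph, at or away from
#' thermodynamic equilibrium.  Tree products are accumulated in log space
#' by default so that widely separated rate scales do not underflow.
#'
#' @inheritParams graph_rates
#' @param log_space accumulate tree products as sums of logs pooled by
#'   log-sum-exp (default); \code{FALSE} uses naive products, which can
#'   underflow for extreme rate ratios.
#' @return a \code{steady_state} with method \code{"spanning_tree"}; its
#'   \code{rho} holds tree weights rescaled by a common factor (their
#'   ratios, which determine the probabilities, are preserved).
#' @export
steady_state_spanning_tree <- function(graph, x, log_space = TRUE) {
  stopifnot(length(x) == 1L)
  sp <- spanning_probs(graph, x, log_space = log_space)
  p <- sp$P[, 1]
  lr <- sp$log_rho[, 1]
  new_steady_state(p, rho = exp(lr - max(lr)), method = "spanning_tree")
}

# ---- oracles --------------------------------------------------------------

#' Independent steady-state oracles (nullspace, ODE)
#'
#' Verification routes that do not share machinery with the production
#' solvers: \code{"nullspace"} extracts the kernel of the master-equation
#' Laplacian by cancellation-free state elimination
#' (Grassmann-Taksar-Heyman), which is accurate to relative machine
#' precision in every component, however small; \code{"ode"} integrates
#' \code{dP/dt = L P} from the uniform distribution until the residual
#' \code{max |dP/dt|} drops below \code{tol}.
#'
#' @inheritParams graph_rates
#' @param method \code{"nullspace"} or \code{"ode"}.
#' @param tol ODE residual threshold; integration continues for one
#'   further decade of time after the residual first drops below it, so
#'   slowly mixing (metastable) graphs are fully relaxed.
#' @param horizon maximum integration time before giving up.
#' @return a \code{steady_state} tagged \code{"nullspace_oracle"} or
#'   \code{"ode_oracle"}.
#' @export
steady_state_oracle <- function(graph, x, method = c("nullspace", "ode"),
                                tol = 1e-13, horizon = 1e9) {
  method <- match.arg(method)
  sc <- is_strongly_connected(graph)
  if (!sc)
    stop("graph is not strongly connected; unreachable: ",
         paste(attr(sc, "unreachable"), collapse = ", "))
  n <- length(graph$vertices)
  if (method == "nullspace") {
    # GTH elimination on the rate matrix: only nonnegative sums and
    # products, so every component carries full relative accuracy
    A <- graph_rates(graph, x)
    for (k in n:2) {
      s <- sum(A[k, seq_len(k - 1)])
      if (s <= 0)
        stop("state ", graph$vertices[k],
             " cannot reach the remaining states; kernel is degenerate")
      A[seq_len(k - 1), k] <- A[seq_len(k - 1), k] / s
      for (i in seq_len(k - 1)) {
        if (A[i, k] > 0) {
          upd <- A[i, seq_len(k - 1)] + A[i, k] * A[k, seq_len(k - 1)]
          upd[i] <- 0
          A[i, seq_len(k - 1)] <- upd
        }
      }
    }
    p <- numeric(n)
    p[1] <- 1
    for (k in 2:n)
      p[k] <- sum(p[seq_len(k - 1)] * A[seq_len(k - 1), k])
    p <- p / sum(p)
    names(p) <- graph$vertices
    return(new_steady_state(p, rho = NULL, method = "nullspace_oracle"))
  }
  L <- laplacian_matrix(graph, x)
  p <- rep(1 / n, n)
  t_end <- 1
  confirmed <- FALSE
  repeat {
    # lsoda may stop early on very stiff graphs; convergence is judged by
    # the residual below, not by the integrator's completion flag
    sol <- suppressWarnings(deSolve::lsoda(
      y = p, times = c(0, t_end),
      func = function(t, y, parms) list(as.vector(L %*% y)),
      rtol = 1e-12, atol = 1e-16, maxsteps = 5e5))
    p <- as.numeric(sol[nrow(sol), -1])
    resid <- max(abs(L %*% p))
    if (resid < tol) {
      # one confirmation decade: a small residual alone can mask a slow
      # metastable mode that is still relaxing
      if (confirmed) break
      confirmed <- TRUE
    } else confirmed <- FALSE
    t_end <- t_end * 10
    if (t_end > horizon)
      stop("ODE oracle did not converge within horizon; residual = ",
           format(resid))
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- graph$vertices
  new_steady_state(p, rho = NULL, method = "ode_oracle")
}
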