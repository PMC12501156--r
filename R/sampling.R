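# Random model generators for the property suites: random state graphs
# (with and without detailed balance) and parameter samplers constrained
# to the coherent regulatory regimes, within biologically plausible
# log-uniform ranges.

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Random strongly connected rate graph
#'
#' A random Hamiltonian cycle (guaranteeing strong connectivity) plus
#' additional random directed edges, with rates drawn log-uniformly.
#' Used to exercise the steady-state solvers across rate scales.
#'
#' @param n_vertices number of states (>= 3).
#' @param extra_edge_prob probability of each additional ordered pair
#'   getting an edge.
#' @param rate_range positive \code{c(lo, hi)} for log-uniform rates.
#' @return a \code{\link{rate_graph}}.
#' @export
random_rate_graph <- function(n_vertices, extra_edge_prob = 0.3,
                              rate_range = c(1e-3, 1e2)) {
  stopifnot(n_vertices >= 3)
  v <- as.character(seq_len(n_vertices))
  ord <- sample(n_vertices)
  from <- v[ord]
  to <- v[c(ord[-1], ord[1])]
  pairs <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  key <- paste(pairs$from, pairs$to)
  used <- key %in% paste(from, to)
  extra <- pairs[!used & stats::runif(nrow(pairs)) < extra_edge_prob, ]
  edges <- data.frame(from = c(from, extra$from), to = c(to, extra$to))
  edges$rate <- runif_log(nrow(edges), rate_range[1], rate_range[2])
  edges$x_coeff <- 0
  rate_graph(v, edges)
}

#' Random reversible graph satisfying the cycle condition
#'
#' Constructed from random vertex potentials: every edge pair's
#' forward/backward ratio equals the potential difference, so every
#' cycle balances exactly (detailed balance by construction).
#'
#' @inheritParams random_rate_graph
#' @param extra_pair_prob probability of each additional vertex pair
#'   being connected (on top of a random spanning tree).
#' @return a \code{\link{rate_graph}} on which
#'   \code{\link{check_cycle_condition}} holds.
#' @export
random_reversible_graph <- function(n_vertices, extra_pair_prob = 0.3,
                                    rate_range = c(1e-3, 1e2)) {
  stopifnot(n_vertices >= 3)
  v <- as.character(seq_len(n_vertices))
  logpot <- stats::runif(n_vertices, -3, 3)
  # random spanning tree: attach each vertex to a random earlier one
  ord <- sample(n_vertices)
  pairs <- cbind(ord[-1],
                 vapply(2:n_vertices, function(i)
                   ord[sample.int(i - 1, 1)], integer(1)))
  all_pairs <- t(utils::combn(n_vertices, 2))
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  extra <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key) &
                       stats::runif(nrow(all_pairs)) < extra_pair_prob, ,
                     drop = FALSE]
  pairs <- rbind(pairs, extra)
  fwd <- runif_log(nrow(pairs), rate_range[1], rate_range[2])
  bwd <- fwd * exp(logpot[pairs[, 1]] - logpot[pairs[, 2]])
  edges <- data.frame(from = v[c(pairs[, 1], pairs[, 2])],
                      to = v[c(pairs[, 2], pairs[, 1])],
                      rate = c(fwd, bwd), x_coeff = 0)
  rate_graph(v, edges)
}

#' Sample equilibrium recruitment parameter sets
#'
#' Log-uniform draws over plausible ranges: KT 1e-4..1e2 1/nM, Kp and
#' the regulatory factors omega, epsilon 1e-2..1e2.
#'
#' @param n number of parameter sets.
#' @return list of \code{\link{eq_recruitment_params}}.
#' @export
sample_eq_recruitment <- function(n) {
  lapply(seq_len(n), function(i)
    eq_recruitment_params(KT = runif_log(1, 1e-4, 1e2),
                          Kp = runif_log(1, 1e-2, 1e2),
                          omega = runif_log(1, 1e-2, 1e2),
                          epsilon = runif_log(1, 1e-2, 1e2),
                          q3 = 1))
}

#' Sample coherent nonequilibrium recruitment parameter sets
#'
#' Coherence constrains every TF effect on Pol to the same side: in the
#' positive mode the TF-Pol cooperativity analogue
#' \code{(aT_p/bT_Tp)/(aT/bT)} and \code{epsilon = q4/q3} both exceed 1,
#' the TF raises the Pol on-rate (\code{ap_T >= ap}) and lowers the Pol
#' off-rate (\code{bp_Tp <= bp}); the negative mode mirrors all four.
#' This excludes incoherence under either published definition (opposed
#' binding/activity effects, or opposed on/off-rate effects).
#'
#' @param n number of parameter sets.
#' @param mode \code{"positive"} or \code{"negative"}.
#' @return list of \code{\link{neq_recruitment_params}}.
#' @export
sample_coherent_recruitment <- function(n, mode = c("positive",
                                                    "negative")) {
  mode <- match.arg(mode)
  lapply(seq_len(n), function(i) {
    aT <- runif_log(1, 1e-4, 1)
    bT <- runif_log(1, 1e-3, 1e2)
    ap <- runif_log(1, 1e-3, 10)
    bp <- runif_log(1, 1e-3, 10)
    fac <- function() runif_log(1, 1, 1e2)   # same-signed effect sizes
    if (mode == "positive") {
      neq_recruitment_params(aT = aT, aT_p = aT * fac(), bT = bT,
                             bT_Tp = bT, ap = ap, ap_T = ap * fac(),
                             bp = bp, bp_Tp = bp / fac(),
                             q3 = 1, q4 = fac())
    } else {
      neq_recruitment_params(aT = aT, aT_p = aT / fac(), bT = bT,
                             bT_Tp = bT, ap = ap, ap_T = ap / fac(),
                             bp = bp, bp_Tp = bp * fac(),
                             q3 = 1, q4 = 1 / fac())
    }
  })
}

#' Sample coherent transcription-cycle parameter sets
#'
#' Positive mode: every non-unit TF effect accelerates the cycle
#' (epsilon 1, 2, 3 >= 1, epsilon 1r <= 1); negative mode mirrors.
#'
#' @inheritParams sample_coherent_recruitment
#' @return list of \code{\link{cycle_params}}.
#' @export
sample_coherent_cycle <- function(n, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  lapply(seq_len(n), function(i) {
    up <- function() runif_log(1, 1, 1e2)
    down <- function() runif_log(1, 1e-2, 1)
    e <- if (mode == "positive") c(up(), down(), up(), up())
         else c(down(), up(), down(), down())
    cycle_params(k1 = runif_log(1, 1e-3, 10), k1r = runif_log(1, 1e-3, 10),
                 k2 = runif_log(1, 1e-3, 10), k3 = runif_log(1, 1e-3, 10),
                 aT = runif_log(1, 1e-4, 1), bT = runif_log(1, 1e-3, 1e2),
                 e1 = e[1], e1r = e[2], e2 = e[3], e3 = e[4])
  })
}

#' Sample coherent occupancy-averaged multisite parameter sets
#'
#' Both modulated rates move the same way with occupancy: positive mode
#' \code{ksat > k0} for k2 and k3, negative mode \code{ksat < k0}.
#'
#' @inheritParams sample_coherent_recruitment
#' @return list with elements \code{k1}, \code{k1r}, \code{mod2},
#'   \code{mod3}, \code{KT} per draw.
#' @export
sample_coherent_multisite <- function(n, mode = c("positive",
                                                  "negative")) {
  mode <- match.arg(mode)
  lapply(seq_len(n), function(i) {
    mk <- function() {
      k0 <- runif_log(1, 1e-3, 10)
      fac <- runif_log(1, 1, 1e2)
      ksat <- if (mode == "positive") k0 * fac else k0 / fac
      modulation_params(k0 = k0, ksat = ksat,
                        s = runif_log(1, 0.1, 5), h = runif_log(1, 0.5, 4))
    }
    list(k1 = runif_log(1, 1e-3, 10), k1r = runif_log(1, 1e-3, 10),
         mod2 = mk(), mod3 = mk(), KT = runif_log(1, 1e-4, 1e2))
  })
}
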