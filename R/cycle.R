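# The 3-state transcription-cycle model: Pol moves irreversibly through
# recruitment (1 -> 2 at k1, reversible with k1r), initiation (2 -> 3 at
# k2) and termination/turnover (3 -> 1 at k3); transcription rate is the
# cycle flux out of state 3.  A TF binds any cycle state (binding aT*x,
# unbinding bT) and, while bound, multiplies cycle rate i by a factor
# epsilon_i > 0.

#' Transcription-cycle model parameters
#'
#' @param k1,k2,k3 clockwise cycle rates (1/time); \code{k2}, \code{k3}
#'   are irreversible.
#' @param k1r reverse of \code{k1} (1/time).
#' @param aT TF binding rate (1/(concentration*time)), identical on all
#'   three cycle states; must be positive so the bound and unbound layers
#'   communicate.
#' @param bT TF unbinding rate (1/time).
#' @param e1,e1r,e2,e3 TF-bound multipliers on the corresponding rate
#'   (default 1 = no effect); >1 accelerates, <1 decelerates.
#' @return object of class \code{cycle_params}.
#' @export
cycle_params <- function(k1, k1r, k2, k3, aT, bT,
                         e1 = 1, e1r = 1, e2 = 1, e3 = 1) {
  p <- list(k1 = k1, k1r = k1r, k2 = k2, k3 = k3, aT = aT, bT = bT,
            e1 = e1, e1r = e1r, e2 = e2, e3 = e3)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("all cycle parameters must be positive scalars")
  structure(p, class = "cycle_params")
}

cycle_vertices <- c("(1,-)", "(2,-)", "(3,-)", "(1,T)", "(2,T)", "(3,T)")

#' Linear-framework graph of the TF-regulated transcription cycle
#'
#' Six vertices \code{(i,-)} / \code{(i,T)} for cycle state i with TF
#' unbound/bound.  The unbound layer carries the bare cycle rates, the
#' bound layer the epsilon-multiplied rates; vertical edges are TF
#' binding (coefficient \code{aT}) and unbinding (\code{bT}).
#'
#' @param p a \code{\link{cycle_params}}.
#' @return a \code{\link{rate_graph}} with 14 edges (8 cycle + 6 binding).
#' @export
build_cycle_graph <- function(p) {
  stopifnot(inherits(p, "cycle_params"))
  edges <- rbind(
    data.frame(from = c("(1,-)", "(2,-)", "(2,-)", "(3,-)"),
               to   = c("(2,-)", "(1,-)", "(3,-)", "(1,-)"),
               rate = c(p$k1, p$k1r, p$k2, p$k3), x_coeff = 0),
    data.frame(from = c("(1,T)", "(2,T)", "(2,T)", "(3,T)"),
               to   = c("(2,T)", "(1,T)", "(3,T)", "(1,T)"),
               rate = c(p$e1 * p$k1, p$e1r * p$k1r,
                        p$e2 * p$k2, p$e3 * p$k3), x_coeff = 0),
    data.frame(from = paste0("(", 1:3, ",-)"),
               to   = paste0("(", 1:3, ",T)"),
               rate = 0, x_coeff = p$aT),
    data.frame(from = paste0("(", 1:3, ",T)"),
               to   = paste0("(", 1:3, ",-)"),
               rate = p$bT, x_coeff = 0))
  rate_graph(cycle_vertices, edges)
}

#' Steady-state transcription rate of the regulated cycle
#'
#' The rate is the probability flux out of cycle state 3 summed over TF
#' layers: \code{k3 P(3,-) + e3 k3 P(3,T)}.  At \code{x = 0} the bound
#' layer empties and the rate reduces to the bare-cycle flux.
#'
#' @inheritParams build_cycle_graph
#' @param x TF concentration(s), vectorized.
#' @return transcription rate(s).
#' @export
cycle_rate <- function(p, x) {
  g <- build_cycle_graph(p)
  sp <- spanning_probs(g, x)
  as.numeric(p$k3 * sp$P["(3,-)", ] + p$e3 * p$k3 * sp$P["(3,T)", ])
}

#' Classify the regulatory mode of a cycle parameter set
#'
#' A TF effect accelerates the cycle when it raises a clockwise rate
#' (\code{e1, e2, e3 > 1}) or lowers the reverse rate (\code{e1r < 1});
#' the mirror effects decelerate it.  Coherent positive: every non-unit
#' epsilon accelerates; coherent negative: every non-unit epsilon
#' decelerates; incoherent: effects conflict; neutral: all unity.
#'
#' @inheritParams build_cycle_graph
#' @return one of \code{"coherent_positive"}, \code{"coherent_negative"},
#'   \code{"incoherent"}, \code{"neutral"}.
#' @export
classify_cycle_mode <- function(p) {
  stopifnot(inherits(p, "cycle_params"))
  up <- c(p$e1 > 1, p$e2 > 1, p$e3 > 1, p$e1r < 1)
  down <- c(p$e1 < 1, p$e2 < 1, p$e3 < 1, p$e1r > 1)
  if (!any(up) && !any(down)) return("neutral")
  if (any(up) && !any(down)) return("coherent_positive")
  if (any(down) && !any(up)) return("coherent_negative")
  "incoherent"
}

#' Net steady-state fluxes around the cycle
#'
#' Layer-summed net fluxes 1->2, 2->3 and 3->1; at steady state all
#' three coincide (what goes around the cycle comes around).
#'
#' @inheritParams cycle_rate
#' @param x scalar TF concentration.
#' @return named numeric vector \code{c(f12, f23, f31)}.
#' @export
cycle_fluxes <- function(p, x) {
  g <- build_cycle_graph(p)
  P <- spanning_probs(g, x)$P[, 1]
  f12 <- p$k1 * P["(1,-)"] - p$k1r * P["(2,-)"] +
    p$e1 * p$k1 * P["(1,T)"] - p$e1r * p$k1r * P["(2,T)"]
  f23 <- p$k2 * P["(2,-)"] + p$e2 * p$k2 * P["(2,T)"]
  f31 <- p$k3 * P["(3,-)"] + p$e3 * p$k3 * P["(3,T)"]
  c(f12 = unname(f12), f23 = unname(f23), f31 = unname(f31))
}
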