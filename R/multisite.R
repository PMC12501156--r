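# Multisite extensions of the transcription cycle.  Two routes:
# (i) occupancy-averaged: TF binding to N equal sites is assumed fast
# enough to equilibrate, and cycle rates respond to the equilibrium mean
# occupancy through a saturable (Hill-type) modulation function;
# (ii) explicit: the binding configuration count is a graph coordinate
# and a state with k sites bound multiplies cycle rate i by k*epsilon_i.

#' Equilibrium mean TF occupancy on N equal independent sites
#'
#' For a single site, \code{a = KT x / (1 + KT x)}; for N equal
#' independent sites the binomial configuration sum gives
#' \code{a = N KT x / (1 + KT x)}.  Computed as the configuration-weighted
#' sum \code{sum_i i C(N,i) (KT x)^i / sum_i C(N,i) (KT x)^i}.
#'
#' @param N number of binding sites (positive integer).
#' @param KT TF affinity constant (1/concentration).
#' @param x TF concentration(s); vectorized.
#' @return mean bound-TF count(s), in \code{[0, N)} for finite x.
#' @export
mean_occupancy <- function(N, KT, x) {
  stopifnot(N >= 1, N == round(N), KT >= 0, all(x >= 0))
  i <- 0:N
  w <- choose(N, i)
  vapply(x, function(xx) {
    t <- (KT * xx)^i
    sum(i * w * t) / sum(w * t)
  }, numeric(1))
}

#' Saturable modulation of a cycle rate by TF occupancy
#'
#' Hill-type interpolation between a basal rate \code{k0} (occupancy 0)
#' and a saturating rate \code{ksat}:
#' \code{k(a) = k0 + (ksat - k0) * a^h / (s^h + a^h)}.  \code{s} is the
#' half-effect occupancy and \code{h} the steepness; \code{ksat > k0}
#' means occupancy accelerates the rate, \code{ksat < k0} decelerates it.
#'
#' @param k0,ksat basal and saturating rates (1/time, positive).
#' @param s half-effect occupancy (positive).
#' @param h Hill steepness (positive, dimensionless).
#' @return object of class \code{modulation_params}.
#' @export
modulation_params <- function(k0, ksat, s, h = 1) {
  p <- list(k0 = k0, ksat = ksat, s = s, h = h)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("modulation parameters must be positive scalars")
  structure(p, class = "modulation_params")
}

#' @rdname modulation_params
#' @param m a \code{modulation_params}.
#' @param a mean occupancy (>= 0); vectorized.
#' @return modulated rate(s), bounded between \code{k0} and \code{ksat}.
#' @export
modulated_rate <- function(m, a) {
  stopifnot(inherits(m, "modulation_params"), all(a >= 0))
  m$k0 + (m$ksat - m$k0) * a^m$h / (m$s^m$h + a^m$h)
}

#' Closed-form steady-state mRNA of the bare 3-state cycle
#'
#' \code{m = k3 k1 k2 / (k2 k3 + k3 k1r + k1 k3 + k1 k2)}, the
#' spanning-tree steady state of the unregulated cycle times the exit
#' rate \code{k3} (mRNA in units of production flux over decay).
#'
#' @param k1,k2,k3 clockwise rates (positive).
#' @param k1r reverse of k1 (>= 0).
#' @return steady-state mRNA level (arbitrary units).
#' @export
cycle_mrna_closed_form <- function(k1, k1r, k2, k3) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0, k1r >= 0)
  k3 * k1 * k2 / (k2 * k3 + k3 * k1r + k1 * k3 + k1 * k2)
}

#' Fold-change response of the occupancy-averaged multisite cycle
#'
#' Chains mean occupancy (at the given N, KT, x) through the saturable
#' modulation of \code{k2} and \code{k3} into the closed-form cycle mRNA,
#' normalized to the basal (zero-occupancy) mRNA:
#' \code{F = m(a) / m(0)}, so \code{F = 1} exactly when \code{a = 0}.
#'
#' @param N site count(s); vectorized (with scalar x) for site-number
#'   response curves.
#' @param KT TF affinity constant (1/concentration).
#' @param x TF concentration(s); vectorized (with scalar N).
#' @param k1,k1r unregulated recruitment rates of the cycle.
#' @param mod2,mod3 \code{\link{modulation_params}} for \code{k2} and
#'   \code{k3}.
#' @return fold change(s), dimensionless and positive.
#' @export
multisite_response <- function(N, KT, x, k1, k1r, mod2, mod3) {
  stopifnot(all(N == round(N)), all(N >= 0))
  if (length(N) > 1L && length(x) > 1L)
    stop("sweep N or x, not both")
  a <- if (length(N) > 1L)
    vapply(N, function(nn)
      if (nn == 0) 0 else mean_occupancy(nn, KT, x), numeric(1))
  else if (N == 0) rep(0, length(x))
  else mean_occupancy(N, KT, x)
  m0 <- cycle_mrna_closed_form(k1, k1r, mod2$k0, mod3$k0)
  ma <- cycle_mrna_closed_form(k1, k1r,
                               modulated_rate(mod2, a),
                               modulated_rate(mod3, a))
  ma / m0
}

#' Multisite-cycle parameters for the explicit-binding graph
#'
#' @param cycle a \code{\link{cycle_params}}.
#' @param N number of equal independent binding sites (1..8).
#' @return object of class \code{multisite_cycle_params}.
#' @export
multisite_cycle_params <- function(cycle, N) {
  stopifnot(inherits(cycle, "cycle_params"), N >= 1, N == round(N))
  if (N > 8) stop("N <= 8 keeps the state count solver-tractable")
  structure(list(cycle = cycle, N = N), class = "multisite_cycle_params")
}

#' Linear-framework graph of the explicit multisite cycle
#'
#' Vertices are (cycle state i, k sites bound), k in 0..N.  Binding
#' k -> k+1 proceeds at \code{(N-k) aT x}, unbinding k+1 -> k at
#' \code{(k+1) bT} (independent equal sites).  With k >= 1 sites bound,
#' cycle rate i is multiplied by \code{k * epsilon_i}; with k = 0 the
#' bare rates apply.  At N = 1 this reduces exactly to
#' \code{\link{build_cycle_graph}}.
#'
#' @param p a \code{\link{multisite_cycle_params}}.
#' @return a \code{\link{rate_graph}} with \code{3(N+1)} vertices.
#' @export
build_multisite_cycle_graph <- function(p) {
  stopifnot(inherits(p, "multisite_cycle_params"))
  cp <- p$cycle
  N <- p$N
  vname <- function(i, k) paste0("(", i, ",", k, ")")
  verts <- as.vector(outer(1:3, 0:N, vname))
  # k bound sites multiply a REGULATED rate (epsilon != 1) by k*epsilon;
  # unregulated rates (epsilon = 1) are untouched at every occupancy
  mult <- function(k, e) if (k == 0 || e == 1) 1 else k * e
  rows <- list()
  for (k in 0:N) {
    rows[[length(rows) + 1L]] <- data.frame(
      from = vname(c(1, 2, 2, 3), k), to = vname(c(2, 1, 3, 1), k),
      rate = c(mult(k, cp$e1) * cp$k1, mult(k, cp$e1r) * cp$k1r,
               mult(k, cp$e2) * cp$k2, mult(k, cp$e3) * cp$k3),
      x_coeff = 0)
  }
  for (k in 0:(N - 1)) {
    rows[[length(rows) + 1L]] <- data.frame(
      from = vname(1:3, k), to = vname(1:3, k + 1),
      rate = 0, x_coeff = (N - k) * cp$aT)
    rows[[length(rows) + 1L]] <- data.frame(
      from = vname(1:3, k + 1), to = vname(1:3, k),
      rate = (k + 1) * cp$bT, x_coeff = 0)
  }
  rate_graph(verts, do.call(rbind, rows))
}

#' Steady-state transcription rate of the explicit multisite cycle
#'
#' Flux out of cycle state 3 summed over binding levels, with the
#' k-bound layer contributing at \code{mult(k, e3) * k3}.
#'
#' @inheritParams build_multisite_cycle_graph
#' @param x TF concentration(s), vectorized.
#' @return transcription rate(s).
#' @export
multisite_cycle_rate <- function(p, x) {
  g <- build_multisite_cycle_graph(p)
  sp <- spanning_probs(g, x)
  cp <- p$cycle
  k <- 0:p$N
  w <- ifelse(k == 0 | cp$e3 == 1, 1, k * cp$e3) * cp$k3
  rows <- paste0("(3,", k, ")")
  as.numeric(w %*% sp$P[rows, , drop = FALSE])
}
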