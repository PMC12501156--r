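# The 4-state regulated-recruitment model: a TF and RNA polymerase (Pol)
# bind a regulatory sequence; the TF modulates Pol recruitment (binding
# kinetics) and Pol activity once bound (the transcription rate from the
# Pol-bound states).  States: 1 empty, 2 TF bound, 3 Pol bound, 4 both.

#' Equilibrium recruitment-model parameters
#'
#' Parameterization of the 4-state model at thermodynamic equilibrium:
#' only rate ratios matter.  \code{KT} (1/concentration) is the TF-DNA
#' affinity constant, \code{Kp} (dimensionless, Pol concentration
#' absorbed) the Pol affinity, \code{omega} the TF-Pol binding
#' cooperativity (>1: TF favors Pol recruitment), \code{epsilon} the
#' factor change of the basal transcription rate \code{q3} when TF is
#' bound (>1: TF enhances Pol activity).
#'
#' @param KT,Kp,omega,epsilon,q3 strictly positive numerics.
#' @return object of class \code{eq_recruitment_params}.
#' @export
eq_recruitment_params <- function(KT, Kp, omega, epsilon, q3 = 1) {
  p <- list(KT = KT, Kp = Kp, omega = omega, epsilon = epsilon, q3 = q3)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("all equilibrium recruitment parameters must be positive scalars")
  structure(p, class = "eq_recruitment_params")
}

#' Steady-state transcription rate of the equilibrium recruitment model
#'
#' Closed form
#' \deqn{r(x) = q_3 (K_p + \epsilon K_p K_T \omega x) /
#'              (1 + K_T x + K_p + K_p K_T \omega x)}
#' obtained by summing the transcription weights of the two Pol-bound
#' states over the equilibrium occupancy distribution.
#'
#' @param p an \code{\link{eq_recruitment_params}}.
#' @param x TF concentration(s), \code{>= 0}; vectorized.
#' @return transcription rate(s), transcripts/time.
#' @export
recruitment_rate_equilibrium <- function(p, x) {
  stopifnot(inherits(p, "eq_recruitment_params"), all(x >= 0))
  with(p, q3 * (Kp + epsilon * Kp * KT * omega * x) /
            (1 + KT * x + Kp + Kp * KT * omega * x))
}

#' Direction of the equilibrium dose response
#'
#' The sign of dr/dx for the equilibrium 4-state model is independent of
#' x and equals the sign of \code{Kp*omega*(epsilon - 1) + epsilon*omega - 1}:
#' the response is monotonically increasing (+1), decreasing (-1), or
#' flat (0) over the whole concentration axis.  Nonmonotonicity is
#' impossible at equilibrium from a single site.
#'
#' @inheritParams recruitment_rate_equilibrium
#' @return -1, 0 or +1.
#' @export
direction_sign_equilibrium <- function(p) {
  stopifnot(inherits(p, "eq_recruitment_params"))
  sign(with(p, Kp * omega * (epsilon - 1) + epsilon * omega - 1))
}

#' Regulatory mode of an equilibrium recruitment parameter set
#'
#' Coherent positive: the TF enhances both Pol recruitment and activity
#' (\code{omega > 1, epsilon > 1}); coherent negative: hinders both;
#' incoherent: one up, one down; neutral when either parameter sits on
#' the boundary 1.
#'
#' @inheritParams recruitment_rate_equilibrium
#' @return one of \code{"coherent_positive"}, \code{"coherent_negative"},
#'   \code{"incoherent"}, \code{"neutral"}.
#' @export
regulatory_mode <- function(p) {
  stopifnot(inherits(p, "eq_recruitment_params"))
  if (p$omega == 1 || p$epsilon == 1) return("neutral")
  if (p$omega > 1 && p$epsilon > 1) return("coherent_positive")
  if (p$omega < 1 && p$epsilon < 1) return("coherent_negative")
  "incoherent"
}

#' General (nonequilibrium) recruitment-model parameters
#'
#' Full kinetic parameterization of the 4-state model.  TF binding rates
#' \code{aT} (to the empty state) and \code{aT_p} (to the Pol-bound
#' state) are in 1/(concentration*time); TF unbinding \code{bT},
#' \code{bT_Tp} in 1/time; Pol binding \code{ap}, \code{ap_T} in 1/time
#' (Pol concentration absorbed); Pol unbinding \code{bp}, \code{bp_Tp}
#' in 1/time.  \code{q3} and \code{q4 = epsilon*q3} are the transcription
#' rates with Pol bound alone or together with the TF.  When the
#' Kolmogorov cycle condition fails the model settles into a
#' nonequilibrium steady state.
#'
#' @param aT,aT_p,bT,bT_Tp,ap,ap_T,bp,bp_Tp,q3,q4 strictly positive.
#' @return object of class \code{neq_recruitment_params}.
#' @export
neq_recruitment_params <- function(aT, aT_p, bT, bT_Tp, ap, ap_T,
                                   bp, bp_Tp, q3 = 1, q4 = 1) {
  p <- list(aT = aT, aT_p = aT_p, bT = bT, bT_Tp = bT_Tp,
            ap = ap, ap_T = ap_T, bp = bp, bp_Tp = bp_Tp,
            q3 = q3, q4 = q4)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("all recruitment rates must be positive scalars")
  structure(p, class = "neq_recruitment_params")
}

#' Linear-framework graph of the 4-state recruitment model
#'
#' Vertices "1" (empty), "2" (TF), "3" (Pol), "4" (TF+Pol).  TF-binding
#' edges carry the concentration coefficient; all other edges are
#' constant.  Transcription weights: \code{q3} on state 3, \code{q4} on
#' state 4.
#'
#' @param p a \code{\link{neq_recruitment_params}}.
#' @return a \code{\link{rate_graph}} with 8 edges.
#' @export
build_recruitment_graph <- function(p) {
  stopifnot(inherits(p, "neq_recruitment_params"))
  edges <- data.frame(
    from    = c("1", "2", "3", "4", "1", "3", "2", "4"),
    to      = c("2", "1", "4", "3", "3", "1", "4", "2"),
    rate    = c(0, p$bT, 0, p$bT_Tp, p$ap, p$bp, p$ap_T, p$bp_Tp),
    x_coeff = c(p$aT, 0, p$aT_p, 0, 0, 0, 0, 0))
  rate_graph(c("1", "2", "3", "4"), edges, q = c("3" = p$q3, "4" = p$q4))
}

#' Map kinetic recruitment parameters onto the equilibrium parameterization
#'
#' \code{KT = aT/bT}, \code{Kp = ap/bp},
#' \code{omega = (aT_p/bT_Tp)/(aT/bT)}, \code{epsilon = q4/q3}.  The
#' closed-form equilibrium rate is valid only when the cycle condition
#' holds for the kinetic rates.
#'
#' @inheritParams build_recruitment_graph
#' @return an \code{\link{eq_recruitment_params}}.
#' @export
as_equilibrium_params <- function(p) {
  stopifnot(inherits(p, "neq_recruitment_params"))
  eq_recruitment_params(KT = p$aT / p$bT, Kp = p$ap / p$bp,
                        omega = (p$aT_p / p$bT_Tp) / (p$aT / p$bT),
                        epsilon = p$q4 / p$q3, q3 = p$q3)
}

#' Steady-state transcription rate of the kinetic recruitment model
#'
#' \code{r(x) = q3 P3(x) + q4 P4(x)} with the steady-state occupancies
#' from the spanning-tree solver, valid at or away from equilibrium.
#'
#' @inheritParams build_recruitment_graph
#' @param x TF concentration(s), vectorized.
#' @return transcription rate(s).
#' @export
recruitment_rate <- function(p, x) {
  g <- build_recruitment_graph(p)
  sp <- spanning_probs(g, x)
  as.numeric(g$q %*% sp$P)
}
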