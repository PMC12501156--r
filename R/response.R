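# Fold-change curves, monotonicity classification, regime maps, and
# log-uniform parameter sampling for the model sweeps.

#' Classify the monotonicity of a fold-change sequence
#'
#' Works on log fold change so the verdict is invariant to monotone
#' rescaling.  Successive differences with \code{|dlogF| <= rtol} are
#' treated as zero.  Classes: \code{"flat"} (all differences zero),
#' \code{"increasing"} / \code{"decreasing"} (all nonzero differences of
#' one sign), \code{"nonmonotonic"} otherwise.  A single sign change
#' from + to - additionally records the peak position.
#'
#' @param F positive fold-change values on an ordered input grid
#'   (>= 3 points).
#' @param rtol tolerance on log-fold-change differences.
#' @param inputs optional grid values; when given, a rise-then-fall
#'   curve's peak is reported in input units (else as an index).
#' @return character class with attribute \code{"peak_input"} (NA unless
#'   nonmonotonic with a single +/- sign change).
#' @export
classify_monotonicity <- function(F, rtol = 1e-6, inputs = NULL) {
  if (length(F) < 3L) stop("need at least 3 grid points to classify")
  if (any(F <= 0)) stop("fold changes must be positive")
  d <- diff(log(F))
  s <- sign(d)
  s[abs(d) <= rtol] <- 0
  nz <- s[s != 0]
  peak <- NA_real_
  cls <- if (!length(nz)) "flat"
  else if (all(nz > 0)) "increasing"
  else if (all(nz < 0)) "decreasing"
  else "nonmonotonic"
  if (cls == "nonmonotonic") {
    r <- rle(nz)
    if (length(r$values) == 2L && r$values[1] == 1) {
      idx <- which.max(log(F))
      peak <- if (is.null(inputs)) idx else inputs[idx]
    }
  }
  structure(cls, peak_input = peak)
}

#' Fold-change response curve of a model over an input grid
#'
#' \code{F(u) = r(u) / r(u0)} with \code{u0} the declared basal input
#' (TF concentration 0, or site count 0 for site-number sweeps).  The
#' evaluator must accept a vector of inputs and return strictly positive
#' rates.
#'
#' @param rate_fn vectorized evaluator, input values -> rates.
#' @param inputs strictly ordered input grid (>= 3 points).
#' @param basal basal input value at which \code{F = 1} (default 0).
#' @param input_name label for the swept input.
#' @param rtol classification tolerance, see
#'   \code{\link{classify_monotonicity}}.
#' @return object of class \code{response_curve}: list with
#'   \code{input_name}, \code{inputs}, \code{F}, \code{class},
#'   \code{peak_input}.
#' @export
fold_change_curve <- function(rate_fn, inputs, basal = 0,
                              input_name = "x", rtol = 1e-6) {
  stopifnot(length(inputs) >= 3L, !is.unsorted(inputs, strictly = TRUE))
  r <- rate_fn(inputs)
  r0 <- rate_fn(basal)
  if (any(!is.finite(r)) || any(r <= 0) || r0 <= 0)
    stop("evaluator returned nonpositive or nonfinite rates")
  F <- r / r0
  cls <- classify_monotonicity(F, rtol = rtol, inputs = inputs)
  structure(list(input_name = input_name, inputs = inputs, F = F,
                 class = as.character(cls),
                 peak_input = attr(cls, "peak_input")),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("response_curve over ", x$input_name, " [",
      format(min(x$inputs)), ", ", format(max(x$inputs)), "], ",
      length(x$inputs), " points: ", x$class, sep = "")
  if (!is.na(x$peak_input))
    cat(" (peak at ", x$input_name, " = ", format(x$peak_input), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Regime map: monotonicity class across a 2D parameter sweep
#'
#' For each value of the outer axis (e.g. the TF unbinding rate bT, or
#' the affinity KT), the fold-change curve over the inner axis (TF
#' concentration x, or site number N) is computed and classified.  This
#' reproduces the structure of the model colormaps: bands of increasing,
#' nonmonotonic and decreasing response.
#'
#' @param curve_fn function(outer_value) returning a vectorized rate
#'   evaluator over the inner axis.
#' @param outer_values,inner_values grids (inner >= 3 points).
#' @param basal basal inner input (default 0).
#' @param outer_name,inner_name axis labels.
#' @param rtol classification tolerance.
#' @return object of class \code{regime_map}: data frame-backed list with
#'   per-outer-value \code{class} and \code{peak_input}, plus the full
#'   fold-change matrix \code{F_grid} (outer x inner).
#' @export
regime_map <- function(curve_fn, outer_values, inner_values, basal = 0,
                       outer_name = "outer", inner_name = "x",
                       rtol = 1e-6) {
  stopifnot(length(inner_values) >= 3L)
  rows <- lapply(outer_values, function(ov) {
    fold_change_curve(curve_fn(ov), inner_values, basal = basal,
                      input_name = inner_name, rtol = rtol)
  })
  structure(list(
    outer_name = outer_name, inner_name = inner_name,
    outer_values = outer_values, inner_values = inner_values,
    classes = vapply(rows, function(r) r$class, character(1)),
    peak_inputs = vapply(rows, function(r) r$peak_input, numeric(1)),
    F_grid = do.call(rbind, lapply(rows, function(r) r$F))),
    class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat("regime_map: ", x$outer_name, " (", length(x$outer_values),
      ") x ", x$inner_name, " (", length(x$inner_values), ")\n", sep = "")
  print(table(x$classes))
  invisible(x)
}

#' @export
as.data.frame.regime_map <- function(x, ...) {
  data.frame(outer = x$outer_values, class = x$classes,
              peak_input = x$peak_inputs)
}

#' Log-spaced grid helper
#'
#' @param lo,hi positive endpoints.
#' @param n number of points.
#' @return n log-spaced values from lo to hi.
#' @export
log_grid <- function(lo, hi, n = 50) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Biologically plausible parameter ranges for the models
#'
#' Log-uniform sampling ranges bracketing the reference parameter sets by
#' roughly two orders of magnitude: TF binding 1e-4..1 1/(nM s),
#' unbinding 1e-3..1e2 1/s, cycle/Pol rates 1e-3..10 1/s, regulatory
#' factors 1e-2..1e2.
#'
#' @return named list of \code{c(lo, hi)} ranges.
#' @export
default_parameter_ranges <- function() {
  list(binding = c(1e-4, 1), unbinding = c(1e-3, 1e2),
       rate = c(1e-3, 10), factor = c(1e-2, 1e2))
}

#' Sample parameter sets log-uniformly
#'
#' @param ranges named list of positive \code{c(lo, hi)} ranges, one per
#'   parameter.
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return data frame with one column per parameter, n rows.
#' @export
sample_parameters <- function(ranges, n, seed = NULL) {
  stopifnot(n >= 0)
  ok <- vapply(ranges, function(r)
    length(r) == 2L && all(r > 0) && r[2] >= r[1], logical(1))
  if (!all(ok)) stop("ranges must be positive c(lo, hi) pairs")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(ranges, function(r)
    exp(stats::runif(n, log(r[1]), log(r[2]))))
  as.data.frame(out)
}
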