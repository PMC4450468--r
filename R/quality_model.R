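# Probability-phred model: the probability that a base call is "informative"
# as a function of its phred score q and a user threshold t.

#' Probability that a base call is correct
#'
#' The classical phred relation: a phred score `q` encodes a base-calling
#' error probability of `10^(-q/10)`, so the probability that the call is
#' correct is `1 - 10^(-q/10)` (0.99 at q = 20).
#'
#' @param q Integer (or numeric) phred score(s), `q >= 0`.
#' @return Probability in `[0, 1)`, vectorized over `q`.
#' @seealso [prob_informative()] for the threshold-shifted model used for
#'   trimming.
#' @export
#' @examples
#' prob_correct(20) # 0.99
prob_correct <- function(q) {
  if (any(q < 0)) stop("negative phred score: check the quality offset", call. = FALSE)
  1 - 10^(-q / 10)
}

#' Shifted probability that a base call is informative
#'
#' `1 - 2^(-q/t)`, where `t` is the minimal phred score considered
#' informative.  The shift places probability 0.5 exactly at `q = t`, so a
#' call is informative precisely when its probability exceeds one half.
#' At `t = 10 * log10(2) ~= 3.0103` this reduces to [prob_correct()].
#'
#' @param q Phred score(s), `q >= 0`.
#' @param t Threshold, `t > 0`.
#' @return Probability in `[0, 1)`, vectorized over `q`.
#' @export
#' @examples
#' prob_informative_raw(40, 20) # 0.75
#' prob_informative_raw(20, 20) # 0.5
prob_informative_raw <- function(q, t) {
  if (t <= 0) stop("threshold t must be > 0", call. = FALSE)
  if (any(q < 0)) stop("negative phred score: check the quality offset", call. = FALSE)
  1 - 2^(-q / t)
}

#' Tangent to the shifted probability function
#'
#' Returns the affine function of q tangent to `1 - 2^(-q/t)` at `q0`
#' (normally `q0 = max(20, t)`, the point where the spline branch of
#' [prob_informative()] takes over).  Used to place the second Bezier
#' control point.
#'
#' @param q0 Abscissa of tangency.
#' @param t Threshold, `t > 0`.
#' @return A function of `q` evaluating the tangent line.
#' @export
tangent_line <- function(q0, t) {
  if (t <= 0) stop("threshold t must be > 0", call. = FALSE)
  f0 <- 1 - 2^(-q0 / t)
  slope <- (log(2) / t) * 2^(-q0 / t)
  function(q) f0 + slope * (q - q0)
}

#' Cubic Bezier polynomial
#'
#' Bernstein form of the cubic Bezier curve through control values
#' `p1..p4`: starts at `p1` toward `p2`, arrives at `p4` from the direction
#' of `p3`.
#'
#' @param u Curve parameter(s) in `[0, 1]`.
#' @param p1,p2,p3,p4 Control values.
#' @return `(1-u)^3 p1 + 3 (1-u)^2 u p2 + 3 (1-u) u^2 p3 + u^3 p4`.
#' @export
bezier_cubic <- function(u, p1, p2, p3, p4) {
  if (any(u < -1e-12) || any(u > 1 + 1e-12)) {
    stop("Bezier parameter u outside [0, 1]: scaling bug", call. = FALSE)
  }
  u <- pmin(pmax(u, 0), 1)
  v <- 1 - u
  v^3 * p1 + 3 * v^2 * u * p2 + 3 * v * u^2 * p3 + u^3 * p4
}

#' Probability that a base call is informative (full spline)
#'
#' The piecewise probability-phred curve used throughout trimming: the
#' shifted function `1 - 2^(-q/t)` up to `q = max(20, t)`, then a cubic
#' Bezier spline that rises to exactly 1 at phred 45 (and stays 1 beyond).
#' The spline starts at the value of the shifted function at the switch
#' point, its second control point lies on the tangent there (one third of
#' the way to 45), and it arrives flat at (45, 1); the curve is continuous
#' and non-decreasing in q.
#'
#' @param q Phred score(s), `q >= 0`.
#' @param t Threshold, `t > 0` (practical range 1-45).
#' @param scaling Bezier parameterization of the spline branch.
#'   `"continuous"` (default) maps `[max(20,t), 45]` onto `[0, 1]`, which
#'   keeps the curve continuous at the branch switch for every t.
#'   `"literal"` maps `[t, 45]` instead (clipped to `[0, 1]`), retained for
#'   comparison; for t < 20 it introduces a jump at the switch.
#' @return Probability in `[0, 1]`, vectorized over `q`.
#' @export
#' @examples
#' prob_informative(45, 20) # 1
#' prob_informative(20, 20) # 0.5
prob_informative <- function(q, t, scaling = c("continuous", "literal")) {
  scaling <- match.arg(scaling)
  if (t <= 0) stop("threshold t must be > 0", call. = FALSE)
  if (any(q < 0)) stop("negative phred score: check the quality offset", call. = FALSE)
  q0 <- max(20, t)
  p <- numeric(length(q))
  low <- q <= q0
  hi <- !low & q >= 45
  mid <- !low & !hi
  p[low] <- prob_informative_raw(q[low], t)
  p[hi] <- 1
  if (any(mid)) {
    p1 <- prob_informative_raw(q0, t)
    # cap the tangent control point at 1: for very small t the tangent at
    # the switch point exceeds 1 and would push the spline above 1; with
    # p1 <= p2 <= p3 = p4 = 1 the control polygon is monotone, so the
    # curve is a monotone probability
    p2 <- min(tangent_line(q0, t)(q0 + (45 - q0) / 3), 1)
    u <- switch(scaling,
      continuous = (q[mid] - q0) / (45 - q0),
      literal = pmin(pmax((q[mid] - t) / (45 - t), 0), 1)
    )
    p[mid] <- bezier_cubic(u, p1, p2, 1, 1)
  }
  p
}

#' Materialize the probability-phred curve as a lookup table
#'
#' Evaluates [prob_informative()] at every integer phred score in `[0, 93]`
#' (the printable-ASCII-encodable range) for a fixed threshold, so the
#' segmentation scan can use O(1) lookups.
#'
#' @param t Threshold, `t > 0`.
#' @param scaling Passed to [prob_informative()].
#' @return An object of class `"phred_curve"`: list with elements `t`,
#'   `q` (0:93) and `p` (probabilities).
#' @export
#' @examples
#' curve <- build_curve(20)
#' curve_prob(curve, c(20, 45)) # 0.5, 1
build_curve <- function(t, scaling = c("continuous", "literal")) {
  scaling <- match.arg(scaling)
  q <- 0:93
  structure(
    list(t = t, q = q, p = prob_informative(q, t, scaling = scaling)),
    class = "phred_curve"
  )
}

#' Look up p(q, t) in a materialized curve
#'
#' @param curve A `"phred_curve"` from [build_curve()].
#' @param q Integer phred score(s) in `[0, 93]`.
#' @return Probabilities, vectorized over `q`.
#' @export
curve_prob <- function(curve, q) {
  stopifnot(inherits(curve, "phred_curve"))
  if (any(q < 0 | q > 93)) stop("phred score outside [0, 93]", call. = FALSE)
  curve$p[q + 1L]
}

#' @export
print.phred_curve <- function(x, ...) {
  cat(sprintf(
    "Probability-phred curve (threshold t = %g)\n  p(0) = %g, p(%g) = %g, p(45..93) = %g\n",
    x$t, x$p[1], x$t, curve_prob(x, round(min(x$t, 93))), x$p[46]
  ))
  invisible(x)
}

#' @export
plot.phred_curve <- function(x, ...) {
  graphics::plot(x$q, x$p,
    type = "l", xlab = "phred score q",
    ylab = "p(q, t)", main = sprintf("t = %g", x$t), ylim = c(0, 1), ...
  )
  graphics::abline(h = 0.5, v = x$t, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.phred_curve <- function(x, ...) {
  data.frame(q = x$q, p = x$p)
}

#' Tabulate the probability-phred curve
#'
#' Convenience wrapper returning the 94-row (q, p) table for a threshold,
#' e.g. for plotting or for the `curve` CLI subcommand.
#'
#' @inheritParams build_curve
#' @return A data.frame with columns `q` and `p`.
#' @export
curve_table <- function(t) {
  as.data.frame(build_curve(t))
}
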