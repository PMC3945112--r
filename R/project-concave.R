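#' Project a vector onto the cone of concave sequences
#'
#' Computes the (optionally weighted) Euclidean projection of `v` onto
#' \eqn{\{u : u_{j+1} - 2 u_j + u_{j-1} \le 0\}} — the classical concave
#' (least-squares) regression problem. Solved exactly through the dual
#' nonnegative least-squares problem with an active-set iteration whose
#' passive-set systems are pentadiagonal, giving near-linear cost per
#' active-set change. Concave inputs are fixed points.
#'
#' @param v numeric vector to project (finite).
#' @param weights optional positive weights for the weighted norm
#'   \eqn{\sum_j w_j (u_j - v_j)^2}; default uniform.
#' @param tol feasibility tolerance on second differences of the result.
#' @param warmStart optional dual multipliers (`length(v) - 2`) from a
#'   previous projection of a nearby vector; used internally by
#'   [fitLogConcave()] to make repeated projections cheap.
#' @return the projected vector, with the dual multipliers attached as
#'   attribute `"mu"` and the realized feasibility as `"maxViolation"`.
#' @examples
#' projectConcave(c(0, -2, 0)) # -> rep(-2/3, 3)
#' @export
projectConcave <- function(v, weights = NULL, tol = 1e-10, warmStart = NULL) {
  stopifnot2(all(is.finite(v)), "v must be finite")
  n <- length(v)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot2(length(weights) == n && all(weights > 0),
             "weights must be positive and match length(v)")
  if (is.null(warmStart)) warmStart <- numeric(0)
  scale <- max(1, max(abs(v)))
  res <- .concaveProjectCpp(as.numeric(v), as.numeric(weights),
                            tol * scale, 0L, as.numeric(warmStart))
  if (!res$converged)
    warning("concave projection did not reach tolerance (max violation ",
            format(res$maxViolation), ")")
  out <- res$u
  attr(out, "mu") <- res$mu
  attr(out, "maxViolation") <- res$maxViolation
  out
}
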