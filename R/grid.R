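#' Shannon channel grid
#'
#' Indexes the Shannon channels \eqn{q_n = n\pi/D} of a particle with maximum
#' dimension \eqn{D}, given the largest momentum transfer \eqn{q_{max}}
#' reached by the experiment. The number of channels supported by the data is
#' \eqn{n_{max} = \lfloor q_{max} D / \pi \rfloor}; when \code{extend} is
#' \code{TRUE} the grid carries coefficients up to \eqn{3 n_{max}} so that
#' channels beyond the measured range can float during a regularized fit
#' instead of being implicitly pinned at zero.
#'
#' @param D maximum particle dimension, in the length unit reciprocal to the
#'   q unit of the data (Angstrom for q in 1/Angstrom).
#' @param q_max largest experimental momentum transfer (reciprocal length).
#' @param extend logical; carry \eqn{3 n_{max}} channels instead of
#'   \eqn{n_{max}}.
#' @return an object of class \code{"shannon_grid"}: a list with elements
#'   \code{D}, \code{q_max}, \code{n_max}, \code{n_total} and \code{q_n}
#'   (channel positions \eqn{n\pi/D} for \eqn{n = 1 \ldots n_{total}}).
#' @examples
#' g <- shannon_grid(D = 50, q_max = 8 * pi / 50)
#' g$n_max      # 8
#' g$q_n[1:3]
#' @export
shannon_grid <- function(D, q_max, extend = TRUE) {
  if (!is.finite(D) || D <= 0) stop("D must be a positive finite length")
  if (!is.finite(q_max) || q_max <= 0) stop("q_max must be positive and finite")
  n_max <- n_shannon(q_max, D)
  if (n_max < 1)
    stop("q_max * D / pi < 1: no Shannon channel fits in the data range; ",
         "increase D or q_max")
  n_total <- if (extend) 3L * n_max else n_max
  structure(
    list(D = D, q_max = q_max, n_max = n_max, n_total = n_total,
         q_n = seq_len(n_total) * pi / D, extend = extend),
    class = "shannon_grid")
}

# floor(q_max * D / pi) with a relative tolerance so that exact channel
# multiples (e.g. q_max = 8*pi/50 with D = 50) are not lost to rounding
n_shannon <- function(q_max, D) {
  as.integer(floor(q_max * D / pi * (1 + 1e-12) + 1e-12))
}

#' @export
print.shannon_grid <- function(x, ...) {
  cat("Shannon grid: D =", format(x$D), " q_max =", format(x$q_max),
      "\n  n_max =", x$n_max, " n_total =", x$n_total,
      if (x$extend) "(extension x3 enabled)" else "", "\n")
  invisible(x)
}
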