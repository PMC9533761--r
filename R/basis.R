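#' Reciprocal-space Shannon basis function B_n(q)
#'
#' The cardinal-series basis of the Shannon-channel parameterization: a
#' band-limited intensity of a particle with maximum dimension \eqn{D} is
#' \eqn{I(q) = \sum_n I_n B_n(q)} where \eqn{I_n = I(n\pi/D)}. In terms of
#' the reduced variable \eqn{x = qD/\pi},
#' \deqn{B_n(q) = (-1)^{n+1} \frac{2 n^2}{n^2 - x^2}\,
#'       \frac{\sin(\pi x)}{\pi x}.}
#' \eqn{B_n} is 1 at its own channel, 0 at every other channel, and
#' \eqn{2(-1)^{n+1}} at \eqn{q = 0}. The removable singularities at
#' \eqn{x = n} and \eqn{x = 0} are handled exactly: for \eqn{q > 0} the
#' algebraically equivalent form
#' \eqn{B_n = 2n^2\,\mathrm{sinc}(x - n) / [x (x + n)]} (with
#' \eqn{\mathrm{sinc}(t) = \sin(\pi t)/(\pi t)}) is free of cancellation
#' everywhere, and \eqn{q = 0} is an explicit limit branch.
#'
#' @param n channel index (scalar integer, >= 1).
#' @param q momentum transfer values (vector, >= 0, reciprocal length).
#' @param D maximum particle dimension (length).
#' @return vector of dimensionless weights, one per element of \code{q}.
#' @examples
#' D <- 50
#' shannon_basis_q(3, 3 * pi / D, D)  # 1 at its own channel
#' shannon_basis_q(3, 0, D)           # 2 * (-1)^(3+1) = 2
#' @export
shannon_basis_q <- function(n, q, D) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  if (!is.finite(D) || D <= 0) stop("D must be a positive finite length")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  x <- q * D / pi
  out <- numeric(length(x))
  # two algebraically equivalent forms, each exact where the other loses
  # precision: near x = 0 the sinc(x) form (denominator n^2 - x^2 is safe);
  # for x >= 1/2 the sinc(x - n) form, where x - n is computed exactly near
  # x = n and the removable singularity disappears
  lo <- x < 0.5
  if (any(lo))
    out[lo] <- (-1)^(n + 1) * 2 * n^2 * sincpi(x[lo]) / (n^2 - x[lo]^2)
  if (any(!lo)) {
    xs <- x[!lo]
    out[!lo] <- 2 * n^2 * sincpi(xs - n) / (xs * (xs + n))
  }
  out
}

# sin(pi t)/(pi t), exact at t = 0, series near it
sincpi <- function(t) {
  out <- numeric(length(t))
  small <- abs(t) < 1e-6
  out[small] <- 1 - (pi * t[small])^2 / 6
  out[!small] <- sinpi(t[!small]) / (pi * t[!small])
  out
}

#' Real-space Shannon basis function S_n(r)
#'
#' The real-space mate of \code{\link{shannon_basis_q}}: the pair
#' distribution function of the particle is
#' \eqn{P(r) = \sum_n I_n S_n(r)} on \eqn{[0, D]} with
#' \deqn{S_n(r) = \frac{n\,r}{2 D^2} \sin\!\left(\frac{n \pi r}{D}\right),}
#' so that \eqn{4\pi \int_0^D P(r)\,\mathrm{sinc}(qr)\,dr} reproduces
#' \eqn{\sum_n I_n B_n(q)} (the two curves are Fourier mates). Every
#' \eqn{S_n} vanishes at both ends of the support, which builds
#' \eqn{P(0) = P(D) = 0} into the representation.
#'
#' @param n channel index (scalar integer, >= 1).
#' @param r real-space distances (vector, within \code{[0, D]}).
#' @param D maximum particle dimension (length).
#' @return vector of weights with units 1/length.
#' @export
shannon_basis_r <- function(n, r, D) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  if (!is.finite(D) || D <= 0) stop("D must be a positive finite length")
  if (any(!is.finite(r)) || any(r < -1e-12 * D) || any(r > D * (1 + 1e-12)))
    stop("r must lie within [0, D]")
  n * r / (2 * D^2) * sinpi(n * r / D)
}

# n_points x n_total matrix of B_n(q_i)
basis_matrix_q <- function(q, grid) {
  m <- vapply(seq_len(grid$n_total),
              function(n) shannon_basis_q(n, q, grid$D),
              numeric(length(q)))
  matrix(m, nrow = length(q), ncol = grid$n_total)
}

# n_points x n_total matrix of S_n(r_i)
basis_matrix_r <- function(r, grid) {
  m <- vapply(seq_len(grid$n_total),
              function(n) shannon_basis_r(n, r, grid$D),
              numeric(length(r)))
  matrix(m, nrow = length(r), ncol = grid$n_total)
}
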