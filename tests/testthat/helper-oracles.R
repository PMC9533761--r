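# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own evaluation paths: direct textbook formulas and
# plain quadrature only.

# direct evaluation of the reciprocal basis away from its singular points
oracle_bn_direct <- function(n, q, D) {
  x <- q * D / pi
  (-1)^(n + 1) * 2 * n^2 * sin(pi * x) / (pi * x) / (n^2 - x^2)
}

# direct evaluation of the real-space basis
oracle_sn_direct <- function(n, r, D) {
  n * r / (2 * D^2) * sin(n * pi * r / D)
}

# trapezoid Fourier transform of a P(r) curve: 4*pi * int P(r) sinc(q r) dr
oracle_pr_to_iq <- function(r, P, q) {
  h <- r[2] - r[1]
  vapply(q, function(qq) {
    s <- ifelse(qq * r < 1e-12, 1, sin(qq * r) / (qq * r))
    f <- P * s
    4 * pi * (sum(f) - 0.5 * (f[1] + f[length(f)])) * h
  }, numeric(1))
}

# curvature penalty int_0^D [P''(r)]^2 dr by central differences on a dense
# grid (endpoints by one-sided second differences)
oracle_curvature_quad <- function(coeffs, n_grid = 1e4) {
  D <- coeffs$grid$D
  r <- seq(0, D, length.out = n_grid + 1)
  h <- r[2] - r[1]
  P <- drop(vapply(seq_len(coeffs$grid$n_total),
                   function(n) oracle_sn_direct(n, r, D),
                   numeric(length(r))) %*% coeffs$values)
  m <- length(P)
  d2 <- numeric(m)
  d2[2:(m - 1)] <- (P[1:(m - 2)] - 2 * P[2:(m - 1)] + P[3:m]) / h^2
  d2[1] <- (2 * P[1] - 5 * P[2] + 4 * P[3] - P[4]) / h^2
  d2[m] <- (2 * P[m] - 5 * P[m - 1] + 4 * P[m - 2] - P[m - 3]) / h^2
  f <- d2^2
  (sum(f) - 0.5 * (f[1] + f[m])) * h
}

# trapezoid integral of y over x
oracle_trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# analytic sphere intensity (independent of the package's implementation)
oracle_sphere_iq <- function(q, R) {
  x <- q * R
  ifelse(x < 1e-8, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}
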