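#' Shannon channel intensities with covariance
#'
#' Container for a set of channel intensities \eqn{I_n} on a
#' \code{\link{shannon_grid}}, together with their covariance matrix from the
#' least-squares fit (zero for analytic coefficients). Values may be
#' negative: no positivity constraint is imposed anywhere in the method.
#'
#' @param values numeric vector of length \code{grid$n_total} (intensity units).
#' @param grid a \code{\link{shannon_grid}}.
#' @param covariance symmetric \code{n_total x n_total} matrix
#'   (intensity^2 units), or \code{NULL} for the zero matrix.
#' @return an object of class \code{"shannon_coeffs"}.
#' @export
shannon_coeffs <- function(values, grid, covariance = NULL) {
  stopifnot(inherits(grid, "shannon_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_total)
    stop("length(values) must equal grid$n_total = ", grid$n_total)
  if (any(!is.finite(values))) stop("values must be finite")
  # NULL stands for the zero matrix (analytic coefficients); kept lazy so
  # very long analytic series do not materialize an n^2 matrix
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == grid$n_total))
      stop("covariance must be n_total x n_total")
    if (max(abs(covariance - t(covariance))) >
        1e-8 * (1 + max(abs(covariance))))
      stop("covariance must be symmetric")
    if (any(diag(covariance) < -1e-12 * (1 + max(abs(covariance)))))
      stop("covariance diagonal must be non-negative")
    covariance <- (covariance + t(covariance)) / 2
    if (all(covariance == 0)) covariance <- NULL
  }
  structure(list(values = values, covariance = covariance, grid = grid),
            class = "shannon_coeffs")
}

#' @export
print.shannon_coeffs <- function(x, ...) {
  cat("Shannon channel intensities: n_total =", x$grid$n_total,
      "(n_max =", x$grid$n_max, "), D =", format(x$grid$D), "\n")
  show <- utils::head(x$values, 8)
  cat("  I_n:", paste(signif(show, 5), collapse = " "),
      if (length(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' Evaluate the reconstructed intensity I_c(q)
#'
#' Computes \eqn{I_c(q) = \sum_n I_n B_n(q)} on an arbitrary q grid
#' (including \eqn{q = 0} and \eqn{q > q_{max}}), with the pointwise 1-sigma
#' uncertainty \eqn{\sqrt{b^\top C\, b}} propagated through the coefficient
#' covariance \eqn{C}, where \eqn{b} is the vector of basis weights at q.
#'
#' @param coeffs a \code{\link{shannon_coeffs}} object.
#' @param q momentum transfer values (finite, >= 0).
#' @return data frame with columns \code{q}, \code{I} and \code{sd}.
#' @examples
#' cf <- sphere_shannon_In(8, R = 25)
#' ift_intensity(cf, c(0, 0.1, 0.2))
#' @export
ift_intensity <- function(coeffs, q) {
  stopifnot(inherits(coeffs, "shannon_coeffs"))
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  B <- basis_matrix_q(q, coeffs$grid)
  I <- drop(B %*% coeffs$values)
  v <- if (is.null(coeffs$covariance)) numeric(length(q)) else
    rowSums((B %*% coeffs$covariance) * B)
  data.frame(q = q, I = I, sd = sqrt(pmax(v, 0)))
}

#' Evaluate the reconstructed pair distribution function P(r)
#'
#' Computes \eqn{P(r) = \sum_n I_n S_n(r)} on \eqn{[0, D]} with the pointwise
#' 1-sigma uncertainty \eqn{\sqrt{s^\top C\, s}}. By construction
#' \eqn{P(0) = P(D) = 0} exactly.
#'
#' @param coeffs a \code{\link{shannon_coeffs}} object.
#' @param r real-space grid; defaults to 501 evenly spaced points on
#'   \code{[0, D]}.
#' @param n_r number of points of the default grid.
#' @return data frame with columns \code{r}, \code{P} and \code{sd}.
#' @export
ift_pr <- function(coeffs, r = NULL, n_r = 501) {
  stopifnot(inherits(coeffs, "shannon_coeffs"))
  if (is.null(r)) r <- seq(0, coeffs$grid$D, length.out = n_r)
  S <- basis_matrix_r(r, coeffs$grid)
  P <- drop(S %*% coeffs$values)
  v <- if (is.null(coeffs$covariance)) numeric(length(r)) else
    rowSums((S %*% coeffs$covariance) * S)
  data.frame(r = r, P = P, sd = sqrt(pmax(v, 0)))
}
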