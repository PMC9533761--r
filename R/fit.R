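#' Design matrix of the Shannon-channel fit
#'
#' Assembles \eqn{A_{in} = B_n(q_i)} over the untrimmed points of a profile,
#' so that the model intensities are \eqn{A I_n}.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param grid a \code{\link{shannon_grid}}; its \code{q_max} should cover
#'   the trimmed data range.
#' @return numeric matrix, \code{n_points x n_total}.
#' @export
design_matrix <- function(profile, grid) {
  stopifnot(inherits(profile, "scattering_profile"),
            inherits(grid, "shannon_grid"))
  if (grid$n_max < 1)
    stop("degenerate grid (n_max < 1): increase D or q_max")
  basis_matrix_q(trimmed(profile)$q, grid)
}

#' Smoothness regularizer as a quadratic form in the channel intensities
#'
#' The curvature penalty \eqn{S = \int_0^D [P''(r)]^2\,dr} of the
#' reconstructed pair distribution function is an exact quadratic form
#' \eqn{S = I_n^\top M I_n} in the channel intensities, because
#' \eqn{P = \sum_n I_n S_n}. The matrix entries are closed-form integrals of
#' \eqn{S_m'' S_n''}:
#' \deqn{M_{mm} = \frac{m^4\pi^2}{4 D^5}\left(\frac{m^2\pi^2}{6} +
#'       \frac{11}{4}\right), \qquad
#'       M_{mn} = \frac{m^2 n^2 \pi^2 (-1)^{m+n}}{2 D^5}
#'       \left[1 + \frac{2 m^2 n^2}{(m^2 - n^2)^2}\right] \ (m \ne n).}
#'
#' @param grid a \code{\link{shannon_grid}}.
#' @return symmetric positive-semidefinite \code{n_total x n_total} matrix
#'   (units 1/length^5).
#' @export
regularizer_matrix <- function(grid) {
  stopifnot(inherits(grid, "shannon_grid"))
  n <- grid$n_total
  D <- grid$D
  idx <- seq_len(n)
  M <- outer(idx, idx, function(m, k) {
    off <- m^2 * k^2 * pi^2 * (-1)^(m + k) / (2 * D^5) *
      (1 + 2 * m^2 * k^2 / (m^2 - k^2)^2)
    dia <- m^4 * pi^2 / (4 * D^5) * (m^2 * pi^2 / 6 + 11 / 4)
    ifelse(m == k, dia, off)
  })
  (M + t(M)) / 2
}

#' Regularized weighted least-squares fit of the channel intensities
#'
#' Minimizes \eqn{T = \chi^2_{unred} + \alpha S} over the channel
#' intensities, where \eqn{\chi^2_{unred} = \sum_i [(I_e(q_i) -
#' I_c(q_i))/\sigma_i]^2} and \eqn{S = I_n^\top M I_n} is the curvature
#' penalty of \code{\link{regularizer_matrix}}. The solution of the normal
#' equations is
#' \eqn{(A^\top W A + \alpha M)\,I_n = A^\top W I_e} with
#' \eqn{W = \mathrm{diag}(1/\sigma_i^2)}, and the coefficient covariance is
#' \eqn{C = (A^\top W A + \alpha M)^{-1}} (experimental sigmas are taken at
#' face value; the covariance is not rescaled by the reduced chi-square).
#'
#' When \code{extend} is on and \eqn{\alpha > 0}, channels with
#' \eqn{n_{max} < n \le 3 n_{max}} float beyond the measured q range,
#' constrained only by the penalty; with \eqn{\alpha = 0} those channels
#' would be completely unconstrained, so the fit falls back to
#' \eqn{n_{total} = n_{max}} with a warning. A symmetric positive-definite
#' factorization is used, with an eigenvalue-clipped pseudo-inverse fallback
#' when the condition number exceeds 1e12 (near-singular systems arise from
#' extension channels at tiny \eqn{\alpha}).
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param D maximum particle dimension; must exceed \eqn{\pi/q_{max}}.
#' @param alpha regularization weight, >= 0.
#' @param extend carry floating channels up to \eqn{3 n_{max}}.
#' @return an object of class \code{"shannon_fit"}: list with
#'   \code{coeffs} (a \code{\link{shannon_coeffs}}), \code{alpha}, \code{D},
#'   \code{chi2} (reduced, dof = n_points - n_max),
#'   \code{chi2_unreduced}, \code{n_max}, \code{n_total} and
#'   \code{regularizer_value}.
#' @examples
#' p <- simulate_sphere_profile(seed = 7)
#' fit <- fit_shannon(p, D = 50, alpha = 0, extend = FALSE)
#' fit$chi2
#' @export
fit_shannon <- function(profile, D, alpha = 0, extend = TRUE) {
  sys <- fit_system(profile, D, extend = extend && alpha > 0)
  fit_shannon_sys(sys, alpha)
}

# precomputed pieces reused across an alpha scan
fit_system <- function(profile, D, extend) {
  stopifnot(inherits(profile, "scattering_profile"))
  tr <- trimmed(profile)
  if (D <= pi / max(tr$q))
    stop("D must exceed pi/q_max so that at least one Shannon channel fits")
  grid <- shannon_grid(D, q_max = max(tr$q), extend = extend)
  if (length(tr$q) <= grid$n_max)
    stop("fewer data points than Shannon channels; cannot fit")
  A <- basis_matrix_q(tr$q, grid)
  w <- 1 / tr$sigma^2
  AtWA <- crossprod(A * sqrt(w))
  AtWy <- drop(crossprod(A, w * tr$I))
  list(profile = profile, grid = grid, A = A, w = w, y = tr$I,
       AtWA = AtWA, AtWy = AtWy, M = regularizer_matrix(grid))
}

fit_shannon_sys <- function(sys, alpha) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  grid <- sys$grid
  if (alpha == 0 && grid$extend) {
    warning("alpha = 0 with extension channels is ill-posed; ",
            "refitting with n_total = n_max")
    sys <- fit_system(sys$profile, grid$D, extend = FALSE)
    grid <- sys$grid
  }
  H <- sys$AtWA + alpha * sys$M
  sol <- solve_spd(H, sys$AtWy)
  In <- sol$x
  C <- sol$inv
  coeffs <- shannon_coeffs(In, grid, C)
  resid <- (sys$y - drop(sys$A %*% In)) / sqrt(1 / sys$w)
  chi2_un <- sum(resid^2)
  dof <- length(sys$y) - grid$n_max
  S <- drop(crossprod(In, sys$M %*% In))
  structure(
    list(coeffs = coeffs, alpha = alpha, D = grid$D,
         chi2 = chi2_un / dof, chi2_unreduced = chi2_un,
         n_max = grid$n_max, n_total = grid$n_total,
         regularizer_value = S, dof = dof),
    class = "shannon_fit")
}

# SPD solve returning solution and inverse, with eigenvalue-clipped
# pseudo-inverse fallback for ill-conditioned systems
solve_spd <- function(H, b, cond_max = 1e12) {
  ev <- eigen(H, symmetric = TRUE)
  lam <- ev$values
  if (lam[1] <= 0) stop("normal matrix is not positive semi-definite")
  if (lam[length(lam)] > lam[1] / cond_max) {
    R <- chol(H)
    x <- backsolve(R, forwardsolve(t(R), b))
    inv <- chol2inv(R)
  } else {
    keep <- lam > lam[1] / cond_max
    if (sum(keep) < 1)
      stop("normal equations are singular: raise alpha or disable extension")
    li <- ifelse(keep, 1 / lam, 0)
    inv <- ev$vectors %*% (li * t(ev$vectors))
    x <- drop(inv %*% b)
  }
  list(x = as.numeric(x), inv = (inv + t(inv)) / 2)
}

#' Reduced chi-square of a fit against a profile
#'
#' Sum of squared sigma-weighted residuals over the untrimmed points,
#' divided by \eqn{N_{points} - n_{max}} (extension channels are
#' penalty-constrained, not counted as free parameters).
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param fit a \code{"shannon_fit"} (or a \code{\link{shannon_coeffs}} with
#'   \code{n_max} taken from its grid).
#' @return dimensionless reduced chi-square.
#' @export
chi2_reduced <- function(profile, fit) {
  coeffs <- if (inherits(fit, "shannon_fit")) fit$coeffs else fit
  stopifnot(inherits(coeffs, "shannon_coeffs"))
  tr <- trimmed(profile)
  n_max <- coeffs$grid$n_max
  if (length(tr$q) <= n_max)
    stop("N_points must exceed n_max")
  Ic <- drop(basis_matrix_q(tr$q, coeffs$grid) %*% coeffs$values)
  sum(((tr$I - Ic) / tr$sigma)^2) / (length(tr$q) - n_max)
}

#' @export
print.shannon_fit <- function(x, ...) {
  cat("Shannon IFT fit: D =", format(x$D),
      " alpha =", format(x$alpha, digits = 4),
      " chi2 =", format(x$chi2, digits = 5), "\n",
      " n_max =", x$n_max, " n_total =", x$n_total,
      " penalty S =", format(x$regularizer_value, digits = 4), "\n")
  invisible(x)
}
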