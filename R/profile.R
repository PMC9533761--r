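#' Experimental scattering profile
#'
#' Container for a measured SAS profile: momentum transfer \code{q},
#' intensities \code{I} and experimental standard deviations \code{sigma},
#' plus an inclusive trim window \code{[first, last]} selecting the points
#' actually fit (outlier points at either end of a measured curve are
#' routinely discarded).
#'
#' @param q strictly increasing positive momentum transfers.
#' @param I intensities (arbitrary units).
#' @param sigma positive standard deviations, same units as \code{I}.
#' @param first,last inclusive trim indices; defaults keep every point.
#' @return an object of class \code{"scattering_profile"}.
#' @export
scattering_profile <- function(q, I, sigma, first = 1L, last = length(q)) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length")
  if (any(!is.finite(q)) || any(!is.finite(I)) || any(!is.finite(sigma)))
    stop("profile columns must be finite")
  if (any(q <= 0)) stop("q must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma <= 0))
    stop("sigma must be positive; offending rows: ",
         paste(utils::head(which(sigma <= 0), 10), collapse = ", "))
  first <- as.integer(first); last <- as.integer(last)
  if (first < 1L || last > length(q) || last - first + 1L < 10L)
    stop("trim window must keep at least 10 points")
  structure(list(q = q, I = I, sigma = sigma, first = first, last = last),
            class = "scattering_profile")
}

# the trimmed view actually used by fits
trimmed <- function(profile) {
  idx <- profile$first:profile$last
  list(q = profile$q[idx], I = profile$I[idx], sigma = profile$sigma[idx])
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat("Scattering profile:", length(x$q), "points, q in [",
      format(min(x$q)), ",", format(max(x$q)), "]")
  if (x$first != 1L || x$last != length(x$q))
    cat(" (trimmed to", x$first, "..", x$last, ")")
  cat("\n")
  invisible(x)
}
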