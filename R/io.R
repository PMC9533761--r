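#' Read a 3-column ASCII scattering profile
#'
#' Parses the whitespace-delimited q / I / sigma dialect produced by SAXS
#' beamlines: blank lines, lines starting with \code{#} and non-numeric
#' header text are skipped; original row order is preserved and q must be
#' strictly increasing after parsing. Lines with more than three numeric
#' columns keep the first three.
#'
#' @param path input file.
#' @param first,last optional trim window applied to the parsed profile.
#' @param drop_zero_sigma silently drop rows with sigma = 0 (the sentinel
#'   used for extrapolated model-only rows in \code{.fit} files) instead of
#'   raising the standard hard error.
#' @return a \code{\link{scattering_profile}}.
#' @export
read_dat <- function(path, first = NULL, last = NULL,
                     drop_zero_sigma = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t,]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (any(is.na(vals))) {
      if (all(is.na(vals))) next            # pure text header line
      stop("line ", i, ": mixed numeric and non-numeric tokens")
    }
    if (length(vals) < 3)
      stop("line ", i, ": fewer than 3 numeric columns")
    rows[[length(rows) + 1L]] <- vals[1:3]
  }
  if (length(rows) == 0) stop("no numeric data rows in ", path)
  m <- do.call(rbind, rows)
  if (drop_zero_sigma) m <- m[m[, 3] > 0, , drop = FALSE]
  if (any(m[, 3] <= 0))
    stop("non-positive sigma at data rows: ",
         paste(utils::head(which(m[, 3] <= 0), 10), collapse = ", "))
  if (any(diff(m[, 1]) <= 0)) stop("q must be strictly increasing")
  scattering_profile(m[, 1], m[, 2], m[, 3],
                     first = if (is.null(first)) 1L else first,
                     last = if (is.null(last)) nrow(m) else last)
}

#' Write a profile as a 3-column .dat file
#'
#' Full-precision (17 significant digits) serialization so that
#' write-then-read round-trips exactly.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param path output file.
#' @param header optional \code{#}-prefixed header line(s).
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path, header = "# q I sigma") {
  stopifnot(inherits(profile, "scattering_profile"))
  body <- sprintf("%.17g %.17g %.17g", profile$q, profile$I, profile$sigma)
  writeLines(c(header, body), path)
  invisible(path)
}

# parameter header shared by the .fit and _pr.dat writers
record_header <- function(record) {
  p <- record$params
  os <- record$oversmoothed
  f <- record$fit
  c(sprintf("# Dmax: %.17g", f$D),
    sprintf("# alpha: %.17g", f$alpha),
    sprintf("# chi2: %.17g", f$chi2),
    sprintf("# I0: %.17g +- %.17g", p$I0$value, p$I0$sd),
    sprintf("# Rg: %.17g +- %.17g", p$Rg$value, p$Rg$sd),
    sprintf("# ravg: %.17g +- %.17g", p$ravg$value, p$ravg$sd),
    sprintf("# Vp: %.17g +- %.17g", os$Vp$value, os$Vp$sd),
    sprintf("# Vc: %.17g +- %.17g", os$Vc$value, os$Vc$sd),
    sprintf("# lc: %.17g +- %.17g", os$lc$value, os$lc$sd),
    sprintf("# MW_kDa: %.17g", os$MW_kDa))
}

#' Write the fitted intensity file (.fit)
#'
#' Saves the experimental data and the calculated fit: a \code{#}-prefixed
#' header with D, alpha, chi2 and all size parameters with uncertainties,
#' then four columns q, I_e, sigma, I_c on the experimental grid, preceded
#' by extrapolated model rows from q = 0 up to the first measured point.
#' Extrapolated rows carry sigma = 0 as a sentinel marking model-only
#' points (I_e is set to I_c there); the first body row has q = 0 and
#' I_c = I(0).
#'
#' @param record an \code{"ift_record"} from \code{\link{ift_auto}}.
#' @param path output file.
#' @param q_out optional user-supplied q grid on which to evaluate the
#'   calculated intensities instead of the experimental grid.
#' @return the path, invisibly.
#' @export
write_fit <- function(record, path, q_out = NULL) {
  stopifnot(inherits(record, "ift_record"))
  tr <- trimmed(record$profile)
  coeffs <- record$fit$coeffs
  if (is.null(q_out)) {
    dq <- tr$q[2] - tr$q[1]
    q_ext <- seq(0, tr$q[1] - dq / 2, by = dq)
    ext <- ift_intensity(coeffs, q_ext)
    obs <- ift_intensity(coeffs, tr$q)
    q_all <- c(q_ext, tr$q)
    Ie <- c(ext$I, tr$I)
    sg <- c(rep(0, length(q_ext)), tr$sigma)
    Ic <- c(ext$I, obs$I)
  } else {
    out <- ift_intensity(coeffs, q_out)
    q_all <- q_out
    Ie <- out$I
    sg <- rep(0, length(q_out))
    Ic <- out$I
  }
  body <- sprintf("%.17g %.17g %.17g %.17g", q_all, Ie, sg, Ic)
  writeLines(c(record_header(record), "# q I_e sigma I_c", body), path)
  invisible(path)
}

#' Write the pair distribution function file (_pr.dat)
#'
#' Three columns r, P(r), sigma_P on the default 501-point grid spanning
#' exactly \code{[0, D]}, under the same parameter header as
#' \code{\link{write_fit}}.
#'
#' @param record an \code{"ift_record"}.
#' @param path output file.
#' @param n_r number of grid points.
#' @return the path, invisibly.
#' @export
write_pr <- function(record, path, n_r = 501) {
  stopifnot(inherits(record, "ift_record"))
  pr <- ift_pr(record$fit$coeffs, n_r = n_r)
  body <- sprintf("%.17g %.17g %.17g", pr$r, pr$P, pr$sd)
  writeLines(c(record_header(record), "# r P(r) sigma_P", body), path)
  invisible(path)
}

# parse a "key: value +- sd" header back into a named list (used in tests
# and by downstream tooling)
#' Parse the parameter header of a .fit or _pr.dat file
#' @param path file written by \code{\link{write_fit}} or
#'   \code{\link{write_pr}}.
#' @return named list of numeric values (and \code{*_sd} entries).
#' @export
read_fit_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^# *([A-Za-z0-9_]+): *([-+0-9.eE]+)( *\\+- *([-+0-9.eE]+))?", ln))[[1]]
    if (length(m) == 0) next
    key <- m[2]
    out[[key]] <- as.numeric(m[3])
    if (m[5] != "") out[[paste0(key, "_sd")]] <- as.numeric(m[5])
  }
  out
}
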