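test_that("design matrix has the cardinal identity pattern on a Shannon-point grid", {
  D <- 50
  qn <- (1:12) * pi / D
  p <- scattering_profile(qn, rep(1, 12), rep(0.1, 12))
  g <- shannon_grid(D, max(qn), extend = FALSE)
  A <- design_matrix(p, g)
  expect_equal(dim(A), c(12L, 12L))
  expect_equal(A, diag(12), tolerance = 1e-10)
})

test_that("design matrix shape follows the extension convention", {
  p <- simulate_sphere_profile(n_q = 100, seed = 1)
  g <- shannon_grid(50, max(p$q), extend = TRUE)
  expect_equal(dim(design_matrix(p, g)), c(100L, 24L))
})

test_that("design matrix applied to sphere channels reproduces sphere intensities", {
  p <- simulate_sphere_profile(n_q = 200, seed = 5)
  cf <- sphere_shannon_In(8, R = 25)
  g <- cf$grid
  A <- design_matrix(p, g)
  got <- drop(A %*% cf$values)
  # compare against an independent direct basis evaluation away from the
  # channel positions, where the naive oracle formula is well defined
  x <- p$q * 50 / pi
  keep <- abs(x - round(x)) > 1e-3
  want <- sapply(which(keep), function(i)
    sum(cf$values * vapply(1:8, function(n)
      oracle_bn_direct(n, p$q[i], 50), numeric(1))))
  expect_equal(got[keep], want, tolerance = 1e-9)
  # with a long channel series the design matrix reproduces the analytic
  # sphere on the profile grid
  cf200 <- sphere_shannon_In(200, R = 25)
  A200 <- design_matrix(p, cf200$grid)
  got200 <- drop(A200 %*% cf200$values)
  Itrue <- oracle_sphere_iq(p$q, 25)
  hi <- Itrue > 1e-3
  expect_lt(max(abs(got200 - Itrue)[hi] / Itrue[hi]), 1e-3)
})

test_that("regularizer matrix is the exact quadratic form of the P'' integral", {
  g <- shannon_grid(50, 10 * pi / 50, extend = FALSE)
  M <- regularizer_matrix(g)
  expect_lt(max(abs(M - t(M))), 1e-12)
  set.seed(21)
  for (rep in 1:20) {
    v <- rnorm(10)
    cf <- shannon_coeffs(v, g)
    expect_equal(drop(crossprod(v, M %*% v)), oracle_curvature_quad(cf),
                 tolerance = 1e-4)
  }
})

test_that("regularizer rescales as a change of variables under D -> 2D", {
  # S = int [P'']^2 dr with r -> 2r maps to a 1/D^5 scaling of the form
  g1 <- shannon_grid(50, 6 * pi / 50, extend = FALSE)
  g2 <- shannon_grid(100, 6 * pi / 100, extend = FALSE)
  expect_equal(regularizer_matrix(g2), regularizer_matrix(g1) / 2^5,
               tolerance = 1e-12)
})

test_that("noise-free band-limited data are recovered exactly at alpha = 0", {
  truth <- sphere_shannon_In(8, R = 25)
  q <- seq(0.002, 8 * pi / 50, length.out = 400)
  I <- ift_intensity(truth, q)$I
  p <- scattering_profile(q, I, rep(1e-6, length(q)))
  fit <- fit_shannon(p, 50, alpha = 0, extend = FALSE)
  expect_equal(fit$coeffs$values, truth$values, tolerance = 1e-8)
  expect_lt(fit$chi2, 1e-10)
})

test_that("chi^2 is non-decreasing and the penalty non-increasing along an alpha ladder", {
  p <- simulate_sphere_profile(seed = 9)
  alphas <- 10^seq(2, 13, length.out = 10)
  fits <- lapply(alphas, function(a) fit_shannon(p, 50, a, extend = TRUE))
  chi2s <- vapply(fits, `[[`, numeric(1), "chi2")
  Ss <- vapply(fits, `[[`, numeric(1), "regularizer_value")
  expect_true(all(diff(chi2s) > -1e-10))
  expect_true(all(diff(Ss) < 1e-12 * max(Ss)))
  # within the fixed (unextended) model family the unpenalized optimum is
  # the chi^2 floor
  f0 <- fit_shannon(p, 50, 0, extend = FALSE)
  chi2s_off <- vapply(alphas, function(a)
    fit_shannon(p, 50, a, extend = FALSE)$chi2, numeric(1))
  expect_true(all(diff(chi2s_off) > -1e-10))
  expect_true(all(chi2s_off >= f0$chi2 - 1e-10))
})

test_that("reduced chi^2 follows its summation convention", {
  D <- 50
  q <- seq(0.01, 0.5, length.out = 40)
  g <- shannon_grid(D, max(q), extend = FALSE)
  set.seed(13)
  v <- rnorm(g$n_total) * 0.3^(seq_len(g$n_total) - 1)
  cf <- shannon_coeffs(v, g)
  Imod <- ift_intensity(cf, q)$I
  # perfect fit -> 0
  p0 <- scattering_profile(q, Imod, rep(0.05, 40))
  expect_equal(chi2_reduced(p0, cf), 0, tolerance = 1e-20)
  # residuals of exactly 1 sigma -> N / (N - n_max)
  p1 <- scattering_profile(q, Imod + 0.05, rep(0.05, 40))
  expect_equal(chi2_reduced(p1, cf), 40 / (40 - g$n_max), tolerance = 1e-10)
  # brute-force summation on random residuals
  eps <- rnorm(40)
  p2 <- scattering_profile(q, Imod + 0.05 * eps, rep(0.05, 40))
  expect_equal(chi2_reduced(p2, cf), sum(eps^2) / (40 - g$n_max),
               tolerance = 1e-10)
})

test_that("normal equations agree with a generic minimizer of T", {
  p <- simulate_sphere_profile(n_q = 60, q_max = 5 * pi / 50, seed = 17)
  D <- 50
  alpha <- 1e6
  fit <- fit_shannon(p, D, alpha, extend = FALSE)
  g <- fit$coeffs$grid
  A <- design_matrix(p, g)
  M <- regularizer_matrix(g)
  w <- 1 / trimmed(p)$sigma^2
  y <- trimmed(p)$I
  Tfun <- function(v) sum(w * (y - drop(A %*% v))^2) +
    alpha * drop(crossprod(v, M %*% v))
  Tgrad <- function(v) -2 * drop(crossprod(A, w * (y - drop(A %*% v)))) +
    2 * alpha * drop(M %*% v)
  opt <- optim(rep(0.1, g$n_total), Tfun, Tgrad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(fit$coeffs$values, opt$par, tolerance = 1e-8)
})

test_that("alpha = 0 with extension requested falls back to n_max channels", {
  p <- simulate_sphere_profile(seed = 2)
  fit <- fit_shannon(p, 50, alpha = 0, extend = TRUE)
  expect_identical(fit$n_total, fit$n_max)
  expect_error(fit_shannon(p, D = 4, alpha = 0), "D must exceed")
})
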