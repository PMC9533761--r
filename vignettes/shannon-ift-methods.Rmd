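---
title: "The Shannon-channel IFT: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Shannon-channel IFT: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shannonift)
```

## The model

A particle of maximum dimension $D$ has a pair distribution function
$P(r)$ supported on $[0, D]$, and its scattering intensity
$I(q) = 4\pi \int_0^D P(r)\,\frac{\sin qr}{qr}\,dr$ is therefore
band-limited: it is fully determined by its values at the Shannon channels
$q_n = n\pi/D$. Writing $Q(r) = P(r)/r$ as a sine series on $[0,D]$ and
identifying the series coefficients with the channel intensities
$I_n = I(q_n)$ yields the cardinal representation

$$I(q) = \sum_n I_n B_n(q), \qquad
  B_n(q) = (-1)^{n+1}\,\frac{2n^2}{n^2 - x^2}\,\frac{\sin \pi x}{\pi x},
  \quad x = \frac{qD}{\pi},$$

$$P(r) = \sum_n I_n S_n(r), \qquad
  S_n(r) = \frac{n\,r}{2D^2}\,\sin\frac{n\pi r}{D}.$$

$B_n$ is 1 at its own channel and 0 at every other ($\delta_{nm}$), so the
fitted curve interpolates the $I_n$ at the Shannon points, and
$B_n(0) = 2(-1)^{n+1}$ gives the forward scattering as the alternating sum
$I(0) = 2\sum_n (-1)^{n+1} I_n$. Every $S_n$ vanishes at $r = 0$ and
$r = D$, which builds the correct endpoint behaviour of $P(r)$ into the
representation. The test suite verifies that the two evaluators are
Fourier mates by quadrature to $10^{-4}$ relative.

Working in the $I_n$ parameterization (rather than abstract series
coefficients) has two practical payoffs: the fitted quantities are
directly interpretable intensities, and every derived parameter becomes a
closed-form channel sum whose gradient is trivial, so uncertainties
propagate exactly through the coefficient covariance.

## Estimation

Given data $(q_i, I_e(q_i), \sigma_i)$, the package minimizes
$T = \chi^2_{\mathrm{unred}} + \alpha S$ with the curvature penalty
$S = \int_0^D [P''(r)]^2\,dr$. Because $P$ is linear in the $I_n$, $S$ is
an exact quadratic form $I_n^\top M I_n$; the entries of $M$ are
closed-form integrals of $S_m'' S_n''$ (diagonal
$\tfrac{m^4\pi^2}{4D^5}(\tfrac{m^2\pi^2}{6} + \tfrac{11}{4})$, and the
off-diagonal form given in `?regularizer_matrix`), verified against
central-difference quadrature to machine precision. The normal equations
$(A^\top W A + \alpha M) I_n = A^\top W I_e$ with
$W = \mathrm{diag}(1/\sigma_i^2)$ give the estimate and the covariance
$C = (A^\top W A + \alpha M)^{-1}$.

Choices a user should know about:

* **Reduced $\chi^2$ convention.** $\chi^2$ is reported divided by
  $N - n_{max}$. Channels beyond $n_{max} = \lfloor q_{max}D/\pi \rfloor$
  (carried up to $3 n_{max}$ when extension is on) exist only to keep the
  regularizer from biasing the unmeasured band toward zero; they are
  penalty-constrained, not data-determined, so they are not counted as
  degrees of freedom.
* **Covariance is not rescaled** by the reduced $\chi^2$: the experimental
  $\sigma_i$ are taken at face value and propagated directly. Monte-Carlo
  tests over 200 noise realizations confirm the reported channel and
  parameter errors match the empirical spread well within a factor 1.5.
* **Extension and ill-posedness.** With $\alpha = 0$ the extension
  channels are completely unconstrained, so that combination falls back to
  $n_{total} = n_{max}$. At tiny positive $\alpha$ the system is
  near-singular; the solver switches from a Cholesky factorization to an
  eigenvalue-clipped pseudo-inverse when the condition number exceeds
  $10^{12}$.
* **Monotonicity caveat.** Within a fixed channel count, $\chi^2$ is
  non-decreasing and $S$ non-increasing in $\alpha$ (a property test
  asserts this). Comparing *across* families (8 unregularized channels vs
  24 regularized ones) the extended fit can undercut the unextended
  $\chi^2$ floor by of order 1%; the $\alpha$ selection rule is defined
  relative to the unextended floor and is unaffected.

## Size and shape parameters

All parameters are channel sums with propagated errors ($\sigma =
\sqrt{g^\top C g}$, with covariances between numerator and denominator
sums retained):

$$I(0) = 2\sum (-1)^{n+1} I_n, \qquad
  R_g^2 = D^2\,\frac{\sum (-1)^{n+1} I_n\,(\tfrac12 - \tfrac{3}{n^2\pi^2})}
  {\sum (-1)^{n+1} I_n},$$

$$\bar r = D\,\frac{\sum I_n\,[(-1)^n(2 - n^2\pi^2) - 2]/(n^2\pi^2)}
  {\sum (-1)^{n+1} I_n}, \qquad
  Q = \frac{\pi^3}{D^3}\sum n^2 I_n, \quad V_p = \frac{2\pi^2 I(0)}{Q},$$

$$\int_0^\infty qI\,dq = \frac{2\pi}{D^2}\sum n\,\mathrm{Si}(n\pi)\,I_n,
  \qquad V_c = \frac{I(0)}{\int qI\,dq}, \quad
  \ell_c = \frac{\pi \int qI\,dq}{Q},$$

so that $V_c = V_p/(2\pi\ell_c)$ holds identically. On the analytic solid
sphere ($I_n$ known in closed form, radius cancelling from the normalized
channel values) these sums reproduce $R_g/R = \sqrt{3/5}$,
$\bar r/R = 36/35$, $\ell_c/R = 3/2$ and $V_p = 4\pi R^3/3$ to 0.2% or
better with a long series.

Numerical choices: the $Q$ sum converges like the Porod tail itself
($n^{-2}$ terms), so the analytic-oracle path adds a tail estimate
$C\,\psi'(N+1)$ with $C$ the mean of $n^4 I_n$ over the trailing channels
— averaging the even/odd envelope is exactly right for any particle whose
odd channels decay faster, as the sphere's do. $\mathrm{Si}(n\pi)$ is
computed exactly (via `pracma::Si`) up to $n = 200$ and by its asymptotic
expansion beyond, where the expansion error is below $10^{-13}$. Fitted
data use the raw truncated sums: truncation at $n_{max} = 8$ channels
overshoots the sphere's $V_p$ by ~7–16%, which is the known behaviour of
the benchmark fit.

The molecular weight estimate is $V_p/1.6$ in Da with $V_p$ in Å³; the
1.6 divisor is calibrated for Å³, so profiles measured in nm$^{-1}$ have
$V_p$ converted ($\times 1000$) for the MW only, with a logged notice.

Because $V_p$, $V_c$ and $\ell_c$ are sensitive to systematic high-$q$
errors, `oversmoothed_parameters()` re-estimates them from an auxiliary
fit with $10\alpha$ on the sub-range $q \le 8/R_g$ — oversmoothing
suppresses shape scattering and enforces a Porod-like decay — without
touching the primary fit or any other parameter.

## Automatic D and alpha

$D$ estimation: a Guinier fit of the first 20 points (window shortened
iteratively to $qR_g \le 1.3$; weighted by $(I/\sigma)^2$; failure
signalled, not thrown) gives $R_g$, with the Guinier-peak estimator
$R_g = \sqrt{3/2}/q_{peak}$ of the $qI(q)$ maximum as fallback. From
$D_0 = 7R_g$ an unregularized fit is made, the channel series is tapered
by a Hann window $w_n = \tfrac12[1 + \cos(\pi n/n_{max})]$ to suppress
truncation ripples, and $D$ is the first point past the $P(r)$ maximum
where the filtered curve falls to $\le 0.01\,P_{max}$ (boundary
inclusive), followed by a refit. The taper is applied in the channel
domain; it is the canonical low-pass realization of a Hann filter for a
band-limited series and makes the procedure exactly testable.

The filter has a resolution cost: smearing widens the apparent support by
roughly half the kernel width, $\sim\pi/q_{max}$ (6.3 Å for the 8-channel
sphere conditions), so $D$ is recovered with a small systematic surplus
(about +9% on the benchmark sphere) even from noise-free band-limited
input. The tests therefore assert recovery within that a-priori
resolution band rather than an arbitrary percentage. The surplus is
benign: a slightly generous $D$ costs a little statistical efficiency but
does not bias the refitted parameters, and the end-to-end pipeline
reproduces the benchmark values comfortably.

$\alpha$ selection scans $10^{-20} \ldots 10^{20}$ in decade steps,
takes $\chi^2_{best}$ from the $\alpha = 0$ fit, log-linearly interpolates
the first crossing of $1.1\,\chi^2_{best}$, and then refines by bisection
in $\log_{10}\alpha$ until the realized $\chi^2$ lies within
$[1.05, 1.15]\,\chi^2_{best}$ — the interpolated crossing alone can miss
the band because $\chi^2(\alpha)$ is strongly curved between decade grid
points. The whole pipeline is deterministic for a fixed profile.

## The synthetic generator and what the tests show

`simulate_sphere_profile()` defines the study conditions: a solid sphere
of radius 25 Å observed over its first 8 Shannon channels
($q_{max} = 8\pi/50$), 500 evenly spaced points, Gaussian noise
$\sigma(q) = 0.02\,[I(q) + 0.01\,I(0)]$. The additive floor
$0.01\,I(0)$ keeps $\sigma$ from vanishing at the form-factor minima,
where a purely fractional model would make $\chi^2$ meaningless; 2% is a
typical well-exposed synchrotron noise level. The generator is the
package's only source of randomness and is bit-reproducible under a seed.

This emulates counting noise on an ideal monodisperse particle. It does
*not* emulate inter-particle interference, background-subtraction errors,
beam smearing, polydispersity or aggregation — so passing tests show the
estimator chain is correct and calibrated under its stated noise model,
not that real-data systematics are handled; the oversmoothed $V_p$ path
exists precisely because real data violate the ideal Porod assumptions.

Problem sizes used by the suite were chosen so every statistical check
has comfortable resolution at interactive runtimes: 200 noise
realizations for calibration tests, 20 seeds for the benchmark-recovery
check, $10^4$-point quadrature grids for transform oracles, and a
$10^5$-channel series (with tail correction) standing in for the
infinite-channel limit, where the residual truncation error is below
$10^{-5}$ relative.

## Degenerate inputs, tie-breaks, tolerances

* $n_{max}$ uses `floor` with a $10^{-12}$ relative tolerance so exact
  channel multiples are not lost to floating-point rounding.
* $B_n$ is evaluated by two algebraically equivalent forms switched at
  $x = 1/2$: near $x = 0$ the $\mathrm{sinc}(x)$ form, elsewhere
  $2n^2\,\mathrm{sinc}(x-n)/[x(x+n)]$, in which $x - n$ is computed
  exactly near the channel (Sterbenz) and the removable singularity
  disappears; both use `sinpi`. This replaces the more conventional
  Taylor-expansion patch around the singular points and is accurate to
  full precision everywhere.
* Profiles must have strictly increasing positive $q$, positive
  $\sigma$, and at least 10 points in the trim window; fits require more
  points than channels and $D > \pi/q_{max}$.
* A filtered $P(r)$ exactly at $0.01 P_{max}$ is accepted as the support
  endpoint (inclusive comparison).
* Extrapolated rows in `.fit` output carry a $\sigma = 0$ sentinel;
  `read_dat(drop_zero_sigma = TRUE)` reads such files back.

## Known limitations

* Slit-smearing/desmearing, non-uniform Shannon grids, positivity or
  Bayesian (MaxEnt) variants, and multi-curve fitting are out of scope.
* $D$ estimation inherits the $\pi/q_{max}$ resolution bias discussed
  above; particles barely covered by a few Shannon channels get
  correspondingly coarse $D$ estimates.
* The MW calibration ($V_p/1.6$) targets globular biological
  macromolecules; it is not meaningful for strongly flexible or
  non-protein particles.
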