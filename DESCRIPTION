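Package: shannonift
Title: Indirect Fourier Transform of Small-Angle Scattering Profiles via
    Shannon-Sampled Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits small-angle scattering (SAXS/SANS) profiles with a reduced
    set of intensities I_n sampled at the Shannon channels q_n = n*pi/D of a
    particle of maximum dimension D. Provides regularized weighted
    least-squares estimation of the channel intensities with full covariance,
    reconstruction of I(q) and of the pair distribution function P(r) with
    pointwise uncertainties, closed-form size and shape parameters (forward
    scattering, radius of gyration, average vector length, Porod invariant
    and volume, volume of correlation, correlation length, molecular weight)
    with propagated errors, automatic estimation of D and of the
    regularization weight, an analytic solid-sphere oracle with a seeded
    noisy-profile simulator, and readers/writers for the standard 3-column
    ASCII profile format together with a command-line driver.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
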