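test_that("transmission reproduces the thin-object phase/amplitude model", {
  opt <- table1_optics()
  n <- 8
  m0 <- zero_maps(n)
  E0 <- transmission(m0, opt$wavelength)
  expect_equal(E0$values, matrix(1 + 0i, n, n))

  # half-wave OPD flips the field sign
  Lh <- matrix(0, n, n); Lh[3, 5] <- opt$wavelength / 2
  Eh <- transmission(sample_maps(Lh, matrix(0, n, n), 1.67), opt$wavelength)
  expect_equal(Eh$values[3, 5], -1 + 0i, tolerance = 1e-12)

  # amplitude is exp(A), phase is 2*pi*L/lambda
  set.seed(1)
  m <- random_maps(n)
  E <- transmission(m, opt$wavelength)
  expect_equal(Mod(E$values), exp(m$A), tolerance = 1e-12)
  expect_equal(Arg(E$values) %% (2 * pi),
               (2 * pi * m$L / opt$wavelength) %% (2 * pi),
               tolerance = 1e-9)

  # integer-wave shifts leave the transmission unchanged
  m2 <- sample_maps(m$L + 3 * opt$wavelength, m$A, m$pixel_pitch)
  expect_equal(transmission(m2, opt$wavelength)$values, E$values,
               tolerance = 1e-12)

  m$L[1, 1] <- NaN
  expect_error(transmission(m, opt$wavelength), "non-finite")
})

test_that("Fresnel propagation is unitary and invertible", {
  set.seed(2)
  n <- 64; pitch <- 1.67; lam <- 0.45
  f <- complex_field(matrix(complex(real = rnorm(n * n),
                                    imaginary = rnorm(n * n)), n, n), pitch)
  for (Z in c(400, -900, 1270)) {
    g <- fresnel_propagate(f, Z, lam)
    expect_equal(sum(Mod(g$values)^2), sum(Mod(f$values)^2),
                 tolerance = 1e-6)
    back <- fresnel_propagate(g, -Z, lam)
    expect_lt(max(Mod(back$values - f$values)) / max(Mod(f$values)), 1e-6)
  }

  # plane wave is an eigenfunction (H(0) = 1, so exactly invariant)
  ones <- complex_field(matrix(1 + 0i, n, n), pitch)
  p <- fresnel_propagate(ones, 800, lam)
  expect_equal(p$values, ones$values, tolerance = 1e-10)

  # back-propagation is the exact adjoint of forward propagation
  u <- f$values
  v <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  lhs <- sum(Conj(fresnel_propagate(complex_field(u, pitch), 700, lam)$values) * v)
  rhs <- sum(Conj(u) *
               fresnel_propagate(complex_field(v, pitch), -700, lam)$values)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)

  expect_warning(
    fresnel_propagate(f, 5e4, lam, on_alias = "warn"), "undersampled")
})

test_that("coherence kernel is a probability kernel with sensible limits", {
  opt <- table1_optics()
  n <- 128
  K <- coherence_kernel(opt, c(n, n))
  expect_true(all(K$values >= 0))
  expect_equal(sum(K$values), 1, tolerance = 1e-6)
  expect_true(all(is.finite(K$values)))

  # fully coherent point source collapses to a discrete Dirac
  optc <- optics_config(source_diameter = 0, spectral_width = 0)
  Kc <- coherence_kernel(optc, c(n, n))
  expect_equal(sum(Kc$values != 0), 1)
  expect_equal(Kc$values[floor(n / 2) + 1, floor(n / 2) + 1], 1)

  # enlarging the source cannot sharpen the kernel. Width is measured as
  # the radial RMS spread of K (proportional to FWHM for a unimodal
  # kernel, and well defined for the discretized source), on a geometry
  # where the demagnified source extent spans several pixels.
  radial_width <- function(K) {
    v <- K$values
    c0 <- floor(nrow(v) / 2) + 1
    r2 <- outer((seq_len(nrow(v)) - c0)^2, (seq_len(ncol(v)) - c0)^2, `+`)
    sqrt(sum(v * r2))
  }
  near <- optics_config(source_sample_distance = 5e3, source_diameter = 100)
  nearer <- optics_config(source_sample_distance = 5e3, source_diameter = 200)
  expect_gte(radial_width(coherence_kernel(nearer, c(n, n))),
             radial_width(coherence_kernel(near, c(n, n))))
})

test_that("predicted intensity follows the forward model", {
  opt <- table1_optics()
  n <- 64
  I0 <- predict_intensity(zero_maps(n), opt)
  expect_equal(max(abs(I0$values - opt$background)) / opt$background, 0,
               tolerance = 1e-6)
  expect_true(all(I0$values >= 0))

  # a Dirac kernel is identical to skipping the coherence convolution
  set.seed(3)
  m <- random_maps(n)
  I_nok <- predict_intensity(m, opt, K = NULL)
  I_dirac <- predict_intensity(m, opt, K = dirac_kernel(c(n, n), 1.67))
  expect_identical(I_nok$values, I_dirac$values)

  # pitch mismatch is rejected
  expect_error(predict_intensity(m, opt, gaussian_kernel(1.75, 2.2)),
               "pitch")
})

test_that("hologram intensity is invariant under integer-wave OPD shifts", {
  opt <- table1_optics()
  n <- 64
  set.seed(4)
  K <- gaussian_kernel(1.75, 1.67)
  for (rep in 1:3) {
    m <- random_maps(n)
    N <- sample(c(-2L, 1L, 3L), 1)
    m_shift <- sample_maps(m$L + N * opt$wavelength, m$A, m$pixel_pitch)
    I1 <- predict_intensity(m, opt, K)
    I2 <- predict_intensity(m_shift, opt, K)
    expect_lt(max(abs(I1$values - I2$values)) / max(I1$values), 1e-12)
    # per-pixel (non-global) integer shifts too
    Np <- matrix(sample(0:3, n * n, replace = TRUE), n, n)
    m_px <- sample_maps(m$L + Np * opt$wavelength, m$A, m$pixel_pitch)
    I3 <- predict_intensity(m_px, opt, K)
    expect_lt(max(abs(I1$values - I3$values)) / max(I1$values), 1e-11)
  }

  # with a dyadic wavelength and dyadic OPD values the invariance is exact
  # at the bit level
  optd <- optics_config(wavelength = 0.5)
  Ld <- matrix(sample.int(2^19, n * n) / 2^20, n, n)
  A <- matrix(runif(n * n, -0.2, 0), n, n)
  I1 <- predict_intensity(sample_maps(Ld, A, 1.67), optd)
  I2 <- predict_intensity(sample_maps(Ld + 2 * 0.5, A, 1.67), optd)
  expect_identical(I1$values, I2$values)
})
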