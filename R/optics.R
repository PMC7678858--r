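#' Optical configuration of a lens-free holographic setup
#'
#' Bundles the illumination and geometry parameters that govern image
#' formation: a quasi-monochromatic LED of finite size illuminates a thin
#' sample in suspension and the diffraction pattern (in-line hologram) is
#' recorded by a bare sensor a distance `sample_sensor_distance` behind it.
#' All lengths are in microns; intensity in grey levels.
#'
#' Defaults are the reference simulation parameters: wavelength
#' 0.450 um with 0.030 um full spectral width, a 50 um source 50 mm away,
#' sample-sensor distance 1270 um, 1.67 um pixel pitch and background 105
#' grey levels.
#'
#' @param wavelength central wavelength (um).
#' @param spectral_width full spectral width of the source (um).
#' @param source_diameter emitting diameter of the source (um); 0 for a
#'   point source.
#' @param source_sample_distance source to sample distance (um).
#' @param sample_sensor_distance sample to sensor distance Z (um).
#' @param pixel_pitch sensor pixel pitch (um).
#' @param background uniform illumination intensity B (grey levels).
#' @param n_spectral_samples number of wavelengths used when discretizing the
#'   spectrum for the partial-coherence kernel.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(wavelength = 0.450,
                          spectral_width = 0.030,
                          source_diameter = 50,
                          source_sample_distance = 50e3,
                          sample_sensor_distance = 1270,
                          pixel_pitch = 1.67,
                          background = 105,
                          n_spectral_samples = 5L) {
  stopifnot(wavelength > 0, spectral_width >= 0, source_diameter >= 0,
            source_sample_distance > 0, sample_sensor_distance != 0,
            pixel_pitch > 0, background > 0, n_spectral_samples >= 1)
  structure(list(
    wavelength = wavelength,
    spectral_width = spectral_width,
    source_diameter = source_diameter,
    source_sample_distance = source_sample_distance,
    sample_sensor_distance = sample_sensor_distance,
    pixel_pitch = pixel_pitch,
    background = background,
    n_spectral_samples = as.integer(n_spectral_samples)
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  wavelength      : %.4g um (+/- %.4g)\n",
              x$wavelength, x$spectral_width / 2))
  cat(sprintf("  source          : %.4g um diameter at %.4g mm\n",
              x$source_diameter, x$source_sample_distance / 1e3))
  cat(sprintf("  Z               : %.4g um\n", x$sample_sensor_distance))
  cat(sprintf("  pixel pitch     : %.4g um\n", x$pixel_pitch))
  cat(sprintf("  background B    : %.4g grey levels\n", x$background))
  invisible(x)
}

#' Paired object-plane maps: optical path difference and absorption
#'
#' The sample is modelled as a single 2D transmission plane described by two
#' real maps: `L`, the optical path difference (OPD, um) accumulated through
#' the object, and `A`, its negative absorption coefficient (dimensionless,
#' <= 0 for physical objects; reconstructions may transiently violate this).
#'
#' @param L 2D numeric matrix of OPD values (um).
#' @param A 2D numeric matrix of absorption values (dimensionless).
#' @param pixel_pitch pixel pitch (um).
#' @return object of class `sample_maps`.
#' @export
sample_maps <- function(L, A, pixel_pitch) {
  L <- as.matrix(L); A <- as.matrix(A)
  if (!identical(dim(L), dim(A))) stop("L and A must have identical shape")
  stopifnot(pixel_pitch > 0)
  structure(list(L = L, A = A, pixel_pitch = pixel_pitch),
            class = "sample_maps")
}

#' @export
print.sample_maps <- function(x, ...) {
  cat(sprintf("<sample_maps> %d x %d, pitch %.3g um, L in [%.3g, %.3g] um\n",
              nrow(x$L), ncol(x$L), x$pixel_pitch, min(x$L), max(x$L)))
  invisible(x)
}

#' Hologram intensity image
#'
#' @param values 2D numeric matrix of nonnegative intensities (grey levels).
#' @param pixel_pitch pixel pitch (um).
#' @return object of class `intensity_image`.
#' @export
intensity_image <- function(values, pixel_pitch) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("intensity values must be nonnegative")
  structure(list(values = values, pixel_pitch = pixel_pitch),
            class = "intensity_image")
}

#' Complex light field at a plane
#'
#' @param values 2D complex matrix (dimensionless amplitude).
#' @param pixel_pitch pixel pitch (um).
#' @return object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_pitch) {
  values <- as.matrix(values)
  stop_if_not_finite(c(Re(values), Im(values)), "field")
  structure(list(values = values, pixel_pitch = pixel_pitch),
            class = "complex_field")
}

#' Sample transmission field
#'
#' The complex field immediately after a thin transparent object is
#' `E = exp(2i*pi*L/lambda + A)`: the OPD map `L` delays the phase, the
#' absorption map `A` attenuates the amplitude. Because the phase enters
#' modulo 2*pi, any map `L + N*lambda` (integer `N`) produces the same
#' transmission - the origin of phase wrapping in the reconstruction.
#' The phase argument is reduced modulo one wave before exponentiation so
#' the invariance holds exactly in floating point whenever `L + N*lambda`
#' is exactly representable.
#'
#' @param maps a [sample_maps] object.
#' @param wavelength wavelength (um).
#' @return a [complex_field].
#' @export
transmission <- function(maps, wavelength) {
  stopifnot(inherits(maps, "sample_maps"), wavelength > 0)
  stop_if_not_finite(maps$L, "L")
  stop_if_not_finite(maps$A, "A")
  phase_cycles <- (maps$L / wavelength) %% 1
  complex_field(exp(maps$A + 2i * pi * phase_cycles), maps$pixel_pitch)
}

#' Fresnel propagation of a complex field
#'
#' Propagates a scalar field over a distance `Z` in the paraxial (Fresnel)
#' approximation, i.e. convolution with the Fresnel kernel
#' `h_Z(r) = 1/(i*lambda*Z) * exp(i*pi*r^2/(lambda*Z))`, evaluated
#' spectrally through its analytic transfer function
#' `H(f) = exp(-i*pi*lambda*Z*|f|^2)`. Negative `Z` back-propagates and is
#' the exact adjoint/inverse of the forward step. On the periodic FFT grid
#' the operator is exactly unitary, so energy is conserved to round-off;
#' `pad_factor > 1` optionally zero-pads before the transform to suppress
#' wrap-around of the diffracted field at the expense of exact unitarity.
#'
#' @param field a [complex_field].
#' @param Z propagation distance (um), nonzero; negative back-propagates.
#' @param wavelength wavelength (um).
#' @param pad_factor linear zero-padding factor (>= 1); default 1 (periodic).
#' @param on_alias what to do when the transfer function is undersampled for
#'   the requested geometry (`|Z| > N * pitch^2 / lambda`): one of
#'   `"ignore"`, `"warn"`, `"error"`.
#' @return a [complex_field] with the same shape and pitch.
#' @export
fresnel_propagate <- function(field, Z, wavelength, pad_factor = 1,
                              on_alias = c("ignore", "warn", "error")) {
  stopifnot(inherits(field, "complex_field"), Z != 0, wavelength > 0,
            pad_factor >= 1)
  on_alias <- match.arg(on_alias)
  u <- field$values
  pitch <- field$pixel_pitch
  n_min <- min(dim(u))
  z_max <- n_min * pitch^2 / wavelength
  if (abs(Z) > z_max && on_alias != "ignore") {
    msg <- sprintf(
      "Fresnel transfer function undersampled: |Z| = %.4g um exceeds N*pitch^2/lambda = %.4g um",
      abs(Z), z_max)
    if (on_alias == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  nr0 <- nrow(u); nc0 <- ncol(u)
  if (pad_factor > 1) {
    nr <- ceiling(nr0 * pad_factor); nc <- ceiling(nc0 * pad_factor)
    big <- matrix(0 + 0i, nr, nc)
    r0 <- floor((nr - nr0) / 2); c0 <- floor((nc - nc0) / 2)
    big[r0 + seq_len(nr0), c0 + seq_len(nc0)] <- u
    u <- big
  }
  fx <- fft_freq(ncol(u), pitch)
  fy <- fft_freq(nrow(u), pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  H <- exp(-1i * pi * wavelength * Z * f2)
  out <- stats::fft(stats::fft(u) * H, inverse = TRUE) / length(u)
  if (pad_factor > 1) {
    out <- out[r0 + seq_len(nr0), c0 + seq_len(nc0), drop = FALSE]
  }
  complex_field(out, pitch)
}

#' Partial-coherence convolution kernel
#'
#' A real LED source is neither a point nor monochromatic; both effects blur
#' the recorded hologram and are captured in the intensity model by a
#' convolution kernel `K`. `coherence_kernel()` derives `K` numerically from
#' two simulations of a Dirac (point) object: `I_total`, the hologram under
#' fully coherent monochromatic point-source illumination, and `I_partial`,
#' the weighted sum of holograms over a discretized source disc (whose
#' off-axis points shift the pattern by the geometrically demagnified offset
#' `Z / source_sample_distance`) and over `n_spectral_samples` wavelengths
#' spanning the spectral width. `K` is the regularized (Wiener-floor)
#' deconvolution of `I_partial` by `I_total`, clipped to nonnegative values
#' and normalized to unit sum.
#'
#' @param config an [optics_config].
#' @param grid_shape integer vector `c(nrow, ncol)` of the simulation grid.
#' @return object of class `coherence_kernel`: a nonnegative map summing to
#'   one whose origin sits at the geometric image centre.
#' @export
coherence_kernel <- function(config, grid_shape) {
  stopifnot(inherits(config, "optics_config"), length(grid_shape) == 2)
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  pitch <- config$pixel_pitch
  Z <- config$sample_sensor_distance
  coherent <- config$source_diameter == 0 &&
    (config$spectral_width == 0 || config$n_spectral_samples == 1L)
  if (coherent) return(dirac_kernel(c(nr, nc), pitch))

  # The Dirac object is an opaque point on the unit illumination background
  # (a bare delta field would propagate to a structureless uniform
  # intensity); its hologram carries the Fresnel ring system whose blurring
  # encodes the source coherence.
  dirac_obj <- matrix(1 + 0i, nr, nc)
  dirac_obj[center_index(nr), center_index(nc)] <- 0 + 0i
  point_intensity <- function(lambda) {
    u <- fresnel_propagate(complex_field(dirac_obj, pitch), Z, lambda)
    Mod(u$values)^2
  }

  I_total <- point_intensity(config$wavelength)

  if (config$spectral_width > 0 && config$n_spectral_samples > 1L) {
    lambdas <- seq(config$wavelength - config$spectral_width / 2,
                   config$wavelength + config$spectral_width / 2,
                   length.out = config$n_spectral_samples)
  } else {
    lambdas <- config$wavelength
  }
  # Source disc as <= 9 points: the axial point plus 8 on the ring of radius
  # R/sqrt(2), which preserves the second moment of a uniform disc.
  if (config$source_diameter > 0) {
    rr <- config$source_diameter / 2 / sqrt(2)
    th <- 2 * pi * (0:7) / 8
    src <- rbind(c(0, 0), cbind(rr * cos(th), rr * sin(th)))
  } else {
    src <- matrix(0, 1, 2)
  }
  demag <- Z / config$source_sample_distance

  fx <- fft_freq(nc, pitch)
  fy <- fft_freq(nr, pitch)
  I_partial <- matrix(0, nr, nc)
  for (lam in lambdas) {
    I_lam <- point_intensity(lam)
    Ihat <- stats::fft(I_lam)
    for (s in seq_len(nrow(src))) {
      dx <- -src[s, 1] * demag   # source offset shifts the image oppositely
      dy <- -src[s, 2] * demag
      ramp <- exp(-2i * pi * outer(fy * dy, fx * dx, `+`))
      I_partial <- I_partial +
        Re(stats::fft(Ihat * ramp, inverse = TRUE)) / (nr * nc)
    }
  }
  I_partial <- I_partial / nrow(src) / length(lambdas)

  # Deconvolve the ring systems with the uniform background removed: the
  # DC term would otherwise dominate the Wiener floor and drown the
  # structure that actually encodes the source blur. A flux-preserving
  # kernel has unit DC gain, restored explicitly.
  Ft <- stats::fft(I_total - mean(I_total))
  Fp <- stats::fft(I_partial - mean(I_partial))
  eps <- 1e-3 * max(Mod(Ft))
  Khat <- Fp * Conj(Ft) / (Mod(Ft)^2 + eps^2)
  Khat[1, 1] <- 1
  K <- Re(stats::fft(Khat, inverse = TRUE)) / (nr * nc)
  K <- fftshift2(K)
  # cleanup: clip deconvolution residuals (negatives and the diffuse noise
  # floor below 1% of the peak), then renormalize to a probability kernel
  K[K < 0] <- 0
  K[K < 0.01 * max(K)] <- 0
  K <- K / sum(K)
  structure(list(values = K, pixel_pitch = pitch), class = "coherence_kernel")
}

#' Discrete Dirac kernel (fully coherent illumination)
#'
#' @param grid_shape integer vector `c(nrow, ncol)`.
#' @param pixel_pitch pixel pitch (um).
#' @return a `coherence_kernel` with a single 1 at the centre pixel.
#' @export
dirac_kernel <- function(grid_shape, pixel_pitch) {
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  K <- matrix(0, nr, nc)
  K[center_index(nr), center_index(nc)] <- 1
  structure(list(values = K, pixel_pitch = pixel_pitch),
            class = "coherence_kernel")
}

#' Isotropic Gaussian coherence kernel
#'
#' Simulation dialect of the partial-coherence kernel: a normalized
#' isotropic Gaussian of given full width at half maximum sampled on the
#' pixel grid (the reference simulations use FWHM 1.75 um). Useful as a
#' cheap, controlled stand-in for the physically derived kernel.
#'
#' @param fwhm full width at half maximum (um).
#' @param pixel_pitch pixel pitch (um).
#' @param grid_shape integer vector `c(nrow, ncol)`.
#' @return a `coherence_kernel`.
#' @export
gaussian_kernel <- function(fwhm = 1.75, pixel_pitch = 1.67,
                            grid_shape = c(31L, 31L)) {
  stopifnot(fwhm > 0, pixel_pitch > 0)
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- (seq_len(nr) - center_index(nr)) * pixel_pitch
  x <- (seq_len(nc) - center_index(nc)) * pixel_pitch
  K <- exp(-outer(y^2, x^2, `+`) / (2 * sigma^2))
  K <- K / sum(K)
  structure(list(values = K, pixel_pitch = pixel_pitch),
            class = "coherence_kernel")
}

is_dirac_kernel <- function(K) {
  v <- K$values
  sum(v != 0) == 1L &&
    v[center_index(nrow(v)), center_index(ncol(v))] == 1
}

# Embed a small centred kernel into a larger centred grid (for convolution
# with an image of different shape).
embed_kernel <- function(K, grid_shape) {
  v <- K$values
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  if (all(dim(v) == c(nr, nc))) return(v)
  if (nrow(v) > nr || ncol(v) > nc) stop("kernel larger than image grid")
  big <- matrix(0, nr, nc)
  r0 <- center_index(nr) - center_index(nrow(v))
  c0 <- center_index(nc) - center_index(ncol(v))
  big[r0 + seq_len(nrow(v)), c0 + seq_len(ncol(v))] <- v
  big
}

#' Predicted hologram intensity
#'
#' The forward model of lens-free image formation: the object transmission
#' `E(L, A)` is Fresnel-propagated to the sensor plane, its squared modulus
#' is blurred by the partial-coherence kernel `K`, and scaled by the uniform
#' background `B`:
#' `I(L, A) = B * (|E(L, A) * h_Z|^2 * K)`.
#' With `K = NULL` (or an exact Dirac) the coherence convolution is skipped
#' entirely, so the fully coherent model is reproduced bit-for-bit.
#'
#' @param maps a [sample_maps] object.
#' @param config an [optics_config].
#' @param K a `coherence_kernel`, or `NULL` for fully coherent imaging.
#' @return an [intensity_image] of predicted grey levels.
#' @export
predict_intensity <- function(maps, config, K = NULL) {
  stopifnot(inherits(maps, "sample_maps"), inherits(config, "optics_config"))
  if (!is.null(K) && abs(K$pixel_pitch - maps$pixel_pitch) > 1e-9) {
    stop("maps and kernel pixel pitch differ")
  }
  E <- transmission(maps, config$wavelength)
  U <- fresnel_propagate(E, config$sample_sensor_distance, config$wavelength)
  I0 <- Mod(U$values)^2
  if (!is.null(K) && !is_dirac_kernel(K)) {
    Kfull <- embed_kernel(K, dim(I0))
    I0 <- conv_centered(I0, Kfull)
    I0[I0 < 0] <- 0   # FFT round-off can leave tiny negatives
  }
  intensity_image(config$background * I0, maps$pixel_pitch)
}
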