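#' Simulation parameter ranges for sphere-cell phantoms
#'
#' Cells in suspension are modelled as homogeneous spheres with a complex
#' refractive-index contrast to the medium. Defaults are the reference
#' simulation ranges: 500-5000 cells per 1000 x 1000 image, radii 5-20 um,
#' real index contrast 0.01-0.05, imaginary contrast 0-0.005, per-image
#' jitter of +/-5% on the sample-sensor distance and +/-30% on the
#' background.
#'
#' @param n_cells_range integer range `c(min, max)` of cells per scene.
#' @param radius_range radius range (um).
#' @param dnr_range range of the real refractive-index contrast.
#' @param dni_range range of the imaginary refractive-index contrast.
#' @param z_jitter relative half-width of the per-image Z jitter.
#' @param background_jitter relative half-width of the per-image B jitter.
#' @param seed optional integer seed applied by [sample_scene()].
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_cells_range = c(500L, 5000L),
                       radius_range = c(5, 20),
                       dnr_range = c(0.01, 0.05),
                       dni_range = c(0, 0.005),
                       z_jitter = 0.05,
                       background_jitter = 0.30,
                       seed = NULL) {
  ranges <- list(n_cells_range = n_cells_range, radius_range = radius_range,
                 dnr_range = dnr_range, dni_range = dni_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop(nm, " must be an ordered pair")
  }
  stopifnot(radius_range[1] > 0, dnr_range[1] >= 0, dni_range[1] >= 0,
            z_jitter >= 0, background_jitter >= 0)
  structure(list(n_cells_range = as.integer(n_cells_range),
                 radius_range = radius_range, dnr_range = dnr_range,
                 dni_range = dni_range, z_jitter = z_jitter,
                 background_jitter = background_jitter, seed = seed),
            class = "sim_params")
}

#' Draw a random scene of spherical cells
#'
#' The cell count is uniform on its integer range, radii and index contrasts
#' are i.i.d. uniform on their ranges, and centres are uniform over the
#' field of view. Overlapping spheres are permitted (their projected
#' thicknesses add); cells may straddle the border.
#'
#' @param params a [sim_params] object.
#' @param grid_shape integer vector `c(nrow, ncol)` in pixels.
#' @param pixel_pitch pixel pitch (um).
#' @return object of class `scene_phantom`: a data frame of cells
#'   (`x`, `y`, `r`, `dnr`, `dni`, in um where applicable) plus grid
#'   geometry.
#' @export
sample_scene <- function(params, grid_shape, pixel_pitch) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  n <- if (params$n_cells_range[1] == params$n_cells_range[2]) {
    params$n_cells_range[1]
  } else {
    sample(params$n_cells_range[1]:params$n_cells_range[2], 1L)
  }
  runif2 <- function(k, r) if (r[1] == r[2]) rep(r[1], k) else runif(k, r[1], r[2])
  cells <- data.frame(
    x = runif(n, 0, nc * pixel_pitch),
    y = runif(n, 0, nr * pixel_pitch),
    r = runif2(n, params$radius_range),
    dnr = runif2(n, params$dnr_range),
    dni = runif2(n, params$dni_range)
  )
  structure(list(cells = cells, grid_shape = c(nr, nc),
                 pixel_pitch = pixel_pitch), class = "scene_phantom")
}

#' @export
print.scene_phantom <- function(x, ...) {
  cat(sprintf("<scene_phantom> %d cells on %d x %d px (%.3g um pitch), %d cells/mm^2\n",
              nrow(x$cells), x$grid_shape[1], x$grid_shape[2], x$pixel_pitch,
              surface_density(nrow(x$cells), x$grid_shape, x$pixel_pitch)))
  invisible(x)
}

#' Render a sphere-cell scene to OPD and absorption maps
#'
#' In the projection approximation a homogeneous sphere of radius `r`
#' contributes its chord thickness `T = 2*sqrt(r^2 - d^2)` at in-plane
#' distance `d` from its centre; thicknesses of overlapping cells add. The
#' optical path difference and absorption maps follow as
#' `L = sum_k T_k * dnr_k` and `A = -(2*pi/lambda) * sum_k T_k * dni_k`.
#' Pixel centres sit at `(index - 0.5) * pitch`.
#'
#' @param scene a [sample_scene()] result.
#' @param wavelength wavelength (um), needed for the absorption map.
#' @return a [sample_maps] object with `L >= 0` and `A <= 0`.
#' @export
render_maps <- function(scene, wavelength) {
  stopifnot(inherits(scene, "scene_phantom"), wavelength > 0)
  nr <- scene$grid_shape[1]; nc <- scene$grid_shape[2]
  pitch <- scene$pixel_pitch
  L <- matrix(0, nr, nc)
  TA <- matrix(0, nr, nc)   # thickness weighted by dni
  xs <- (seq_len(nc) - 0.5) * pitch
  ys <- (seq_len(nr) - 0.5) * pitch
  cells <- scene$cells
  for (k in seq_len(nrow(cells))) {
    cx <- cells$x[k]; cy <- cells$y[k]; r <- cells$r[k]
    ci <- which(xs >= cx - r & xs <= cx + r)
    ri <- which(ys >= cy - r & ys <= cy + r)
    if (!length(ci) || !length(ri)) next
    d2 <- outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, `+`)
    Tk <- matrix(0, length(ri), length(ci))
    inside <- d2 < r^2
    Tk[inside] <- 2 * sqrt(r^2 - d2[inside])
    L[ri, ci] <- L[ri, ci] + Tk * cells$dnr[k]
    TA[ri, ci] <- TA[ri, ci] + Tk * cells$dni[k]
  }
  A <- -(2 * pi / wavelength) * TA
  sample_maps(L, A, pitch)
}

#' Simulate a noisy hologram of a sample
#'
#' Evaluates the forward model and adds Poisson shot noise, interpreting
#' grey levels as photo-electron counts: each pixel is a Poisson draw whose
#' mean is the predicted intensity.
#'
#' @param maps a [sample_maps] object.
#' @param config an [optics_config].
#' @param K a `coherence_kernel` or `NULL` (coherent model).
#' @return an [intensity_image] of noisy grey levels.
#' @export
simulate_hologram <- function(maps, config, K = NULL) {
  I_mean <- predict_intensity(maps, config, K)
  stopifnot(all(I_mean$values >= 0))
  noisy <- matrix(rpois(length(I_mean$values), I_mean$values),
                  nrow(I_mean$values), ncol(I_mean$values))
  intensity_image(noisy, maps$pixel_pitch)
}

#' Surface density of cells
#'
#' Number of cells divided by the physical image area, truncated (floored)
#' to an integer number of cells per square millimetre. On the reference
#' 1000 x 1000 grid at 1.67 um pitch, 1001 cells give 358 cells/mm^2 and
#' 5000 give 1792.
#'
#' @param n_cells cell count.
#' @param grid_shape integer vector `c(nrow, ncol)` in pixels.
#' @param pixel_pitch pixel pitch (um).
#' @return integer density in cells/mm^2.
#' @export
surface_density <- function(n_cells, grid_shape, pixel_pitch) {
  stopifnot(n_cells >= 0, pixel_pitch > 0)
  area_mm2 <- (grid_shape[1] * pixel_pitch * 1e-3) *
    (grid_shape[2] * pixel_pitch * 1e-3)
  as.integer(floor(n_cells / area_mm2))
}

#' Build a phase-unwrapping training set
#'
#' For each image: draw a scene, render ground-truth maps, simulate a noisy
#' hologram with per-image jitter on `Z` (uniform within `z_jitter`) and on
#' the background `B` (uniform within `background_jitter`), then run the
#' first (fast, coherent, wrapping-prone) reconstruction. Each element pairs
#' that reconstruction (network input) with the ground truth (target).
#'
#' @param n_images number of image pairs.
#' @param params a [sim_params] object.
#' @param config an [optics_config] (nominal values; jitter is applied
#'   around `sample_sensor_distance` and `background`).
#' @param grid_shape image shape in pixels.
#' @param K coherence kernel used for simulation (default the Gaussian
#'   simulation kernel, FWHM 1.75 um); the first reconstruction always uses
#'   the coherent (Dirac) model.
#' @param solver_config optional [solver_config] overriding the stage-1
#'   defaults for the reconstruction step.
#' @return list of training pairs, each a list with `input` and `target`
#'   [sample_maps] plus `meta` (`Z`, `B`, `n_cells`, `converged`).
#' @export
build_training_set <- function(n_images, params, config,
                               grid_shape = c(1000L, 1000L),
                               K = gaussian_kernel(1.75, config$pixel_pitch),
                               solver_config = NULL) {
  stopifnot(n_images >= 1)
  pairs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    scene <- sample_scene(params, grid_shape, config$pixel_pitch)
    truth <- render_maps(scene, config$wavelength)
    cfg_i <- config
    cfg_i$sample_sensor_distance <- config$sample_sensor_distance *
      runif(1, 1 - params$z_jitter, 1 + params$z_jitter)
    cfg_i$background <- config$background *
      runif(1, 1 - params$background_jitter, 1 + params$background_jitter)
    holo <- simulate_hologram(truth, cfg_i, K)
    rec <- first_reconstruction(holo, cfg_i, config = solver_config)
    pairs[[i]] <- list(
      input = rec$maps, target = truth, scene = scene,
      meta = list(Z = cfg_i$sample_sensor_distance, B = cfg_i$background,
                  n_cells = nrow(scene$cells),
                  converged = all(is.finite(rec$maps$L)) &&
                    all(is.finite(rec$maps$A)))
    )
  }
  pairs
}

#' Extract random vignette crops from training pairs
#'
#' Draws `n` axis-aligned square crops at random positions from randomly
#' chosen pairs; the identical window is applied to input and target so the
#' pair stays registered. The reference training protocol uses 121 x 121
#' vignettes.
#'
#' @param pairs list of training pairs from [build_training_set()].
#' @param size crop side length in pixels (default 121).
#' @param n number of vignettes to draw.
#' @return list of vignette pairs (`input`, `target` [sample_maps]).
#' @export
extract_vignettes <- function(pairs, size = 121L, n = 1L) {
  stopifnot(length(pairs) >= 1, n >= 1)
  dims <- dim(pairs[[1]]$input$L)
  if (size > min(dims)) stop("vignette size exceeds image size")
  out <- vector("list", n)
  idx <- sample.int(length(pairs), n, replace = TRUE)
  r_off <- sample.int(dims[1] - size + 1L, n, replace = TRUE) - 1L
  c_off <- sample.int(dims[2] - size + 1L, n, replace = TRUE) - 1L
  for (i in seq_len(n)) {
    p <- pairs[[idx[i]]]
    rs <- r_off[i] + seq_len(size)
    cs <- c_off[i] + seq_len(size)
    out[[i]] <- list(
      input = sample_maps(p$input$L[rs, cs], p$input$A[rs, cs],
                          p$input$pixel_pitch),
      target = sample_maps(p$target$L[rs, cs], p$target$A[rs, cs],
                           p$target$pixel_pitch)
    )
  }
  out
}
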