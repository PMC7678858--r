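#' Peak signal-to-noise ratio between a reconstruction and ground truth
#'
#' `PSNR = 10 * log10(data_range^2 / MSE)` in decibels. Identical maps
#' (MSE = 0) are reported as the `cap` sentinel rather than infinity.
#'
#' @param recon reconstructed 2D map (matrix).
#' @param truth ground-truth 2D map, same shape.
#' @param data_range dynamic range of the signal; default `max(truth)`.
#' @param cap value returned for an exact match (dB).
#' @return PSNR in dB.
#' @export
psnr <- function(recon, truth, data_range = max(truth), cap = 120) {
  stopifnot(identical(dim(as.matrix(recon)), dim(as.matrix(truth))),
            data_range > 0)
  mse <- mean((recon - truth)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(data_range^2 / mse))
}

#' Recover per-cell refractive-index contrasts from reconstructed maps
#'
#' For each phantom cell `k` with known centre and radius, the reconstructed
#' maps are integrated over the disc `S` of that radius (pixel-centre
#' membership, pixel-area weighting) and normalized by the sphere volume
#' `V = (4/3) * pi * r^3`:
#' `dnr = (1/V) * integral_S L`,  `dni = -lambda/(2*pi*V) * integral_S A`.
#' On ground-truth maps of an isolated sphere this recovers the true
#' contrasts up to pixelization error (the chord integral over the disc is
#' exactly the sphere volume).
#'
#' @param maps reconstructed (or ground-truth) [sample_maps].
#' @param scene the [sample_scene()] phantom providing true geometry and
#'   contrasts.
#' @param wavelength wavelength (um).
#' @return data frame of class `cell_recovery` with one row per evaluable
#'   cell: `cell`, `x`, `y`, `r`, `dnr_true`, `dnr_recons`, `dni_true`,
#'   `dni_recons`. Cells whose disc lies fully outside the field are
#'   skipped; their indices are kept in the `skipped` attribute.
#' @export
refractive_index_recovery <- function(maps, scene, wavelength) {
  stopifnot(inherits(maps, "sample_maps"), inherits(scene, "scene_phantom"))
  pitch <- maps$pixel_pitch
  nr <- nrow(maps$L); nc <- ncol(maps$L)
  xs <- (seq_len(nc) - 0.5) * pitch
  ys <- (seq_len(nr) - 0.5) * pitch
  cells <- scene$cells
  rows <- vector("list", nrow(cells))
  skipped <- integer(0)
  for (k in seq_len(nrow(cells))) {
    cx <- cells$x[k]; cy <- cells$y[k]; r <- cells$r[k]
    ci <- which(xs >= cx - r & xs <= cx + r)
    ri <- which(ys >= cy - r & ys <= cy + r)
    if (!length(ci) || !length(ri)) {
      skipped <- c(skipped, k)
      next
    }
    inside <- outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, `+`) <= r^2
    if (!any(inside)) {
      skipped <- c(skipped, k)
      next
    }
    V <- 4 / 3 * pi * r^3
    sL <- sum(maps$L[ri, ci][inside]) * pitch^2
    sA <- sum(maps$A[ri, ci][inside]) * pitch^2
    rows[[k]] <- data.frame(
      cell = k, x = cx, y = cy, r = r,
      dnr_true = cells$dnr[k], dnr_recons = sL / V,
      dni_true = cells$dni[k],
      dni_recons = -wavelength / (2 * pi) * sA / V
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  attr(out, "skipped") <- skipped
  class(out) <- c("cell_recovery", class(out))
  out
}

#' Ordinary least-squares summary of recovered versus true values
#'
#' Fits `recovered ~ true` with intercept and reports slope, intercept,
#' coefficient of determination and the number of points. A perfect
#' reconstruction gives slope 1 and R-squared 1.
#'
#' @param x_true true values.
#' @param y_recons recovered values, same length.
#' @return object of class `regression_summary` with fields `slope`,
#'   `intercept`, `r_squared`, `n_points`. Degenerate predictors (zero
#'   variance) yield `NA` slope with a `degenerate` flag.
#' @export
regression_summary <- function(x_true, y_recons) {
  stopifnot(length(x_true) == length(y_recons), length(x_true) >= 3)
  if (stats::var(x_true) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_points = length(x_true),
                          degenerate = TRUE),
                     class = "regression_summary"))
  }
  fit <- stats::lm(y_recons ~ x_true)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y_recons - mean(y_recons))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(x_true), degenerate = FALSE),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("<regression_summary> slope %.3f, intercept %.3g, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Per-component regressions of a cell-recovery table
#'
#' @param recoveries a [refractive_index_recovery()] result.
#' @return list with `dnr` and `dni` [regression_summary] objects.
#' @export
recovery_regression <- function(recoveries) {
  list(dnr = regression_summary(recoveries$dnr_true, recoveries$dnr_recons),
       dni = regression_summary(recoveries$dni_true, recoveries$dni_recons))
}

#' Phase shift in units of pi
#'
#' The phase delay `2*pi*L/lambda` of an optical path difference, expressed
#' in multiples of pi: `2*L/lambda`. A 1000 nm OPD at 405 nm is a shift of
#' about 5 pi.
#'
#' @param L optical path difference (any length unit).
#' @param wavelength wavelength (same unit).
#' @return phase shift in units of pi.
#' @export
phase_shift_in_pi <- function(L, wavelength) {
  stopifnot(wavelength > 0)
  2 * L / wavelength
}

#' Convert a surface cell density to a volumetric density
#'
#' For cells confined in a chamber of known thickness, a surface density in
#' cells/mm^2 divided by the thickness in um is numerically the volumetric
#' density in 10^6 cells/ml (1140 cells/mm^2 in a 20 um chamber is
#' 57 x 10^6 cells/ml).
#'
#' @param density surface density (cells/mm^2).
#' @param thickness chamber thickness (um).
#' @return volumetric density in 10^6 cells/ml.
#' @export
surface_to_volumetric <- function(density, thickness) {
  stopifnot(density >= 0, thickness > 0)
  density / thickness
}
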