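#' Configuration of the three-step alternation pipeline
#'
#' @param optics an [optics_config].
#' @param model a trained `unwrap_net`.
#' @param stage1 [solver_config] for the first reconstruction.
#' @param stage2 [solver_config] for the final reconstruction.
#' @param kernel coherence kernel used by the final reconstruction (default
#'   the Gaussian simulation kernel, FWHM 1.75 um).
#' @param z_tolerance maximum relative mismatch tolerated between the
#'   model's training Z and `optics$sample_sensor_distance` (default 5%,
#'   the simulation's own Z jitter band); beyond it the pipeline refuses to
#'   run, since the unwrapper is trained per distance.
#' @param output_dir optional directory; when set, intermediate maps and the
#'   convergence log are written there.
#' @param save_intermediates write stage outputs when `output_dir` is set.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(optics, model,
                            stage1 = solver_config("first"),
                            stage2 = solver_config("second"),
                            kernel = gaussian_kernel(1.75, optics$pixel_pitch),
                            z_tolerance = 0.05,
                            output_dir = NULL,
                            save_intermediates = FALSE) {
  stopifnot(inherits(optics, "optics_config"), inherits(model, "unwrap_net"),
            z_tolerance >= 0)
  structure(list(optics = optics, model = model, stage1 = stage1,
                 stage2 = stage2, kernel = kernel,
                 z_tolerance = z_tolerance, output_dir = output_dir,
                 save_intermediates = save_intermediates),
            class = "pipeline_config")
}

#' Run the three-step alternation reconstruction
#'
#' The alternation scheme: (1) a fast variational reconstruction from a null
#' sample with the coherent model, which is accurate in data terms but
#' carries phase-wrapping artefacts wherever the true OPD exceeds half a
#' wavelength; (2) the trained fully-convolutional network maps the wrapped
#' `(L, A)` maps to an unwrapped prediction; (3) a longer variational
#' reconstruction initialized at the prediction, with the partial-coherence
#' kernel and the OPD-domain regularizer, pulls the prediction back into
#' agreement with the measured hologram (its data fidelity can only decrease
#' from the initialization).
#'
#' @param I_meas measured [intensity_image] hologram.
#' @param config a [pipeline_config].
#' @return object of class `pipeline_result` with `first`, `predicted`,
#'   `final`, and a combined convergence `log` (stage, iteration, fidelity,
#'   regularization, total).
#' @export
run_alternation <- function(I_meas, config) {
  stopifnot(inherits(config, "pipeline_config"))
  optics <- config$optics
  model <- config$model
  if (is.finite(model$training_Z)) {
    mismatch <- abs(model$training_Z - optics$sample_sensor_distance) /
      optics$sample_sensor_distance
    if (mismatch > config$z_tolerance) {
      stop(sprintf(
        "model trained for Z = %.4g um but optics Z = %.4g um (%.1f%% > %.1f%% tolerance); train a network for this distance",
        model$training_Z, optics$sample_sensor_distance, 100 * mismatch,
        100 * config$z_tolerance), call. = FALSE)
    }
  }
  first <- first_reconstruction(I_meas, optics, config = config$stage1)
  predicted <- predict(model, first$maps)
  final <- second_reconstruction(I_meas, predicted, optics,
                                 K = config$kernel, config = config$stage2)
  log <- rbind(
    cbind(stage = "first", first$history),
    cbind(stage = "final", final$history)
  )
  res <- structure(list(first = first, predicted = predicted, final = final,
                        log = log, optics = optics,
                        provenance = list(
                          stage1 = config$stage1, stage2 = config$stage2,
                          z_tolerance = config$z_tolerance,
                          model_training_Z = model$training_Z,
                          package_version =
                            as.character(utils::packageVersion("holocell")))),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(log, file.path(config$output_dir, "convergence.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (config$save_intermediates) {
      write_map(first$maps$L, file.path(config$output_dir, "first_L.txt"),
                first$maps$pixel_pitch)
      write_map(first$maps$A, file.path(config$output_dir, "first_A.txt"),
                first$maps$pixel_pitch)
      write_map(predicted$L, file.path(config$output_dir, "predicted_L.txt"),
                predicted$pixel_pitch)
      write_map(predicted$A, file.path(config$output_dir, "predicted_A.txt"),
                predicted$pixel_pitch)
    }
    write_map(final$maps$L, file.path(config$output_dir, "final_L.txt"),
              final$maps$pixel_pitch)
    write_map(final$maps$A, file.path(config$output_dir, "final_A.txt"),
              final$maps$pixel_pitch)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  f1 <- x$first$history
  f3 <- x$final$history
  cat("<pipeline_result>\n")
  cat(sprintf("  first  : %d iters, fidelity %.5g -> %.5g\n",
              x$first$n_iterations_run, f1$fidelity[1],
              f1$fidelity[nrow(f1)]))
  cat(sprintf("  network: max L %.3g -> %.3g um\n",
              max(x$first$maps$L), max(x$predicted$L)))
  cat(sprintf("  final  : %d iters, fidelity %.5g -> %.5g\n",
              x$final$n_iterations_run, f3$fidelity[1],
              f3$fidelity[nrow(f3)]))
  invisible(x)
}

#' Simulated validation experiment across scenes
#'
#' For each scene: draw a phantom, simulate its noisy hologram, run the full
#' alternation, and evaluate all three stages against the ground truth
#' (per-cell refractive-index recovery, per-component regression slopes and
#' R-squared, and OPD-channel PSNR). Returns per-stage summaries analogous
#' to the quantitative validation of the method on simulated data.
#'
#' @param params a [sim_params].
#' @param config a [pipeline_config].
#' @param n_scenes number of scenes.
#' @param grid_shape image shape in pixels.
#' @return object of class `validation_report`: a data frame `summary` with
#'   one row per (scene, stage) holding density, PSNR, slopes, R-squared and
#'   data fidelity, plus the per-scene recovery tables in `recoveries`.
#' @export
run_validation_experiment <- function(params, config, n_scenes = 1L,
                                      grid_shape = c(256L, 256L)) {
  optics <- config$optics
  rows <- list()
  recoveries <- list()
  for (sc in seq_len(n_scenes)) {
    scene <- sample_scene(params, grid_shape, optics$pixel_pitch)
    truth <- render_maps(scene, optics$wavelength)
    holo <- simulate_hologram(truth, optics, config$kernel)
    res <- run_alternation(holo, config)
    stages <- list(first = res$first$maps, cnn = res$predicted,
                   final = res$final$maps)
    fidelity <- c(
      first = res$first$history$fidelity[nrow(res$first$history)],
      cnn = res$final$history$fidelity[1],   # evaluated at the prediction
      final = res$final$history$fidelity[nrow(res$final$history)]
    )
    recoveries[[sc]] <- list()
    for (st in names(stages)) {
      rec <- refractive_index_recovery(stages[[st]], scene,
                                       optics$wavelength)
      recoveries[[sc]][[st]] <- rec
      regs <- if (nrow(rec) >= 3) recovery_regression(rec) else
        list(dnr = list(slope = NA, r_squared = NA),
             dni = list(slope = NA, r_squared = NA))
      rows[[length(rows) + 1L]] <- data.frame(
        scene = sc, stage = st,
        n_cells = nrow(scene$cells),
        density = surface_density(nrow(scene$cells), grid_shape,
                                  optics$pixel_pitch),
        psnr_L = psnr(stages[[st]]$L, truth$L),
        slope_dnr = regs$dnr$slope, r2_dnr = regs$dnr$r_squared,
        slope_dni = regs$dni$slope, r2_dni = regs$dni$r_squared,
        fidelity = unname(fidelity[st])
      )
    }
  }
  structure(list(summary = do.call(rbind, rows), recoveries = recoveries),
            class = "validation_report")
}
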