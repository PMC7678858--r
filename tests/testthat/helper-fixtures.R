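# Shared fixtures: small optics and deterministic phantoms built in code.

table1_optics <- function(...) optics_config(...)

# A single spherical cell centred on a pixel centre of an n x n grid.
single_cell_scene <- function(n, r, dnr, dni, optics = table1_optics(),
                              at = NULL) {
  pitch <- optics$pixel_pitch
  if (is.null(at)) {
    ij <- floor(n / 2) + 1L
    at <- c((ij - 0.5) * pitch, (ij - 0.5) * pitch)
  }
  structure(list(
    cells = data.frame(x = at[1], y = at[2], r = r, dnr = dnr, dni = dni),
    grid_shape = c(n, n), pixel_pitch = pitch
  ), class = "scene_phantom")
}

zero_maps <- function(n, pitch = 1.67) {
  sample_maps(matrix(0, n, n), matrix(0, n, n), pitch)
}

random_maps <- function(n, pitch = 1.67, l_max = 1, a_min = -0.3) {
  sample_maps(matrix(runif(n * n, 0, l_max), n, n),
              matrix(runif(n * n, a_min, 0), n, n), pitch)
}

# A network whose output is identically zero: final conv weights and biases
# nulled. Deterministic stand-in where pipeline tests need a predictor but
# not a trained one.
zero_network <- function(training_Z = NA_real_) {
  net <- build_network(network_spec(n_blocks = 1L, kernel_size = 3L,
                                    n_features = 2L, scale = "reduced"))
  net$final$W[] <- 0
  net$final$b[] <- 0
  net$trained <- TRUE
  net$training_Z <- training_Z
  net
}

# Reduced-size solver settings for orchestration smoke tests.
quick_solver <- function(stage, n_iterations = 3L) {
  solver_config(stage, n_iterations = n_iterations)
}
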