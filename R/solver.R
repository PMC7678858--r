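#' Inverse-solver configuration
#'
#' Controls the regularized variational reconstruction. The criterion is
#' `fidelity + alpha * zeta` where the fidelity is the intensity-weighted
#' squared residual between the forward model and the measured hologram and
#' `zeta` is the stage regularizer: stage `"first"` applies total variation
#' to the complex transmission field (insensitive to wavelength jumps of the
#' OPD), an OPD sparsity term and a one-sided absorption penalty; stage
#' `"second"` applies total variation directly to the OPD (assumed unwrapped
#' by then), OPD sparsity, an absorption smoothness (Laplacian) term and
#' one-sided penalties keeping `A <= 0` and `L >= 0`.
#'
#' @param stage `"first"` or `"second"`.
#' @param n_iterations conjugate-gradient iterations; defaults 20 (first
#'   stage) and 70 (second stage).
#' @param alpha global regularization weight. The default (4) was fixed once
#'   by balancing `alpha * zeta` at the ground truth against ~10% of the
#'   initial fidelity on a reference phantom.
#' @param tv_epsilon smoothing of the non-differentiable magnitudes,
#'   `sqrt(x^2 + eps^2)`.
#' @param fidelity_floor floor (grey levels) for the `1/I_meas` weight.
#' @param ls_factor,ls_c1,ls_max Armijo backtracking line-search parameters:
#'   shrink factor, sufficient-decrease constant, maximum trials.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(stage = c("first", "second"),
                          n_iterations = NULL,
                          alpha = 4,
                          tv_epsilon = 1e-3,
                          fidelity_floor = 1,
                          ls_factor = 0.5, ls_c1 = 1e-4, ls_max = 20L) {
  stage <- match.arg(stage)
  if (is.null(n_iterations)) n_iterations <- if (stage == "first") 20L else 70L
  stopifnot(n_iterations >= 1, alpha >= 0, tv_epsilon > 0,
            fidelity_floor > 0, ls_factor > 0, ls_factor < 1, ls_max >= 1)
  structure(list(stage = stage, n_iterations = as.integer(n_iterations),
                 alpha = alpha, tv_epsilon = tv_epsilon,
                 fidelity_floor = fidelity_floor,
                 ls_factor = ls_factor, ls_c1 = ls_c1,
                 ls_max = as.integer(ls_max)),
            class = "solver_config")
}

#' Data-fidelity term of the reconstruction criterion
#'
#' Sum over pixels of `(I_model - I_meas)^2 / I_meas`, the chi-square-like
#' discrepancy between the forward model and the measured hologram. Measured
#' pixels below `floor` grey levels are clamped in the weight (and counted
#' in the `n_floored` attribute) to keep the weight finite.
#'
#' @param maps candidate [sample_maps].
#' @param I_meas measured [intensity_image].
#' @param config an [optics_config].
#' @param K coherence kernel or `NULL`.
#' @param floor weight floor in grey levels.
#' @return nonnegative scalar; zero iff the model fits exactly.
#' @export
data_fidelity <- function(maps, I_meas, config, K = NULL, floor = 1) {
  stopifnot(identical(dim(maps$L), dim(I_meas$values)))
  I_model <- predict_intensity(maps, config, K)
  w <- pmax(I_meas$values, floor)
  val <- sum((I_model$values - I_meas$values)^2 / w)
  attr(val, "n_floored") <- sum(I_meas$values < floor)
  val
}

# Smoothed magnitude sqrt(x^2 + eps^2) summed over a matrix.
smooth_abs_sum <- function(x, eps) sum(sqrt(x^2 + eps^2))

#' Stage-1 regularizer (total variation on the transmission field)
#'
#' `zeta(L, A) = sum sqrt(|dE/dx|^2 + |dE/dy|^2 + eps^2)
#'             + sum sqrt(L^2 + eps^2) + 10 * sum A^2 * (A > 0)`
#' with `E = transmission(L, A)`. Because the field TV sees only `E`, it is
#' blind to wavelength jumps of `L` and does not propagate wrapping
#' artefacts; the second term is an OPD sparsity prior; the third keeps the
#' absorption coefficient nonpositive.
#'
#' @param maps a [sample_maps] object.
#' @param wavelength wavelength (um).
#' @param eps smoothing of the magnitudes.
#' @return scalar regularization value.
#' @export
reg_stage1 <- function(maps, wavelength, eps = 1e-3) {
  E <- transmission(maps, wavelength)$values
  gx <- diff_x(E); gy <- diff_y(E)
  tv <- sum(sqrt(Mod(gx)^2 + Mod(gy)^2 + eps^2))
  sparsity <- smooth_abs_sum(maps$L, eps)
  pos_a <- 10 * sum((maps$A[maps$A > 0])^2)
  tv + sparsity + pos_a
}

#' Stage-2 regularizer (total variation on the unwrapped OPD)
#'
#' `zeta(L, A) = sum sqrt((dL/dx)^2 + (dL/dy)^2 + eps^2)
#'             + (1/5) sum sqrt(L^2 + eps^2) + (1/5) sum (Lap A)^2
#'             + 10 sum A^2 (A > 0) + sum L^2 (L < 0)`
#' Once the OPD has been unwrapped (by the network step), total variation is
#' applied to `L` itself, the absorption map is smoothed through its
#' Laplacian, and a one-sided penalty enforces positivity of the OPD.
#'
#' @param maps a [sample_maps] object.
#' @param eps smoothing of the magnitudes.
#' @return scalar regularization value.
#' @export
reg_stage2 <- function(maps, eps = 1e-3) {
  L <- maps$L; A <- maps$A
  gx <- diff_x(L); gy <- diff_y(L)
  tv <- sum(sqrt(gx^2 + gy^2 + eps^2))
  sparsity <- smooth_abs_sum(L, eps) / 5
  lap <- laplacian(A)
  smooth_a <- sum(lap^2) / 5
  pos_a <- 10 * sum((A[A > 0])^2)
  neg_l <- sum((L[L < 0])^2)
  tv + sparsity + smooth_a + pos_a + neg_l
}

# Gradient of the fidelity term plus (stage 1 only) the field-TV term, via
# the adjoint of the forward chain: residual -> K^T -> |.|^2 -> h_{-Z} ->
# exp. Returns the criterion pieces and gradient maps w.r.t. L and A.
criterion_pieces <- function(maps, I_meas, scfg, optics, K) {
  lambda <- optics$wavelength
  Z <- optics$sample_sensor_distance
  B <- optics$background
  eps <- scfg$tv_epsilon
  use_K <- !is.null(K) && !is_dirac_kernel(K)

  E <- transmission(maps, lambda)$values
  U <- fresnel_propagate(complex_field(E, maps$pixel_pitch), Z, lambda)$values
  I0 <- Mod(U)^2
  if (use_K) {
    Kfull <- embed_kernel(K, dim(I0))
    Iconv <- conv_centered(I0, Kfull)
    Iconv[Iconv < 0] <- 0
  } else {
    Iconv <- I0
  }
  I_model <- B * Iconv

  w <- pmax(I_meas$values, scfg$fidelity_floor)
  resid <- I_model - I_meas$values
  fidelity <- sum(resid^2 / w)

  dI <- 2 * resid / w                       # d fidelity / d I_model
  dI0 <- if (use_K) B * conv_centered(dI, Kfull, adjoint = TRUE) else B * dI
  G_U <- dI0 * U                            # df = 2 Re <G_U, dU>
  G_E <- fresnel_propagate(complex_field(G_U, maps$pixel_pitch),
                           -Z, lambda)$values

  # Regularizer value and its gradient; field-TV contributes through G_E.
  if (scfg$stage == "first") {
    gxE <- diff_x(E); gyE <- diff_y(E)
    t1 <- sqrt(Mod(gxE)^2 + Mod(gyE)^2 + eps^2)
    reg <- sum(t1) + smooth_abs_sum(maps$L, eps) +
      10 * sum((maps$A[maps$A > 0])^2)
    G_E_reg <- 0.5 * (diff_x_adj(gxE / t1) + diff_y_adj(gyE / t1))
    G_E <- G_E + scfg$alpha * G_E_reg
    grad_L_reg <- maps$L / sqrt(maps$L^2 + eps^2)
    grad_A_reg <- 20 * maps$A * (maps$A > 0)
  } else {
    L <- maps$L; A <- maps$A
    gxL <- diff_x(L); gyL <- diff_y(L)
    t1 <- sqrt(gxL^2 + gyL^2 + eps^2)
    lap <- laplacian(A)
    reg <- sum(t1) + smooth_abs_sum(L, eps) / 5 + sum(lap^2) / 5 +
      10 * sum((A[A > 0])^2) + sum((L[L < 0])^2)
    grad_L_reg <- diff_x_adj(gxL / t1) + diff_y_adj(gyL / t1) +
      (1 / 5) * L / sqrt(L^2 + eps^2) + 2 * L * (L < 0)
    grad_A_reg <- (2 / 5) * laplacian(lap) + 20 * A * (A > 0)
  }

  # Chain rule through E = exp(2 i pi L / lambda + A):
  # dE = E (2 i pi / lambda dL + dA), df = 2 Re <G_E, dE>.
  ge <- Conj(G_E) * E
  grad_L <- -(4 * pi / lambda) * Im(ge) + scfg$alpha * grad_L_reg
  grad_A <- 2 * Re(ge) + scfg$alpha * grad_A_reg

  if (!all(is.finite(grad_L)) || !all(is.finite(grad_A))) {
    stop("non-finite gradient encountered", call. = FALSE)
  }
  list(fidelity = fidelity, reg = reg,
       total = fidelity + scfg$alpha * reg,
       grad_L = grad_L, grad_A = grad_A)
}

#' Reconstruction criterion and its analytic gradient
#'
#' Evaluates the total criterion (fidelity plus the stage's weighted
#' regularizer) and its exact analytic gradient with respect to the `L` and
#' `A` maps, obtained as the adjoint of the forward chain (conjugate
#' back-propagation of the intensity residual through the coherence
#' convolution, the squared modulus, the Fresnel kernel and the complex
#' exponential).
#'
#' @param maps candidate [sample_maps].
#' @param I_meas measured [intensity_image].
#' @param config a [solver_config].
#' @param optics an [optics_config].
#' @param K coherence kernel or `NULL`.
#' @return list with `total`, `fidelity`, `reg`, and gradient maps
#'   `grad_L`, `grad_A`.
#' @export
criterion_and_gradient <- function(maps, I_meas, config, optics, K = NULL) {
  stopifnot(identical(dim(maps$L), dim(I_meas$values)))
  criterion_pieces(maps, I_meas, config, optics, K)
}

#' Minimize the reconstruction criterion by nonlinear conjugate gradient
#'
#' Polak-Ribiere+ conjugate gradient with Armijo backtracking line search
#' over the concatenated `(L, A)` maps. The direction is restarted (to
#' steepest descent) every `min(n_pixels, 50)` iterations or whenever it
#' fails to be a descent direction; a failed line search falls back to
#' steepest descent for that iteration and, if that also fails, terminates
#' early. Iteration 0 of the history logs the criterion at the
#' initialization, so the history is a complete convergence record
#' (fidelity, regularization, total per iteration) and is non-increasing in
#' the total.
#'
#' @param I_meas measured [intensity_image].
#' @param init initial [sample_maps].
#' @param config a [solver_config].
#' @param optics an [optics_config].
#' @param K coherence kernel or `NULL`.
#' @return object of class `recon_result`: final `maps`, a `history` data
#'   frame (`iteration`, `fidelity`, `regularization`, `total`, `step`) and
#'   `n_iterations_run`.
#' @export
minimize_criterion <- function(I_meas, init, config, optics, K = NULL) {
  stopifnot(inherits(config, "solver_config"),
            identical(dim(init$L), dim(I_meas$values)))
  pitch <- init$pixel_pitch
  L <- init$L; A <- init$A
  mk <- function(L, A) sample_maps(L, A, pitch)

  ev <- criterion_pieces(mk(L, A), I_meas, config, optics, K)
  hist <- data.frame(iteration = 0L, fidelity = ev$fidelity,
                     regularization = ev$reg, total = ev$total, step = 0)
  gL <- ev$grad_L; gA <- ev$grad_A
  dL <- -gL; dA <- -gA
  g_dot <- sum(gL^2) + sum(gA^2)
  t_prev <- NA_real_
  restart_every <- min(length(L), 50L)
  n_run <- 0L

  for (it in seq_len(config$n_iterations)) {
    slope <- sum(gL * dL) + sum(gA * dA)
    if (!is.finite(slope) || slope >= 0 || it %% restart_every == 0L) {
      dL <- -gL; dA <- -gA
      slope <- -g_dot
    }
    if (g_dot == 0) break   # exact stationary point

    # Initial trial step: continue from the previous accepted scale, capped
    # so no OPD pixel moves by more than ~0.2 um in one trial.
    d_inf <- max(max(abs(dL)), max(abs(dA)), 1e-30)
    t0 <- if (is.finite(t_prev)) min(2 * t_prev, 0.2 / d_inf) else 0.2 / d_inf
    armijo <- function(t0, dL, dA, slope) {
      t <- t0
      for (trial in seq_len(config$ls_max)) {
        cand <- tryCatch(
          criterion_pieces(mk(L + t * dL, A + t * dA), I_meas, config,
                           optics, K),
          error = function(e) NULL)
        if (!is.null(cand) &&
            cand$total <= ev$total + config$ls_c1 * t * slope) {
          return(list(t = t, ev = cand))
        }
        t <- t * config$ls_factor
      }
      NULL
    }
    acc <- armijo(t0, dL, dA, slope)
    if (is.null(acc)) {
      # steepest-descent fallback for this iteration
      dL <- -gL; dA <- -gA
      slope <- -g_dot
      acc <- armijo(0.2 / max(max(abs(dL)), max(abs(dA)), 1e-30), dL, dA,
                    slope)
      if (is.null(acc)) break
    }
    L <- L + acc$t * dL
    A <- A + acc$t * dA
    t_prev <- acc$t
    ev_new <- acc$ev
    gL_new <- ev_new$grad_L; gA_new <- ev_new$grad_A
    g_dot_new <- sum(gL_new^2) + sum(gA_new^2)
    beta <- max(0, (sum(gL_new * (gL_new - gL)) +
                      sum(gA_new * (gA_new - gA))) / g_dot)
    dL <- -gL_new + beta * dL
    dA <- -gA_new + beta * dA
    gL <- gL_new; gA <- gA_new; g_dot <- g_dot_new
    ev <- ev_new
    n_run <- it
    hist <- rbind(hist, data.frame(iteration = it, fidelity = ev$fidelity,
                                   regularization = ev$reg, total = ev$total,
                                   step = acc$t))
  }

  structure(list(maps = mk(L, A), history = hist, n_iterations_run = n_run,
                 config = config),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("<recon_result> stage %s, %d iterations, criterion %.6g -> %.6g\n",
              x$config$stage, x$n_iterations_run,
              h$total[1], h$total[nrow(h)]))
  invisible(x)
}

#' First (fast, wrapping-prone) holographic reconstruction
#'
#' Stage 1 of the alternation: minimize the criterion from a null sample
#' (`L = 0`, `A = 0`) with the coherent forward model (Dirac kernel), the
#' field-TV regularizer, and a deliberately low iteration count (20). No
#' attempt is made at phase unwrapping: wherever the true OPD exceeds half a
#' wavelength the result carries wavelength-jump artefacts, which the
#' network step is trained to remove.
#'
#' @param I_meas measured [intensity_image].
#' @param optics an [optics_config]. If `background` is `NA`, the median of
#'   the measured hologram is used.
#' @param config optional [solver_config] (defaults to stage-1 settings).
#' @return a `recon_result`.
#' @export
first_reconstruction <- function(I_meas, optics, config = NULL) {
  if (is.null(config)) config <- solver_config("first")
  if (is.na(optics$background)) {
    optics$background <- stats::median(I_meas$values)
  }
  sz <- dim(I_meas$values)
  init <- sample_maps(matrix(0, sz[1], sz[2]), matrix(0, sz[1], sz[2]),
                      I_meas$pixel_pitch)
  minimize_criterion(I_meas, init, config, optics, K = NULL)
}

#' Final holographic reconstruction
#'
#' Stage 3 of the alternation: minimize the criterion starting from the
#' (typically network-predicted, unwrapped) maps, now with the
#' partial-coherence kernel in the forward model, the OPD-TV regularizer,
#' and more iterations (70). Descent guarantees the final data fidelity is
#' never worse than at the initialization, so network hallucinations that
#' contradict the measurement are corrected.
#'
#' @param I_meas measured [intensity_image].
#' @param init initial [sample_maps] (the network prediction).
#' @param optics an [optics_config].
#' @param K coherence kernel (defaults to the Gaussian simulation kernel).
#' @param config optional [solver_config] (defaults to stage-2 settings).
#' @return a `recon_result`.
#' @export
second_reconstruction <- function(I_meas, init, optics,
                                  K = gaussian_kernel(1.75, I_meas$pixel_pitch),
                                  config = NULL) {
  if (is.null(config)) config <- solver_config("second")
  if (is.na(optics$background)) {
    optics$background <- stats::median(I_meas$values)
  }
  minimize_criterion(I_meas, init, config, optics, K)
}
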