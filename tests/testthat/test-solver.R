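test_that("data fidelity is the intensity-weighted squared residual", {
  opt <- table1_optics()
  n <- 32
  set.seed(40)
  m <- random_maps(n, l_max = 0.3)
  I_exact <- predict_intensity(m, opt)
  expect_equal(data_fidelity(m, I_exact, opt), 0, tolerance = 1e-18,
               ignore_attr = TRUE)

  # brute-force elementwise oracle on a random instance
  I_meas <- intensity_image(matrix(rpois(n * n, 105), n, n), 1.67)
  fid <- data_fidelity(m, I_meas, opt)
  I_model <- predict_intensity(m, opt)$values
  oracle <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w <- max(I_meas$values[i, j], 1)
      oracle <- oracle + (I_model[i, j] - I_meas$values[i, j])^2 / w
    }
  }
  expect_equal(as.numeric(fid), oracle, tolerance = 1e-12)

  # quadratic form: doubling the residual quadruples the criterion.
  # Residuals r and 2r correspond to measurements I_model - r and
  # I_model - 2r with the weight held fixed, checked via the oracle form.
  r <- I_model - I_meas$values
  w <- pmax(I_meas$values, 1)
  expect_equal(sum((2 * r)^2 / w), 4 * sum(r^2 / w))
})

test_that("stage regularizers implement their printed terms", {
  opt <- table1_optics()
  n <- 24
  eps <- 1e-3
  z0 <- zero_maps(n)
  # null maps: only the epsilon floors contribute
  expect_equal(reg_stage1(z0, opt$wavelength, eps), 2 * n * n * eps)
  # A <= 0 everywhere: the one-sided absorption penalty is exactly zero,
  # so the value equals field-TV + sparsity computed directly
  set.seed(41)
  m <- random_maps(n, l_max = 0.4)
  E <- transmission(m, opt$wavelength)$values
  expected1 <- sum(sqrt(Mod(holocell:::diff_x(E))^2 +
                          Mod(holocell:::diff_y(E))^2 + eps^2)) +
    sum(sqrt(m$L^2 + eps^2))
  expect_equal(reg_stage1(m, opt$wavelength, eps), expected1,
               tolerance = 1e-12)
  # a positive-A map pays the 10 A^2 penalty on top
  m_posA <- sample_maps(m$L, -m$A, m$pixel_pitch)
  E2 <- transmission(m_posA, opt$wavelength)$values
  expected2 <- sum(sqrt(Mod(holocell:::diff_x(E2))^2 +
                          Mod(holocell:::diff_y(E2))^2 + eps^2)) +
    sum(sqrt(m$L^2 + eps^2)) + 10 * sum(m$A^2)
  expect_equal(reg_stage1(m_posA, opt$wavelength, eps), expected2,
               tolerance = 1e-12)

  # stage 2: L >= 0 kills the last term, constant A kills the Laplacian term
  m2 <- sample_maps(abs(m$L), m$A, m$pixel_pitch)
  flatA <- sample_maps(abs(m$L), matrix(-0.1, n, n), m$pixel_pitch)
  r_flat <- reg_stage2(flatA, eps)
  gx <- holocell:::diff_x(flatA$L); gy <- holocell:::diff_y(flatA$L)
  expected <- sum(sqrt(gx^2 + gy^2 + eps^2)) +
    sum(sqrt(flatA$L^2 + eps^2)) / 5
  expect_equal(r_flat, expected, tolerance = 1e-12)
})

test_that("field-TV ignores wavelength jumps that OPD-TV penalizes", {
  opt <- table1_optics()
  n <- 32
  lam <- opt$wavelength
  # a half-plane shifted by one wavelength: invisible to the transmission
  # field, a sharp edge for the OPD
  L_flat <- matrix(0.1, n, n)
  L_step <- L_flat
  L_step[, (n / 2 + 1):n] <- 0.1 + lam
  A <- matrix(-0.05, n, n)
  m_flat <- sample_maps(L_flat, A, 1.67)
  m_step <- sample_maps(L_step, A, 1.67)

  field_tv <- function(m) {
    E <- transmission(m, lam)$values
    sum(sqrt(Mod(holocell:::diff_x(E))^2 +
               Mod(holocell:::diff_y(E))^2 + 1e-6))
  }
  opd_tv <- function(m) {
    sum(sqrt(holocell:::diff_x(m$L)^2 + holocell:::diff_y(m$L)^2 + 1e-6))
  }
  expect_equal(field_tv(m_step), field_tv(m_flat), tolerance = 1e-9)
  expect_gt(opd_tv(m_step), opd_tv(m_flat) + n * lam * 0.9)

  # global one-wave shift: stage-1 regularizer changes only through the
  # sparsity term, the field-TV part is exactly invariant
  m_gshift <- sample_maps(L_flat + lam, A, 1.67)
  expect_equal(field_tv(m_gshift), field_tv(m_flat), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  opt <- optics_config(sample_sensor_distance = 600)
  n <- 32
  set.seed(42)
  m <- random_maps(n, l_max = 0.8)
  I_meas <- intensity_image(matrix(rpois(n * n, 105), n, n), 1.67)
  K <- gaussian_kernel(1.75, 1.67, c(n, n))
  h <- 1e-5
  for (stage in c("first", "second")) {
    for (Ku in list(NULL, K)) {
      cfg <- solver_config(stage, alpha = 4)
      cg <- criterion_and_gradient(m, I_meas, cfg, opt, Ku)
      set.seed(43)
      dL <- matrix(rnorm(n * n), n, n)
      dA <- matrix(rnorm(n * n), n, n)
      fp <- criterion_and_gradient(
        sample_maps(m$L + h * dL, m$A + h * dA, 1.67), I_meas, cfg, opt,
        Ku)$total
      fm <- criterion_and_gradient(
        sample_maps(m$L - h * dL, m$A - h * dA, 1.67), I_meas, cfg, opt,
        Ku)$total
      fd <- (fp - fm) / (2 * h)
      an <- sum(cg$grad_L * dL) + sum(cg$grad_A * dA)
      expect_lt(abs(fd - an) / abs(fd), 1e-4)
    }
  }

  # at an exact fit with zero regularization the gradient vanishes
  I_fit <- predict_intensity(m, opt)
  cg0 <- criterion_and_gradient(m, I_fit, solver_config("first", alpha = 0),
                                opt)
  scale <- max(abs(criterion_and_gradient(m, I_meas,
                                          solver_config("first", alpha = 0),
                                          opt)$grad_L))
  expect_lt(max(abs(cg0$grad_L)) / scale, 1e-10)

  # the one-sided absorption penalty has zero gradient where A < 0: the
  # regularizer is insensitive to small A perturbations of a strictly
  # negative map through that term (central difference on the penalty)
  pen <- function(A) 10 * sum((A[A > 0])^2)
  A_neg <- -abs(m$A) - 0.01
  expect_equal((pen(A_neg + h) - pen(A_neg - h)) / (2 * h), 0)
})

test_that("conjugate-gradient minimization descends and logs consistently", {
  opt <- table1_optics()
  n <- 128
  set.seed(44)
  sc <- single_cell_scene(n, r = 8, dnr = 0.006, dni = 0.001)
  truth <- render_maps(sc, opt$wavelength)
  expect_lt(max(truth$L), opt$wavelength / 4)  # sub-wrapping control
  K <- gaussian_kernel(1.75, 1.67)
  holo <- simulate_hologram(truth, opt, K)

  rec <- first_reconstruction(holo, opt)
  h <- rec$history
  # monotone descent and the logged identity total = fidelity + alpha * reg
  expect_true(all(diff(h$total) <= 1e-9 * h$total[1]))
  expect_equal(h$total, h$fidelity + rec$config$alpha * h$regularization,
               tolerance = 1e-9)
  expect_equal(h$iteration, 0:rec$n_iterations_run)
  # 20 iterations reduce the data term below 10% of its initial value
  expect_lt(h$fidelity[nrow(h)], 0.10 * h$fidelity[1])

  # determinism
  rec2 <- first_reconstruction(holo, opt)
  expect_identical(rec$maps$L, rec2$maps$L)

  # null data with null init stays at the origin
  flat <- intensity_image(matrix(opt$background, n, n), 1.67)
  rec0 <- first_reconstruction(flat, opt)
  expect_lt(max(abs(rec0$maps$L)), 1e-2)
})

test_that("first reconstruction recovers sub-wrapping cells and wraps dense OPDs", {
  opt <- table1_optics()
  K <- gaussian_kernel(1.75, 1.67)

  # sub-wrapping single cell: per-cell dnr within 20%
  n <- 256
  set.seed(45)
  sc <- single_cell_scene(n, r = 8, dnr = 0.006, dni = 0.001)
  truth <- render_maps(sc, opt$wavelength)
  holo <- simulate_hologram(truth, opt, K)
  rec <- first_reconstruction(holo, opt)
  r <- refractive_index_recovery(rec$maps, sc, opt$wavelength)
  expect_lt(abs(r$dnr_recons - 0.006) / 0.006, 0.20)

  # super-half-wave phantom: reconstruction is wrapped
  n <- 128
  set.seed(46)
  sc2 <- single_cell_scene(n, r = 10, dnr = 0.05, dni = 0.002)
  truth2 <- render_maps(sc2, opt$wavelength)
  expect_gt(max(truth2$L), opt$wavelength / 2)
  holo2 <- simulate_hologram(truth2, opt, K)
  rec2 <- first_reconstruction(holo2, opt)
  expect_true(any(abs(rec2$maps$L - truth2$L) > opt$wavelength / 4))
  expect_lt(max(rec2$maps$L), max(truth2$L) - opt$wavelength / 2)
})

test_that("final reconstruction is stable at truth and corrects bad initializations", {
  opt <- table1_optics()
  n <- 128
  K <- gaussian_kernel(1.75, 1.67)
  set.seed(47)
  p <- sim_params(n_cells_range = c(2L, 2L), radius_range = c(6, 9),
                  dnr_range = c(0.01, 0.02), dni_range = c(0.001, 0.002))
  sc <- sample_scene(p, c(n, n), 1.67)
  truth <- render_maps(sc, opt$wavelength)

  # noise-free hologram: ground truth is a fidelity minimum, the solver
  # stays within 5% RMS of it
  holo_nf <- predict_intensity(truth, opt, K)
  rec <- second_reconstruction(holo_nf, truth, opt, K)
  rel_rms <- sqrt(mean((rec$maps$L - truth$L)^2)) / sqrt(mean(truth$L^2))
  expect_lt(rel_rms, 0.05)

  # a spurious blob absent from the hologram: descent strictly improves the
  # data term from that initialization
  blob <- truth
  ij <- 30:40
  blob$L[ij, ij] <- blob$L[ij, ij] + 0.3
  set.seed(48)
  holo <- simulate_hologram(truth, opt, K)
  rec_b <- second_reconstruction(holo, blob, opt, K)
  hb <- rec_b$history
  expect_lt(hb$fidelity[nrow(hb)], hb$fidelity[1])

  # initialized at a wrapped first reconstruction of a super-half-wave
  # cell, the gradient-based solver cannot escape the wrap local minimum
  set.seed(49)
  sc2 <- single_cell_scene(n, r = 10, dnr = 0.05, dni = 0.002)
  truth2 <- render_maps(sc2, opt$wavelength)
  holo2 <- simulate_hologram(truth2, opt, K)
  rec1 <- first_reconstruction(holo2, opt)
  rec2 <- second_reconstruction(holo2, rec1$maps, opt, K)
  expect_true(any(abs(rec2$maps$L - truth2$L) > opt$wavelength / 4))
  expect_lt(max(rec2$maps$L), max(truth2$L) - opt$wavelength / 2)
})
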