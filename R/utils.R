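# Internal array helpers shared by the forward model and the solver.

#' @keywords internal
stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite entries in ", what, call. = FALSE)
}

# Centre index convention: the kernel origin (r = 0) sits at
# (floor(nr/2) + 1, floor(nc/2) + 1), the geometric image centre.
center_index <- function(n) floor(n / 2L) + 1L

circshift <- function(m, by) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - by[1L]) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - by[2L]) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

fftshift2 <- function(m) circshift(m, c(floor(nrow(m) / 2L), floor(ncol(m) / 2L)))

ifftshift2 <- function(m) circshift(m, c(-floor(nrow(m) / 2L), -floor(ncol(m) / 2L)))

# FFT sample frequencies in cycles per micron for n samples at `pitch` spacing.
fft_freq <- function(n, pitch) {
  k <- 0:(n - 1L)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k / (n * pitch)
}

# Circular convolution of a real image with a centred kernel, by FFT.
conv_centered <- function(img, kernel, adjoint = FALSE) {
  kh <- stats::fft(ifftshift2(kernel))
  if (adjoint) kh <- Conj(kh)
  out <- stats::fft(stats::fft(img) * kh, inverse = TRUE) / length(img)
  Re(out)
}

# Forward difference with replicate (Neumann) boundary: last row/col slope 0.
diff_x <- function(u) {
  nc <- ncol(u)
  cbind(u[, -1L, drop = FALSE] - u[, -nc, drop = FALSE], rep(0, nrow(u)))
}

diff_y <- function(u) {
  nr <- nrow(u)
  rbind(u[-1L, , drop = FALSE] - u[-nr, , drop = FALSE], rep(0, ncol(u)))
}

# Adjoints of the forward differences (negative divergence components).
diff_x_adj <- function(v) {
  nc <- ncol(v)
  left <- cbind(rep(0, nrow(v)), v[, -nc, drop = FALSE])
  vz <- v
  vz[, nc] <- 0
  left - vz
}

diff_y_adj <- function(v) {
  nr <- nrow(v)
  up <- rbind(rep(0, ncol(v)), v[-nr, , drop = FALSE])
  vz <- v
  vz[nr, ] <- 0
  up - vz
}

# Self-adjoint discrete Laplacian, -(Dx' Dx + Dy' Dy) with Neumann boundaries.
laplacian <- function(u) {
  -(diff_x_adj(diff_x(u)) + diff_y_adj(diff_y(u)))
}
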