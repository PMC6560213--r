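# Non-uniform discrete Fourier transform by Kaiser-Bessel gridding:
# oversampled FFT plus sparse interpolation. Forward and adjoint are exact
# transposes of one another by construction (the interpolation is a sparse
# matrix; the FFT adjoint is the unnormalized inverse FFT), so adjointness
# holds to machine precision while interpolation accuracy is governed by
# the oversampling factor and kernel width.

kb_kernel <- function(u, width, beta) {
  x <- 2 * u / width
  out <- u * 0          # preserves matrix shape
  ok <- abs(x) <= 1
  out[ok] <- besselI(beta * sqrt(1 - x[ok]^2), 0)
  out
}

# Continuous Fourier transform of the kernel at image coordinate x (units
# of cycles per oversampled-grid pixel), by Simpson quadrature. Used to
# deapodize the image before gridding.
kb_kernel_ft <- function(x, width, beta, n_quad = 2001) {
  u <- seq(0, width / 2, length.out = n_quad)
  w <- rep(c(2, 4), length.out = n_quad); w[1] <- w[n_quad] <- 1
  w <- w * (u[2] - u[1]) / 3
  ku <- kb_kernel(u, width, beta) * w
  2 * as.vector(cos(2 * pi * outer(x, u)) %*% ku)
}

#' Plan a 2D non-uniform Fourier transform
#'
#' Precomputes the sparse Kaiser-Bessel interpolation matrix, embedding
#' indices and deapodization image for evaluating
#' `y(k) = sum_r x(r) exp(-2i pi (kx*rx + ky*ry) / n)` at arbitrary
#' frequencies (cycles/FOV, `|k| <= n/2`) from an `n x n` image with
#' centered pixel coordinates.
#'
#' @param kx,ky Sample frequencies, cycles/FOV.
#' @param n Image matrix size.
#' @param osf Grid oversampling factor.
#' @param width Interpolation kernel width (grid points).
#' @return A plan object for [nufft_forward()] / [nufft_adjoint()].
#' @export
nufft_plan <- function(kx, ky, n, osf = 2, width = 8) {
  stopifnot(length(kx) == length(ky), n >= 2)
  if (any(abs(c(kx, ky)) > n / 2 + 1e-9))
    stop("sample frequencies exceed the grid Nyquist limit n/2")
  ng <- 2L * ceiling(osf * n / 2)
  beta <- pi * sqrt((width / (ng / n))^2 * ((ng / n) - 0.5)^2 - 0.8)
  half <- width / 2
  nsamp <- length(kx)
  offs <- seq_len(width) - 1L
  idx1d <- function(k) {
    kos <- k * (ng / n)
    j0 <- ceiling(kos - half)
    j <- outer(j0, offs, "+")                    # nsamp x width integer freqs
    w <- kb_kernel(kos - j, width, beta)
    list(col = (j %% ng) + 1L, w = w)
  }
  gx <- idx1d(kx); gy <- idx1d(ky)
  rows <- rep(seq_len(nsamp), times = width * width)
  ix <- gx$col[, rep(seq_len(width), times = width)]
  iy <- gy$col[, rep(seq_len(width), each = width)]
  wgt <- gx$w[, rep(seq_len(width), times = width)] *
    gy$w[, rep(seq_len(width), each = width)]
  S <- Matrix::sparseMatrix(i = rows, j = as.vector(ix + (iy - 1L) * ng),
                            x = as.vector(wgt), dims = c(nsamp, ng * ng))
  # centered pixel r = -n/2 .. n/2-1 embeds at grid index (r mod ng) + 1
  r <- seq_len(n) - 1L - n %/% 2L
  emb <- (r %% ng) + 1L
  embed_idx <- as.vector(outer(emb, (emb - 1L) * ng, "+"))
  apod1 <- kb_kernel_ft(r / ng, width, beta)
  list(S = S, ng = ng, n = n, nsamp = nsamp, embed_idx = embed_idx,
       apod = outer(apod1, apod1))
}

#' Evaluate the planned NUFFT (image to samples)
#'
#' @param plan A [nufft_plan()].
#' @param x Complex `n x n` image (centered pixel coordinates).
#' @return Complex sample vector.
#' @export
nufft_forward <- function(plan, x) {
  g <- matrix(0 + 0i, plan$ng, plan$ng)
  g[plan$embed_idx] <- x / plan$apod
  sp_cplx_mult(plan$S, as.vector(stats::fft(g)))
}

# real sparse matrix times complex vector (Matrix has no complex class)
sp_cplx_mult <- function(S, z) {
  m <- as.matrix(S %*% cbind(Re(z), Im(z)))
  complex(real = m[, 1], imaginary = m[, 2])
}

sp_cplx_crossprod <- function(S, z) {
  m <- as.matrix(Matrix::crossprod(S, cbind(Re(z), Im(z))))
  complex(real = m[, 1], imaginary = m[, 2])
}

#' Adjoint of the planned NUFFT (samples to image)
#'
#' Exact conjugate-transpose of [nufft_forward()].
#'
#' @param plan A [nufft_plan()].
#' @param y Complex sample vector.
#' @return Complex `n x n` image.
#' @export
nufft_adjoint <- function(plan, y) {
  g <- matrix(sp_cplx_crossprod(plan$S, y), plan$ng, plan$ng)
  G <- stats::fft(g, inverse = TRUE)
  matrix(G[plan$embed_idx], plan$n, plan$n) / plan$apod
}

# Direct NDFT summation; the brute-force oracle used in tests.
ndft_direct <- function(kx, ky, x) {
  n <- nrow(x)
  r <- seq_len(n) - 1 - n %/% 2
  ph <- outer(kx, r) # nsamp x n
  ey <- exp(-2i * pi * outer(ky, r) / n)
  ex <- exp(-2i * pi * ph / n)
  rowSums((ex %*% x) * ey)
}
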