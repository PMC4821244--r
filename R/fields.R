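# Squared spatial frequencies (cycles/um)^2 along one axis of length n with
# sample spacing d (um/px), in FFT order.
freq_sq <- function(n, d) {
  k <- c(seq(0L, floor(n / 2)), seq(-(ceiling(n / 2) - 1L), -1L))
  (k / (n * d))^2
}

# Matrix of fx^2 + fy^2 over a (ny, nx) grid.
fsq_matrix <- function(ny, nx, d) {
  outer(freq_sq(ny, d), freq_sq(nx, d), "+")
}

# Fourier multiplier of an isotropic Gaussian blur with sd `sigma` (um).
gaussian_decay <- function(fsq, sigma) {
  exp(-2 * pi^2 * sigma^2 * fsq)
}

ifft2 <- function(fhat) Re(stats::fft(fhat, inverse = TRUE)) / length(fhat)

#' Propagate a field by free 2-D diffusion
#'
#' Convolves `field` with an isotropic Gaussian kernel of standard deviation
#' `sigma` (um), evaluated spectrally.  With `pad_factor > 1` the field is
#' embedded centrally in a zero- (or constant-) padded domain before the
#' periodic convolution and cropped afterwards, which suppresses wrap-around
#' artefacts for compactly supported perturbations.
#'
#' @param field numeric matrix (y, x).
#' @param sigma Gaussian sd in um; `sqrt(2 * D * t)` for diffusion
#'   coefficient `D` (um^2/s) acting over `t` seconds.
#' @param pixel_size um per pixel.
#' @param pad_factor integer >= 1; 1 means plain periodic convolution.
#' @param pad_value value used outside the field; defaults to the mean of the
#'   border pixels so that a flat plateau continues smoothly.
#' @return matrix of the same shape as `field`.
#' @export
diffuse_field <- function(field, sigma, pixel_size, pad_factor = 2,
                          pad_value = NULL) {
  stopifnot(is.matrix(field), sigma >= 0, pixel_size > 0, pad_factor >= 1)
  if (sigma == 0) return(field)
  ny <- nrow(field); nx <- ncol(field)
  if (pad_factor > 1) {
    py <- as.integer(round(ny * pad_factor)); px <- as.integer(round(nx * pad_factor))
    if (is.null(pad_value)) {
      border <- c(field[1, ], field[ny, ], field[, 1], field[, nx])
      pad_value <- mean(border)
    }
    big <- matrix(pad_value, py, px)
    oy <- (py - ny) %/% 2; ox <- (px - nx) %/% 2
    big[oy + seq_len(ny), ox + seq_len(nx)] <- field
    out <- ifft2(stats::fft(big) * gaussian_decay(fsq_matrix(py, px, pixel_size), sigma))
    out[oy + seq_len(ny), ox + seq_len(nx)]
  } else {
    ifft2(stats::fft(field) * gaussian_decay(fsq_matrix(ny, nx, pixel_size), sigma))
  }
}

# Physical coordinates of pixel centers: pixel (0-based index i) sits at
# i * pixel_size um from the top-left pixel center; x runs along columns,
# y along rows.
pixel_coords <- function(n, pixel_size) (seq_len(n) - 1) * pixel_size

# Squared distance (um^2) of every pixel center from (cx, cy) um.
dist2_grid <- function(ny, nx, pixel_size, cx, cy) {
  dx2 <- (pixel_coords(nx, pixel_size) - cx)^2
  dy2 <- (pixel_coords(ny, pixel_size) - cy)^2
  outer(dy2, dx2, "+")
}
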