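# Cell segmentation and per-cell fluorescence quantification.
#
# The edge-detection pipeline is a standard threshold + morphology chain:
# Gaussian smoothing, automatic (Otsu) threshold — applied to the local
# gradient magnitude for bright-field images — morphological closing with a
# disc, hole filling, and retention of the largest connected component.

# Gaussian blur in pixel units (spectral, zero-padded against wrap).
blur_px <- function(img, sigma) {
  if (sigma <= 0) return(img)
  diffuse_field(img, sigma, pixel_size = 1, pad_factor = 1.25)
}

# Otsu's threshold on a 256-bin histogram; invariant to positive rescaling.
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image", call. = FALSE)
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * nbins) + 1, 1),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

# Full 2-D convolution via FFT, cropped to "same" extent.
conv2_same <- function(a, k) {
  pa <- dim(a) + dim(k) - 1L
  big_a <- matrix(0, pa[1], pa[2]); big_a[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  big_k <- matrix(0, pa[1], pa[2]); big_k[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- ifft2(stats::fft(big_a) * stats::fft(big_k))
  oy <- (nrow(k) - 1L) %/% 2L; ox <- (ncol(k) - 1L) %/% 2L
  full[oy + seq_len(nrow(a)), ox + seq_len(ncol(a))]
}

disc_kernel <- function(radius) {
  r <- ceiling(radius)
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  (d2 <= radius^2) * 1
}

dilate <- function(mask, kernel) conv2_same(mask * 1, kernel) > 0.5
erode <- function(mask, kernel) conv2_same(mask * 1, kernel) > sum(kernel) - 0.5
morph_close <- function(mask, radius) {
  k <- disc_kernel(radius)
  erode(dilate(mask, k), k)
}

# Connected-component labels (4-connectivity) of a logical mask.
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  id <- matrix(seq_len(ny * nx), ny, nx)
  e_h <- cbind(as.vector(id[, -nx]), as.vector(id[, -1]))
  e_h <- e_h[as.vector(mask[, -nx]) & as.vector(mask[, -1]), , drop = FALSE]
  e_v <- cbind(as.vector(id[-ny, ]), as.vector(id[-1, ]))
  e_v <- e_v[as.vector(mask[-ny, ]) & as.vector(mask[-1, ]), , drop = FALSE]
  g <- igraph::make_graph(as.vector(t(rbind(e_h, e_v))), n = ny * nx,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- matrix(memb, ny, nx)
  lab[!mask] <- 0L
  # renumber foreground components 1..k
  u <- sort(unique(lab[lab > 0]))
  matrix(match(lab, u, nomatch = 0L), ny, nx) * (lab > 0)
}

fill_holes <- function(mask) {
  bg <- label_components(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

gradient_magnitude <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  gx <- img[, c(2:nx, nx)] - img[, c(1, 1:(nx - 1))]
  gy <- img[c(2:ny, ny), ] - img[c(1, 1:(ny - 1)), ]
  sqrt(gx^2 + gy^2) / 2
}

#' Detect the cell edge on a single-frame image
#'
#' Fluorescence channel: Gaussian smoothing, Otsu threshold.  Bright-field
#' channel: Otsu threshold on the smoothed local gradient magnitude (the
#' cell rim is the high-contrast feature).  Both are followed by
#' morphological closing with a disc, hole filling, and retention of the
#' largest connected component.
#'
#' @param image numeric matrix.
#' @param channel `"fluorescence"` or `"brightfield"`, chosen by the user
#'   according to where the cell outline is visible.
#' @param params list; `sigma` (smoothing sd, px, default 2), `close_radius`
#'   (disc radius, px, default 5; bright-field uses at least 7),
#'   `min_area` (minimum component area, px, default 500).
#' @return object of class `cell_mask`: `mask` (logical matrix),
#'   `source_channel`, `area`, `method_params`.
#' @export
detect_cell_edge <- function(image, channel = c("fluorescence", "brightfield"),
                             params = list()) {
  channel <- match.arg(channel)
  p <- utils::modifyList(list(sigma = 2, close_radius = 5, min_area = 500),
                         params)
  stopifnot(is.matrix(image))
  if (diff(range(image)) == 0)
    stop("constant image: no edge to detect", call. = FALSE)
  if (channel == "fluorescence") {
    sm <- blur_px(image, p$sigma)
    bin <- sm > otsu_threshold(sm)
    bin <- morph_close(bin, p$close_radius)
    bin <- fill_holes(bin)
  } else {
    gm <- blur_px(gradient_magnitude(image), p$sigma)
    ring <- gm > otsu_threshold(gm)
    bin <- fill_holes(morph_close(ring, max(p$close_radius, 7)))
    # the filled mask ends at the OUTER edge of the detected rim band;
    # pull the boundary back by the band's half thickness (area/perimeter)
    perim <- sum(bin & !erode(bin, disc_kernel(1)))
    if (perim > 0) {
      half_w <- round(sum(ring & bin) / perim / 2)
      if (half_w >= 1) bin <- erode(bin, disc_kernel(half_w))
    }
  }
  lab <- label_components(bin)
  if (max(lab) == 0)
    stop("no connected component found", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  mask <- lab == best
  if (sum(mask) < p$min_area)
    stop("largest component (", sum(mask), " px) is below min_area (",
         p$min_area, ")", call. = FALSE)
  structure(list(mask = mask, source_channel = channel, area = sum(mask),
                 method_params = p), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("Cell mask: %d px from the %s channel\n", x$area,
              x$source_channel))
  invisible(x)
}

as_mask <- function(x, dims) {
  if (inherits(x, "cell_mask")) return(x$mask)
  if (is.logical(x) && is.matrix(x)) return(x)
  if (inherits(x, "frap_region")) return(rasterize_roi(x, dims, 1))
  stop("expected a cell_mask, logical matrix, or frap_region", call. = FALSE)
}

#' Background-subtracted mean fluorescence of a cell
#'
#' Mean intensity over the cell mask minus the mean over a disjoint
#' background region; negative results are reported as-is.
#'
#' @param image numeric matrix (fluorescence channel).
#' @param mask a `cell_mask`, logical matrix, or `frap_region` (regions are
#'   interpreted in pixel units here).
#' @param background_region same forms as `mask`; must be disjoint from it.
#' @return background-subtracted mean intensity (scalar).
#' @export
mean_cell_intensity <- function(image, mask, background_region) {
  m <- as_mask(mask, dim(image))
  b <- as_mask(background_region, dim(image))
  if (!any(m)) stop("empty cell mask", call. = FALSE)
  if (!any(b)) stop("empty background region", call. = FALSE)
  if (any(m & b)) stop("cell mask and background region overlap", call. = FALSE)
  mean(image[m]) - mean(image[b])
}

#' Normalize binding measurements to a baseline condition
#'
#' Divides every measurement by the mean of the baseline condition's
#' measurements.
#'
#' @param measurements data.frame with columns `condition` and
#'   `mean_intensity` (one row per cell/image).
#' @param baseline_label baseline condition (default `"untreated"`).
#' @return the data.frame with a `normalized_value` column appended.
#' @export
normalize_binding <- function(measurements, baseline_label = "untreated") {
  stopifnot(is.data.frame(measurements),
            all(c("condition", "mean_intensity") %in% names(measurements)))
  base <- measurements$mean_intensity[measurements$condition == baseline_label]
  if (!length(base))
    stop("baseline condition '", baseline_label, "' not present", call. = FALSE)
  bm <- mean(base)
  if (!is.finite(bm) || bm <= 0)
    stop("baseline condition '", baseline_label,
         "' has a non-positive mean intensity", call. = FALSE)
  measurements$normalized_value <- measurements$mean_intensity / bm
  measurements
}
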