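#' Simulation configuration for a synthetic FRAP experiment
#'
#' Describes the acquisition geometry and the generative two-population
#' (mobile + immobile) model.  Defaults reproduce the acquisition used
#' throughout the package's validation: a 22.49 x 22.49 um field imaged at
#' 256 x 256 px, six pre-bleach frames, an instantaneous 2.5 um-radius disc
#' bleach, then 994 recovery frames spanning 195.6 s.
#'
#' @param grid_shape integer c(ny, nx) pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @param n_recovery number of post-bleach frames.
#' @param bleach_center c(x, y) in um from the top-left pixel center;
#'   default is the field center.
#' @param bleach_radius disc radius in um.
#' @param bleach_depth fraction of fluorescence destroyed inside the disc,
#'   in \[0, 1\].
#' @param bleach_edge_sigma Gaussian soft-edge width of the bleach profile
#'   (um); 0 gives a hard disc.
#' @param diffusion_coeff diffusion coefficient D of the mobile population
#'   (um^2/s).
#' @param mobile_fraction fraction f_m of fluorophores that diffuse freely;
#'   the remaining 1 - f_m are immobile.
#' @param monitor_bleach_rate per-frame fractional loss from imaging
#'   illumination, in \[0, 1).  The default loses ~20\% over 1000 frames.
#' @param background_level additive camera/optical offset (intensity units).
#' @param initial_intensity mean fluorescence of the unbleached field
#'   (intensity units above background).
#' @param site_heterogeneity "uniform" or "clustered" binding-site density;
#'   clustered adds bright Gaussian puncta (see `cluster_density`,
#'   `cluster_sigma`, `cluster_amp`).
#' @param cluster_density clusters per um^2 (clustered mode).
#' @param cluster_sigma cluster radius parameter, um.
#' @param cluster_amp peak amplitude of a cluster relative to the uniform
#'   density (density field is renormalized to mean 1).
#' @param cell_free_corner side (um) of the zero-fluorescence square kept in
#'   the top-left corner so that a background ROI measures the true offset;
#'   0 disables it.
#' @param noise_model list; `list(type = "none")`,
#'   `list(type = "gaussian", sigma = ...)`, or the default
#'   `list(type = "poisson_gaussian", gain = 1, sigma_read = 2)` (shot noise
#'   on expected counts plus Gaussian read noise).
#' @param seed integer seed driving all randomness of one simulation.
#' @param bit_depth 8, 16, or "float" (no quantization).
#' @return object of class `frap_sim_config`.
#' @export
frap_sim_config <- function(grid_shape = c(256L, 256L),
                            pixel_size = 22.49 / 256,
                            frame_interval = 195.6 / 994,
                            n_prebleach = 6L,
                            n_recovery = 994L,
                            bleach_center = NULL,
                            bleach_radius = 2.5,
                            bleach_depth = 0.9,
                            bleach_edge_sigma = 0.2,
                            diffusion_coeff = 0.06,
                            mobile_fraction = 1,
                            monitor_bleach_rate = 1 - 0.8^(1 / 1000),
                            background_level = 10,
                            initial_intensity = 200,
                            site_heterogeneity = c("uniform", "clustered"),
                            cluster_density = 0.35,
                            cluster_sigma = 0.35,
                            cluster_amp = 4,
                            cell_free_corner = 5,
                            noise_model = list(type = "poisson_gaussian",
                                               gain = 1, sigma_read = 2),
                            seed = 1L,
                            bit_depth = 16) {
  site_heterogeneity <- match.arg(site_heterogeneity)
  if (is.null(bleach_center)) {
    bleach_center <- c((grid_shape[2] - 1) / 2, (grid_shape[1] - 1) / 2) * pixel_size
  }
  cfg <- structure(list(
    grid_shape = as.integer(grid_shape),
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    n_prebleach = as.integer(n_prebleach),
    n_recovery = as.integer(n_recovery),
    bleach_center = bleach_center,
    bleach_radius = bleach_radius,
    bleach_depth = bleach_depth,
    bleach_edge_sigma = bleach_edge_sigma,
    diffusion_coeff = diffusion_coeff,
    mobile_fraction = mobile_fraction,
    monitor_bleach_rate = monitor_bleach_rate,
    background_level = background_level,
    initial_intensity = initial_intensity,
    site_heterogeneity = site_heterogeneity,
    cluster_density = cluster_density,
    cluster_sigma = cluster_sigma,
    cluster_amp = cluster_amp,
    cell_free_corner = cell_free_corner,
    noise_model = noise_model,
    seed = as.integer(seed),
    bit_depth = bit_depth
  ), class = "frap_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "frap_sim_config"))
  with(cfg, {
    if (length(grid_shape) != 2 || any(grid_shape < 8))
      stop("grid_shape must be two integers >= 8", call. = FALSE)
    if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
    if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
    if (n_prebleach < 1) stop("n_prebleach must be >= 1", call. = FALSE)
    if (n_recovery < 1) stop("n_recovery must be >= 1", call. = FALSE)
    if (mobile_fraction < 0 || mobile_fraction > 1)
      stop("mobile_fraction must lie in [0, 1]", call. = FALSE)
    if (bleach_depth < 0 || bleach_depth > 1)
      stop("bleach_depth must lie in [0, 1]", call. = FALSE)
    if (diffusion_coeff < 0) stop("diffusion_coeff must be >= 0", call. = FALSE)
    if (monitor_bleach_rate < 0 || monitor_bleach_rate >= 1)
      stop("monitor_bleach_rate must lie in [0, 1)", call. = FALSE)
    ext_x <- (grid_shape[2] - 1) * pixel_size
    ext_y <- (grid_shape[1] - 1) * pixel_size
    if (bleach_center[1] - bleach_radius < 0 ||
        bleach_center[1] + bleach_radius > ext_x ||
        bleach_center[2] - bleach_radius < 0 ||
        bleach_center[2] + bleach_radius > ext_y)
      stop("bleach disc extends outside the imaged field", call. = FALSE)
    if (!bit_depth %in% list(8, 16, 8L, 16L, "float"))
      stop("bit_depth must be 8, 16 or \"float\"", call. = FALSE)
    if (!is.list(noise_model) ||
        !noise_model$type %in% c("none", "gaussian", "poisson_gaussian"))
      stop("noise_model$type must be none, gaussian or poisson_gaussian",
           call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.frap_sim_config <- function(x, ...) {
  cat(sprintf(
    "FRAP simulation config: %dx%d px (%.4f um/px), %d pre + %d recovery frames (dt = %.4f s)\n",
    x$grid_shape[1], x$grid_shape[2], x$pixel_size,
    x$n_prebleach, x$n_recovery, x$frame_interval))
  cat(sprintf("  bleach: disc r = %.2f um, depth = %.2f, edge sigma = %.2f um\n",
              x$bleach_radius, x$bleach_depth, x$bleach_edge_sigma))
  cat(sprintf("  model: D = %.4g um^2/s, mobile fraction = %.3f, k_mon = %.3g/frame\n",
              x$diffusion_coeff, x$mobile_fraction, x$monitor_bleach_rate))
  cat(sprintf("  intensity %g + background %g, noise %s, sites %s, seed %d, %s-bit\n",
              x$initial_intensity, x$background_level, x$noise_model$type,
              x$site_heterogeneity, x$seed, as.character(x$bit_depth)))
  if (!is.null(x$preset_info))
    cat(sprintf("  preset: %s (%s)\n", x$preset_info$name, x$preset_info$citation))
  invisible(x)
}
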