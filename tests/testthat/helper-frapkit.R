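# Shared fixtures: small noiseless geometries and independent oracles.

# Small, fast simulation geometry: 64x64 px at the standard pixel size
# (5.5 um field), 0.8 um central bleach disc.
small_config <- function(...) {
  args <- utils::modifyList(list(
    grid_shape = c(64L, 64L), pixel_size = 22.49 / 256,
    frame_interval = 0.2, n_prebleach = 3L, n_recovery = 80L,
    bleach_center = c(2.8, 2.8), bleach_radius = 0.8,
    diffusion_coeff = 0.05, mobile_fraction = 1,
    monitor_bleach_rate = 0, background_level = 5, initial_intensity = 100,
    cell_free_corner = 0, noise_model = list(type = "none"),
    bit_depth = "float", seed = 1L
  ), list(...))
  do.call(frap_sim_config, args)
}

# Geometry for end-to-end pipeline tests: 96x96 px (8.35 um field) with a
# 2 um cell-free corner so the background ROI reads the true offset.
pipe_config <- function(...) {
  args <- utils::modifyList(list(
    grid_shape = c(96L, 96L), pixel_size = 22.49 / 256,
    frame_interval = 0.2, n_prebleach = 4L, n_recovery = 150L,
    bleach_center = c(4.6, 4.6), bleach_radius = 0.8,
    diffusion_coeff = 0.05, mobile_fraction = 0.7,
    monitor_bleach_rate = 0, background_level = 5, initial_intensity = 100,
    cell_free_corner = 2, noise_model = list(type = "none"),
    bit_depth = "float", seed = 1L
  ), list(...))
  do.call(frap_sim_config, args)
}

pipe_rois <- function(cfg = pipe_config()) {
  roi_set(
    bleach = roi_disc(cfg$bleach_center, cfg$bleach_radius),
    reference = roi_disc(c(6.8, 2.2), 0.5),
    background = roi_rect(c(0.3, 1.5), c(0.3, 1.5))
  )
}

# Closed-form diffused hard disc: the fraction of a disc of radius w that a
# Gaussian of variance s2 centred at distance r = sqrt(r2) overlaps equals a
# noncentral chi-square tail: g(r) = P(chisq_2(r2/s2) <= w^2/s2).  Exact for
# free diffusion of a disc profile; independent of the spectral simulator.
oracle_disc_blur <- function(r2, w, s2) {
  stats::pchisq(w^2 / s2, df = 2, ncp = r2 / s2)
}

# Independent re-implementation of the correction / normalization chain,
# written directly from the defining formulas with explicit loops.
oracle_chain <- function(I, I_b, I_r, n_pre) {
  n <- length(I)
  ref_pre <- mean(I_r[1:n_pre] - I_b[1:n_pre])
  I_c <- numeric(n)
  for (k in 1:n) I_c[k] <- (I[k] - I_b[k]) * ref_pre / (I_r[k] - I_b[k])
  I_cn <- I_c / mean(I_c[1:n_pre])
  b <- n_pre + 1
  I_dcn <- (I_cn - I_cn[b]) / (1 - I_cn[b])
  list(I_c = I_c, I_cn = I_cn, I_dcn = I_dcn)
}

# Random raw traces that look like plausible FRAP data (positive reference
# margin, bleach dip, noise), for property-style tests.
random_traces <- function(n_pre = 6, n_post = 60, seed = 1) {
  set.seed(seed)
  n <- n_pre + n_post
  I_b <- runif(n, 4, 6)
  I_r <- 50 + cumsum(rnorm(n, -0.02, 0.3)) + I_b
  rec <- 1 - 0.8 * exp(-(seq_len(n_post) - 1) / runif(1, 5, 25))
  I <- c(runif(n_pre, 58, 62), 60 * rec + rnorm(n_post, 0, 0.5)) + I_b
  frapkit:::new_frap_curve(t = (seq_len(n) - n_pre - 1) * 0.2,
                           I = I, I_b = I_b, I_r = I_r,
                           n_prebleach = n_pre, bleach_index = n_pre + 1L)
}

iou <- function(a, b) sum(a & b) / sum(a | b)
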