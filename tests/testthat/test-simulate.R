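test_that("no perturbation gives a flat series", {
  cfg <- small_config(bleach_depth = 0, n_recovery = 20)
  sim <- simulate_frap(cfg)
  f <- sim$series$frames
  ref <- f[, , 1]
  for (k in 2:dim(f)[3]) expect_equal(f[, , k], ref, tolerance = 0)
  expect_equal(max(abs(ref - (cfg$initial_intensity + cfg$background_level))),
               0)
})

test_that("identical seed and config give bit-identical stacks", {
  cfg <- small_config(noise_model = list(type = "poisson_gaussian", gain = 1,
                                         sigma_read = 2),
                      bit_depth = 16, n_recovery = 15, seed = 42L)
  a <- simulate_frap(cfg)$series$frames
  b <- simulate_frap(cfg)$series$frames
  expect_identical(a, b)
  cfg$seed <- 43L
  expect_false(identical(simulate_frap(cfg)$series$frames, a))
})

test_that("an immobile pool shows no recovery", {
  cfg <- pipe_config(mobile_fraction = 0, n_recovery = 100)
  sim <- simulate_frap(cfg)
  res <- analyze_frap(sim$series, pipe_rois(cfg))
  # post-bleach disc intensity constant over time
  post <- res$curve$I[res$curve$bleach_index:length(res$curve$I)]
  expect_lt(diff(range(post)) / mean(post), 1e-9)
  expect_lt(abs(res$i_f), 1e-6)
  expect_true(is.na(res$tau_half))
  expect_equal(res$mobile_fraction, 0)
})

test_that("periodic diffusion conserves total intensity", {
  set.seed(7)
  f <- matrix(runif(48 * 48, 50, 150), 48, 48)
  g <- diffuse_field(f, sigma = 0.5, pixel_size = 0.1, pad_factor = 1)
  expect_lt(abs(sum(g) - sum(f)) / sum(f), 1e-6)
  # and with no bleach the simulated stack is constant frame to frame
  cfg <- small_config(bleach_depth = 0, n_recovery = 10)
  f3 <- simulate_frap(cfg)$series$frames
  sums <- apply(f3, 3, sum)
  expect_lt(diff(range(sums)) / mean(sums), 1e-6)
})

test_that("a point source spreads with variance 2 D t per axis", {
  n <- 129L; px <- 0.05
  f <- matrix(0, n, n); f[65, 65] <- 1
  D <- 0.04; tt <- 3
  g <- diffuse_field(f, sigma = sqrt(2 * D * tt), pixel_size = px,
                     pad_factor = 2)
  x <- (seq_len(n) - 65) * px
  var_x <- sum(g * matrix(x^2, n, n, byrow = TRUE)) / sum(g)
  var_y <- sum(g * matrix(x^2, n, n)) / sum(g)
  expect_lt(abs(var_x - 2 * D * tt) / (2 * D * tt), 0.02)
  expect_lt(abs(var_y - 2 * D * tt) / (2 * D * tt), 0.02)
})

test_that("simulated bleach field matches the closed-form disc-blur oracle", {
  cfg <- small_config(n_recovery = 40)
  sim <- simulate_frap(cfg)
  f <- sim$series$frames
  plateau <- cfg$initial_intensity + cfg$background_level
  r2 <- frapkit:::dist2_grid(64, 64, cfg$pixel_size,
                             cfg$bleach_center[1], cfg$bleach_center[2])
  # compare once the total blur spans several pixels; at the bleach frame
  # itself the pixel-sampled disc differs from the continuum by O(px/sigma)
  for (j in c(10, 20, 40)) {
    s2 <- cfg$bleach_edge_sigma^2 +
      2 * cfg$diffusion_coeff * (j - 1) * cfg$frame_interval
    g_oracle <- oracle_disc_blur(r2, cfg$bleach_radius, s2)
    g_sim <- (plateau - f[, , cfg$n_prebleach + j]) /
      (cfg$initial_intensity * cfg$bleach_depth)
    expect_lt(max(abs(g_sim - g_oracle)), 0.02)
  }
})

test_that("Fourier-space ROI traces equal rasterized trace extraction", {
  cfg <- pipe_config(n_recovery = 50)
  sim <- simulate_frap(cfg)
  rois <- pipe_rois(cfg)
  cur <- extract_traces(sim$series, rois)
  tds <- (seq_len(cfg$n_recovery) - 1) * cfg$frame_interval
  s2 <- cfg$bleach_edge_sigma^2 + 2 * cfg$diffusion_coeff * tds
  for (nm in c("bleach", "reference")) {
    mask <- rasterize_roi(rois[[nm]], cfg$grid_shape, cfg$pixel_size)
    g <- frapkit:::sim_trace_sigma2(cfg, mask, s2)
    d0 <- g[1]
    pred <- cfg$initial_intensity *
      (1 - cfg$bleach_depth * (cfg$mobile_fraction * g +
                                 (1 - cfg$mobile_fraction) * d0)) +
      cfg$background_level
    got <- if (nm == "bleach") cur$I else cur$I_r
    expect_lt(max(abs(pred - got[(cfg$n_prebleach + 1):length(got)])), 1e-9)
  }
})

test_that("bit depth quantization clips and rounds", {
  cfg <- small_config(bit_depth = 8, n_recovery = 5,
                      noise_model = list(type = "gaussian", sigma = 30),
                      initial_intensity = 240)
  f <- simulate_frap(cfg)$series$frames
  expect_true(all(f >= 0 & f <= 255))
  expect_true(all(f == round(f)))
})

test_that("clustered site heterogeneity raises spatial variability", {
  cfg_u <- small_config(n_recovery = 2, bleach_depth = 0)
  cfg_c <- small_config(n_recovery = 2, bleach_depth = 0,
                        site_heterogeneity = "clustered")
  cv <- function(cfg, seed) {
    cfg$seed <- seed
    fr <- simulate_frap(cfg)$series$frames[, , 1] - cfg$background_level
    sd(fr) / mean(fr)
  }
  for (s in 1:5) expect_gt(cv(cfg_c, s), cv(cfg_u, s) + 0.1)
})

test_that("reference trace decays under monitor bleaching", {
  cfg <- pipe_config(monitor_bleach_rate = 2e-3, n_recovery = 60,
                     noise_model = list(type = "poisson_gaussian", gain = 1,
                                        sigma_read = 2))
  slopes <- vapply(1:5, function(s) {
    cfg$seed <- s
    cur <- extract_traces(simulate_frap(cfg)$series, pipe_rois(cfg))
    unname(stats::coef(stats::lm(cur$I_r ~ cur$t))[2])
  }, numeric(1))
  expect_true(all(slopes < 0))
})
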