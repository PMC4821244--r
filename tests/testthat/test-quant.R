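test_that("photobleaching correction follows the reference-anchored formula", {
  # direct substitution: I = 100, I_b = 10, I_r = 55 at a later frame,
  # pre-bleach mean of (I_r - I_b) = 90 -> I_c = (100 - 10) * 90 / 45 = 180
  cur <- frapkit:::new_frap_curve(
    t = c(-0.2, 0, 0.2), I = c(110, 100, 100), I_b = c(10, 10, 10),
    I_r = c(100, 60, 55), n_prebleach = 1, bleach_index = 2)
  out <- correct_photobleach(cur)
  expect_equal(out$I_c[3], 180)
  expect_equal(out$I_c[1], 100)

  # identity case: zero background, reference constant at its pre-bleach mean
  cur2 <- frapkit:::new_frap_curve(
    t = seq(-0.4, 0.6, by = 0.2), I = c(10, 9, 3, 4, 5, 6),
    I_b = rep(0, 6), I_r = rep(42, 6), n_prebleach = 2, bleach_index = 3)
  expect_equal(correct_photobleach(cur2)$I_c, cur2$I)

  # I == I_b -> I_c == 0
  cur3 <- frapkit:::new_frap_curve(
    t = c(-0.2, 0, 0.2), I = c(7, 7, 7), I_b = c(7, 7, 7),
    I_r = c(20, 18, 16), n_prebleach = 1, bleach_index = 2)
  expect_equal(correct_photobleach(cur3)$I_c, rep(0, 3))

  # non-positive reference margin is rejected with the frame index
  cur4 <- cur2; cur4$I_r[4] <- 0
  expect_error(correct_photobleach(cur4), "frame.*4")
})

test_that("pre-bleach normalization and its identities", {
  cur <- random_traces(seed = 3)
  cur <- normalize_prebleach(correct_photobleach(cur))
  expect_equal(mean(cur$I_cn[1:cur$n_prebleach]), 1, tolerance = 1e-12)

  # constant corrected trace -> I_cn == 1; scale invariance
  base <- correct_photobleach(frapkit:::new_frap_curve(
    t = c(-0.2, 0, 0.2, 0.4), I = c(50, 20, 30, 40), I_b = rep(0, 4),
    I_r = rep(10, 4), n_prebleach = 1, bleach_index = 2))
  n1 <- normalize_prebleach(base)
  base2 <- base; base2$I_c <- base$I_c * 2
  expect_equal(normalize_prebleach(base2)$I_cn, n1$I_cn)
  expect_equal(n1$I_cn[1], 1)
  # pre-bleach mean 50, later value 25 -> 0.5
  base3 <- base; base3$I_c <- c(50, 25, 25, 25)
  expect_equal(normalize_prebleach(base3)$I_cn[2], 0.5)
  base4 <- base; base4$I_c <- c(0, 1, 1, 1)
  expect_error(normalize_prebleach(base4), "positive")
})

test_that("post-bleach renormalization maps bleach frame to 0 and full recovery to 1", {
  mk <- function(icn) {
    cur <- frapkit:::new_frap_curve(
      t = (seq_along(icn) - 2) * 0.2, I = icn, I_b = rep(0, length(icn)),
      I_r = rep(1, length(icn)), n_prebleach = 1, bleach_index = 2)
    cur$I_c <- icn; cur$I_cn <- icn
    cur
  }
  out <- renormalize_postbleach(mk(c(1, 0.2, 0.6, 1)))
  expect_equal(out$I_dcn, c(1, 0, 0.5, 1))
  # forever at the bleach level -> identically 0 after the bleach
  out2 <- renormalize_postbleach(mk(c(1, 0.3, 0.3, 0.3)))
  expect_equal(out2$I_dcn[-1], rep(0, 3))
  expect_error(renormalize_postbleach(mk(c(1, 1.01, 1, 1))), "no bleach")
})

test_that("normalization identities hold on random traces", {
  for (s in 1:25) {
    cur <- random_traces(n_pre = sample(3:8, 1), n_post = 40, seed = s)
    cur <- renormalize_postbleach(normalize_prebleach(correct_photobleach(cur)))
    expect_lt(abs(mean(cur$I_cn[1:cur$n_prebleach]) - 1), 1e-9)
    expect_identical(cur$I_dcn[cur$bleach_index], 0)
  }
})

test_that("chain matches the independent oracle on random traces", {
  for (s in 1:20) {
    cur <- random_traces(seed = 100 + s)
    got <- renormalize_postbleach(normalize_prebleach(correct_photobleach(cur)))
    want <- oracle_chain(cur$I, cur$I_b, cur$I_r, cur$n_prebleach)
    expect_equal(got$I_c, want$I_c, tolerance = 1e-12)
    expect_equal(got$I_cn, want$I_cn, tolerance = 1e-12)
    expect_equal(got$I_dcn, want$I_dcn, tolerance = 1e-12)
  }
})

test_that("with constant reference and zero background the chain reduces to the simple form", {
  set.seed(9)
  n_pre <- 6; n <- 66
  I <- c(runif(n_pre, 95, 105), runif(n - n_pre, 20, 90))
  cur <- frapkit:::new_frap_curve(
    t = (seq_len(n) - n_pre - 1) * 0.2, I = I, I_b = rep(0, n),
    I_r = rep(77, n), n_prebleach = n_pre, bleach_index = n_pre + 1L)
  out <- renormalize_postbleach(normalize_prebleach(correct_photobleach(cur)))
  m <- mean(I[1:n_pre]); b <- n_pre + 1
  want <- (I / m - I[b] / m) / (1 - I[b] / m)
  expect_equal(out$I_dcn, want, tolerance = 1e-12)
})

test_that("final recovery level is the tail mean", {
  mk <- function(idcn, npre = 2) {
    n <- length(idcn)
    cur <- frapkit:::new_frap_curve(
      t = (seq_len(n) - npre - 1) * 0.2, I = idcn, I_b = rep(0, n),
      I_r = rep(1, n), n_prebleach = npre, bleach_index = npre + 1L)
    cur$I_dcn <- idcn
    cur
  }
  z <- mk(c(1, 1, rep(0, 30)))
  expect_equal(final_recovery(z), 0)
  expect_equal(final_recovery(z, tail_frames = 1), 0)
  # saturating exponential to 0.5 with tau << total time
  tt <- (0:499) * 0.2
  e <- mk(c(1, 1, 0.5 * (1 - exp(-tt / 2))))
  expect_equal(final_recovery(e), 0.5, tolerance = 1e-3)
  expect_error(final_recovery(z, tail_frames = 31), "exceeds")
})

test_that("half recovery time matches the analytic exponential half-rise", {
  dt <- 195.6 / 994
  mk_exp <- function(i_f, tau0, n = 994, npre = 6) {
    tt <- (0:(n - 1)) * dt
    idcn <- c(rep(1, npre), i_f * (1 - exp(-tt / tau0)))
    cur <- frapkit:::new_frap_curve(
      t = (seq_along(idcn) - npre - 1) * dt, I = idcn,
      I_b = rep(0, length(idcn)), I_r = rep(1, length(idcn)),
      n_prebleach = npre, bleach_index = npre + 1L)
    cur$I_dcn <- idcn
    cur
  }
  for (tau0 in c(5, 20, 45)) {
    cur <- mk_exp(0.8, tau0)
    i_f <- final_recovery(cur)
    half_level_time <- -tau0 * log(1 - i_f / (2 * 0.8))  # exact crossing of I_f/2
    res <- half_recovery_time(cur, i_f = i_f)
    expect_lt(abs(res$tau_half - half_level_time), dt)
    # close to tau0 * ln 2 because I_f here is ~ the asymptote
    expect_lt(abs(res$tau_half - tau0 * log(2)), max(dt, 0.02 * tau0))
    expect_true(res$tau_a <= res$tau_half && res$tau_half <= res$tau_b)
    # smoothing moves the estimate by at most 2 frame intervals (noiseless)
    res1 <- half_recovery_time(cur, smoothing_window = 1, i_f = i_f)
    expect_lt(abs(res$tau_half - res1$tau_half), 2 * dt)
    # literal extrema rule agrees on a noiseless monotone curve
    resl <- half_recovery_time(cur, i_f = i_f, rule = "literal")
    expect_lt(abs(resl$tau_half - res$tau_half), 2 * dt)
  }
  # immediate step to I_f -> tau = 0
  step <- mk_exp(0.8, 1e-9)
  expect_equal(half_recovery_time(step, i_f = 0.8)$tau_half, 0)
  # I_f <= 0 -> immobile, NA
  flat <- mk_exp(0, 10)
  out <- half_recovery_time(flat, i_f = 0)
  expect_true(is.na(out$tau_half) && out$immobile)
  # inconsistent I_f is an error
  low <- mk_exp(0.2, 10)
  expect_error(half_recovery_time(low, i_f = 0.9), "never")
})

test_that("disc ROI rasterization covers the expected pixel count", {
  mask <- rasterize_roi(roi_disc(c(11.2, 11.2), 2.5), c(256L, 256L),
                        22.49 / 256)
  expect_gte(sum(mask), 2400)
  expect_lte(sum(mask), 2650)
})

test_that("trace extraction averages ROI pixels and assigns times", {
  f <- array(100, dim = c(32, 32, 6))
  ser <- frap_series(f, pixel_size = 0.1, frame_interval = 0.5,
                     bleach_frame = 3)
  rois <- roi_set(roi_disc(c(1.5, 1.5), 0.5), roi_disc(c(2.4, 0.6), 0.25),
                  roi_rect(c(0.05, 3.05), c(2.45, 3.05)))
  cur <- extract_traces(ser, rois)
  expect_equal(cur$I, rep(100, 6))
  expect_equal(cur$I_r, rep(100, 6))
  expect_equal(cur$t, ((1:6) - 3) * 0.5)
  # empty/too-small ROI rejected
  tiny <- roi_set(roi_disc(c(1.5, 1.5), 0.5), roi_disc(c(2.4, 0.6), 0.05),
                  roi_rect(c(0.05, 3.05), c(2.45, 3.05)))
  expect_error(extract_traces(ser, tiny), "fewer than")
  # overlapping ROIs rejected
  overlap <- roi_set(roi_disc(c(1.5, 1.5), 0.5), roi_disc(c(1.6, 1.5), 0.5),
                     roi_rect(c(0.05, 3.05), c(2.45, 3.05)))
  expect_error(extract_traces(ser, overlap), "disjoint")
})

test_that("correction removes monitor bleaching", {
  cfg <- pipe_config(monitor_bleach_rate = 2e-3, n_recovery = 800,
                     mobile_fraction = 0.7)
  sim <- simulate_frap(cfg)
  res <- analyze_frap(sim$series, pipe_rois(cfg))
  expect_lt(abs(res$i_f - 0.7), 0.02)
  # without the reference correction, the tail is biased down by at least
  # the cumulative monitor loss
  cur <- extract_traces(sim$series, pipe_rois(cfg))
  cur$I_c <- cur$I - cur$I_b      # background subtraction only
  cur <- renormalize_postbleach(normalize_prebleach(cur))
  i_f_raw <- final_recovery(cur)
  loss <- 1 - (1 - cfg$monitor_bleach_rate)^(cfg$n_prebleach + cfg$n_recovery)
  expect_gte(0.7 - i_f_raw, loss / 2)
})

test_that("recovery ceiling: long noiseless runs reach the mobile fraction", {
  for (fm in c(0.5, 0.85)) {
    cfg <- pipe_config(mobile_fraction = fm, n_recovery = 800)
    res <- analyze_frap(simulate_frap(cfg)$series, pipe_rois(cfg))
    expect_lt(abs(res$i_f - fm), 0.02)
  }
})

test_that("analysis is deterministic and reports staged errors", {
  cfg <- pipe_config(n_recovery = 30,
                     noise_model = list(type = "poisson_gaussian", gain = 1,
                                        sigma_read = 2))
  r1 <- analyze_frap(simulate_frap(cfg)$series, pipe_rois(cfg))
  r2 <- analyze_frap(simulate_frap(cfg)$series, pipe_rois(cfg))
  expect_identical(r1$i_f, r2$i_f)
  expect_identical(r1$tau_half, r2$tau_half)
  expect_equal(r1$mobile_fraction + r1$immobile_fraction, 100)
  # stage tag propagates: a "background" region brighter than the reference
  f <- array(100, dim = c(32, 32, 8))
  f[28:32, , ] <- 250
  ser <- frap_series(f, pixel_size = 0.1, frame_interval = 0.5,
                     bleach_frame = 3)
  rois <- roi_set(roi_disc(c(1.5, 1.5), 0.5), roi_disc(c(2.4, 0.6), 0.25),
                  roi_rect(c(0.05, 3.05), c(2.75, 3.05)))
  expect_error(analyze_frap(ser, rois), "correct_photobleach")
})
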