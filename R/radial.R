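# Azimuthally averaged recovery profiles around the bleach disc.

new_radial_profile <- function(bin_centers, mean_intensity, n_pixels,
                               timepoint_label, frame, max_radius,
                               sd_intensity = rep(NA_real_, length(bin_centers))) {
  structure(list(bin_centers = bin_centers, mean_intensity = mean_intensity,
                 sd_intensity = sd_intensity, n_pixels = n_pixels,
                 timepoint_label = timepoint_label, frame = frame,
                 max_radius = max_radius),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile '%s': %d bins to %.2f um (frame %s)\n",
              x$timepoint_label, length(x$bin_centers), x$max_radius,
              ifelse(is.na(x$frame), "-", x$frame)))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(timepoint = x$timepoint_label, bin_center_um = x$bin_centers,
             mean = x$mean_intensity, sd = x$sd_intensity, n = x$n_pixels)
}

resolve_timepoint_frames <- function(series, timepoints, frap_result) {
  nt <- dim(series$frames)[3]
  b <- series$bleach_frame
  t <- frame_times(series)
  vapply(timepoints, function(lab) {
    switch(lab,
      before = b - 1L,
      after = b,
      half = {
        if (is.null(frap_result) || is.na(frap_result$tau_half))
          stop("timepoint 'half' needs a frap_result with a defined tau_half",
               call. = FALSE)
        which.min(abs(t - frap_result$tau_half))
      },
      final = nt,
      stop("unknown timepoint label: ", lab, call. = FALSE))
  }, integer(1))
}

#' Photobleach-corrected radial intensity profiles
#'
#' For each requested timepoint, applies the per-frame photobleaching
#' correction (the scalar factor from the reference/background traces, plus
#' background subtraction) to the frame and averages the corrected pixel
#' intensities in annular bins by pixel-center distance from the disc
#' center.  Timepoint labels: `before` (last pre-bleach frame), `after`
#' (first post-bleach frame), `half` (frame nearest the half recovery time,
#' which requires `frap_result`), `final` (last frame).
#'
#' @param series a [frap_series()].
#' @param rois a [roi_set()] supplying the reference and background regions
#'   (and, by default, the profile center from the bleach disc).
#' @param frap_result optional [analyze_frap()] result, required for the
#'   `half` label.
#' @param center c(x, y) um; defaults to the bleach-disc center.
#' @param max_radius outer profile radius, um (default 7, i.e. a 14 um
#'   diameter).
#' @param bin_width annulus width, um.
#' @param timepoints character vector of labels.
#' @return named list of `radial_profile` objects.
#' @export
radial_profiles <- function(series, rois, frap_result = NULL, center = NULL,
                            max_radius = 7, bin_width = 0.25,
                            timepoints = c("before", "after", "half", "final")) {
  d <- dim(series$frames)
  p <- series$pixel_size
  if (is.null(center)) {
    stopifnot(rois$bleach$shape == "disc")
    center <- rois$bleach$center
  }
  ext_x <- (d[2] - 1) * p; ext_y <- (d[1] - 1) * p
  if (center[1] - max_radius < 0 || center[1] + max_radius > ext_x ||
      center[2] - max_radius < 0 || center[2] + max_radius > ext_y)
    stop("profile disc of max_radius extends outside the image", call. = FALSE)
  curve <- extract_traces(series, rois)
  ref <- curve$I_r - curve$I_b
  if (any(ref <= 0))
    stop("reference minus background is non-positive", call. = FALSE)
  corr <- mean(ref[seq_len(curve$n_prebleach)]) / ref
  frames_idx <- resolve_timepoint_frames(series, timepoints, frap_result)
  r <- sqrt(dist2_grid(d[1], d[2], p, center[1], center[2]))
  edges <- seq(0, max_radius, by = bin_width)
  if (edges[length(edges)] < max_radius) edges <- c(edges, max_radius)
  nb <- length(edges) - 1L
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  sel <- bin >= 1 & bin <= nb & r <= max_radius
  bin_f <- factor(bin[sel], levels = seq_len(nb))
  counts <- as.integer(table(bin_f))
  if (any(counts == 0))
    stop("empty annulus at bin index ", which(counts == 0)[1], call. = FALSE)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- lapply(seq_along(timepoints), function(i) {
    k <- frames_idx[i]
    fr <- (series$frames[, , k] - curve$I_b[k]) * corr[k]
    means <- as.numeric(tapply(fr[sel], bin_f, mean))
    new_radial_profile(centers, means, counts, timepoints[i], k, max_radius)
  })
  names(out) <- timepoints
  out
}

#' Average radial profiles across replicates
#'
#' Per-bin mean and sample standard deviation of replicate profiles with
#' identical binning (and the same timepoint label).
#'
#' @param profiles list of `radial_profile` objects.
#' @return a `radial_profile` whose `sd_intensity` holds the across-replicate
#'   sample standard deviation (0 for a single replicate).
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "radial_profile")))
  ref <- profiles[[1]]
  for (pr in profiles[-1]) {
    if (length(pr$bin_centers) != length(ref$bin_centers) ||
        any(abs(pr$bin_centers - ref$bin_centers) > 1e-12))
      stop("replicate profiles have mismatched bins", call. = FALSE)
  }
  m <- do.call(rbind, lapply(profiles, `[[`, "mean_intensity"))
  sdv <- if (nrow(m) == 1) rep(0, ncol(m)) else apply(m, 2, stats::sd)
  new_radial_profile(ref$bin_centers, colMeans(m), ref$n_pixels,
                     ref$timepoint_label, NA_integer_, ref$max_radius,
                     sd_intensity = sdv)
}
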