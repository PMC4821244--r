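# FRAP quantification: ROI traces, photobleaching correction, double
# normalization, final recovery level and half recovery time.
#
# With I, I_b, I_r the mean intensities of the bleached, background and
# reference regions, and <.>_pre the mean over the pre-bleach frames:
#
#   I_c[k]   = (I[k] - I_b[k]) * <I_r - I_b>_pre / (I_r[k] - I_b[k])
#   I_cn[k]  = I_c[k] / <I_c>_pre
#   I_dcn[k] = (I_cn[k] - I_cn[b]) / (1 - I_cn[b]),  b = first post-bleach
#   I_f      = mean of I_dcn over the last tail frames
#   tau_1/2  = first time the (smoothed) post-bleach I_dcn reaches I_f / 2
#
# so that <I_cn>_pre = 1 and I_dcn[b] = 0 exactly, a fully recovered frame
# maps to I_dcn = 1, and I_f estimates the mobile fraction.

new_frap_curve <- function(t, I, I_b, I_r, n_prebleach, bleach_index,
                           I_c = NULL, I_cn = NULL, I_dcn = NULL) {
  n <- length(t)
  stopifnot(length(I) == n, length(I_b) == n, length(I_r) == n,
            n_prebleach >= 1, bleach_index == n_prebleach + 1,
            bleach_index <= n)
  structure(list(t = t, I = I, I_b = I_b, I_r = I_r,
                 I_c = I_c, I_cn = I_cn, I_dcn = I_dcn,
                 n_prebleach = as.integer(n_prebleach),
                 bleach_index = as.integer(bleach_index)),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("FRAP curve: %d frames (%d pre-bleach), stages: %s\n",
              length(x$t), x$n_prebleach,
              paste(c("raw", if (!is.null(x$I_c)) "corrected",
                      if (!is.null(x$I_cn)) "normalized",
                      if (!is.null(x$I_dcn)) "renormalized"), collapse = " + ")))
  invisible(x)
}

#' @export
as.data.frame.frap_curve <- function(x, ...) {
  d <- data.frame(t = x$t, I = x$I, I_b = x$I_b, I_r = x$I_r)
  if (!is.null(x$I_c)) d$I_c <- x$I_c
  if (!is.null(x$I_cn)) d$I_cn <- x$I_cn
  if (!is.null(x$I_dcn)) d$I_dcn <- x$I_dcn
  d
}

#' Extract raw ROI traces from an image series
#'
#' Computes, for every frame, the arithmetic mean intensity over each ROI's
#' pixels (membership by pixel center).  Times are taken from the series'
#' frame interval with t = 0 at the first post-bleach frame.
#'
#' @param series a [frap_series()].
#' @param rois a [roi_set()].
#' @return a `frap_curve` carrying the raw `I`, `I_b`, `I_r` traces.
#' @export
extract_traces <- function(series, rois) {
  d <- dim(series$frames)
  masks <- rasterize_roi_set(rois, d[1:2], series$pixel_size)
  flat <- series$frames
  dim(flat) <- c(d[1] * d[2], d[3])
  tr <- function(mask) colMeans(flat[as.vector(mask), , drop = FALSE])
  npre <- series$bleach_frame - 1L
  new_frap_curve(t = frame_times(series),
                 I = tr(masks$bleach), I_b = tr(masks$background),
                 I_r = tr(masks$reference),
                 n_prebleach = npre, bleach_index = series$bleach_frame)
}

pre_idx <- function(curve) seq_len(curve$n_prebleach)

#' Photobleaching correction against the reference region
#'
#' Background-subtracts the bleach and reference traces and rescales every
#' frame by the reference region's deviation from its pre-bleach mean, which
#' removes monitor bleaching:
#' `I_c[k] = (I[k] - I_b[k]) * <I_r - I_b>_pre / (I_r[k] - I_b[k])`.
#'
#' @param curve a `frap_curve` with raw traces.
#' @return the curve with `I_c` filled in.
#' @export
correct_photobleach <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  ref <- curve$I_r - curve$I_b
  bad <- which(ref <= 0)
  if (length(bad))
    stop("reference minus background is non-positive at frame(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  ref_pre <- mean(ref[pre_idx(curve)])
  if (ref_pre <= 0)
    stop("pre-bleach mean of (I_r - I_b) must be positive", call. = FALSE)
  curve$I_c <- (curve$I - curve$I_b) * ref_pre / ref
  curve
}

#' Normalize to the pre-bleach level
#'
#' Divides the corrected trace by its pre-bleach mean:
#' `I_cn[k] = I_c[k] / <I_c>_pre`, so the pre-bleach mean of `I_cn` is 1.
#'
#' @param curve a `frap_curve` with `I_c`.
#' @return the curve with `I_cn` filled in.
#' @export
normalize_prebleach <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"), !is.null(curve$I_c))
  m <- mean(curve$I_c[pre_idx(curve)])
  if (m <= 0)
    stop("pre-bleach mean of I_c must be positive", call. = FALSE)
  curve$I_cn <- curve$I_c / m
  curve
}

#' Renormalize to the first post-bleach frame
#'
#' Subtracts the first post-bleach value and rescales so that the bleach
#' frame maps to 0 and a fully recovered frame to 1:
#' `I_dcn[k] = (I_cn[k] - I_cn[b]) / (1 - I_cn[b])`.
#'
#' @param curve a `frap_curve` with `I_cn`.
#' @return the curve with `I_dcn` filled in.
#' @export
renormalize_postbleach <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"), !is.null(curve$I_cn))
  b <- curve$bleach_index
  icb <- curve$I_cn[b]
  if (icb >= 1)
    stop("no bleach detected: I_cn at the bleach frame is ", signif(icb, 4),
         " (>= 1)", call. = FALSE)
  curve$I_dcn <- (curve$I_cn - icb) / (1 - icb)
  curve
}

#' Final recovery level
#'
#' Mean of the doubly normalized trace over the last `tail_frames` frames.
#' `tail_frames = 1` reproduces the literal "last measurement" definition;
#' the default of 10 averages away frame noise.
#'
#' @param curve a `frap_curve` with `I_dcn`.
#' @param tail_frames number of trailing frames to average (>= 1).
#' @return the final recovery level `I_f` (dimensionless).
#' @export
final_recovery <- function(curve, tail_frames = 10) {
  stopifnot(inherits(curve, "frap_curve"), !is.null(curve$I_dcn),
            tail_frames >= 1)
  n <- length(curve$I_dcn)
  n_post <- n - curve$bleach_index + 1L
  if (tail_frames > n_post)
    stop("tail_frames (", tail_frames, ") exceeds the post-bleach length (",
         n_post, ")", call. = FALSE)
  mean(curve$I_dcn[(n - tail_frames + 1L):n])
}

# centered moving average with reflect padding; w odd
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  stopifnot(w %% 2 == 1)
  h <- (w - 1L) / 2L
  n <- length(x)
  if (n == 1) return(x)
  refl <- function(idx) {
    idx <- abs(idx - 1L) + 1L                 # reflect at the left edge
    idx <- n - abs(n - idx)                   # reflect at the right edge
    idx
  }
  xp <- x[refl(seq.int(1L - h, n + h))]
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2)[(h + 1L):(h + n)])
}

#' Half recovery time
#'
#' Smooths the post-bleach doubly normalized trace with a centered moving
#' average, then locates the half-recovery level `I_f / 2`: `tau_b` is the
#' time of the first smoothed sample at or above the level, `tau_a` the time
#' of the sample before it, and `tau_half` the linear interpolation between
#' them at the level (or their midpoint with `method = "midpoint"`).  With
#' `rule = "literal"` the crossing pair is instead the literal extrema rule —
#' `tau_a` at the maximum value below the level and `tau_b` at the minimum
#' value above it — which is fragile under noise and kept for comparison.
#'
#' If the first post-bleach sample is already at or above the level,
#' `tau_half = 0`.  If `i_f <= 0` the molecule is reported immobile
#' (`tau_half = NA`).  A positive `i_f` whose level is never reached is an
#' error (inconsistent with the trace).
#'
#' @param curve a `frap_curve` with `I_dcn`.
#' @param smoothing_window odd moving-average width in frames (default 11;
#'   1 disables smoothing).
#' @param i_f final recovery level; computed by [final_recovery()] with
#'   `tail_frames` when omitted.
#' @param tail_frames passed to [final_recovery()] when `i_f` is missing.
#' @param method `"interpolate"` (default) or `"midpoint"`.
#' @param rule `"crossing"` (default, first crossing after smoothing) or
#'   `"literal"`.
#' @return list with `tau_a`, `tau_b`, `tau_half` (seconds).
#' @export
half_recovery_time <- function(curve, smoothing_window = 11, i_f = NULL,
                               tail_frames = 10,
                               method = c("interpolate", "midpoint"),
                               rule = c("crossing", "literal")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "frap_curve"), !is.null(curve$I_dcn))
  if (is.null(i_f)) i_f <- final_recovery(curve, tail_frames)
  if (is.na(i_f) || i_f <= 0)
    return(list(tau_a = NA_real_, tau_b = NA_real_, tau_half = NA_real_,
                immobile = TRUE))
  b <- curve$bleach_index
  post <- curve$I_dcn[b:length(curve$I_dcn)]
  tpost <- curve$t[b:length(curve$t)]
  s <- smooth_ma(post, smoothing_window)
  half <- i_f / 2
  if (rule == "literal") {
    below <- which(s < half); above <- which(s > half)
    if (!length(above))
      stop("trace never exceeds I_f / 2; inconsistent with I_f = ",
           signif(i_f, 4), call. = FALSE)
    if (!length(below))
      return(list(tau_a = 0, tau_b = 0, tau_half = 0, immobile = FALSE))
    ia <- below[which.max(s[below])]
    ib <- above[which.min(s[above])]
    tau_a <- tpost[ia]; tau_b <- tpost[ib]
    tau_half <- if (method == "interpolate" && s[ib] != s[ia])
      tau_a + (half - s[ia]) * (tau_b - tau_a) / (s[ib] - s[ia])
    else (tau_a + tau_b) / 2
    return(list(tau_a = tau_a, tau_b = tau_b, tau_half = tau_half,
                immobile = FALSE))
  }
  j <- which(s >= half)[1]
  if (is.na(j))
    stop("smoothed trace never reaches I_f / 2; inconsistent with I_f = ",
         signif(i_f, 4), call. = FALSE)
  if (j == 1L)
    return(list(tau_a = 0, tau_b = 0, tau_half = 0, immobile = FALSE))
  tau_a <- tpost[j - 1L]; tau_b <- tpost[j]
  tau_half <- if (method == "interpolate" && s[j] != s[j - 1L])
    tau_a + (half - s[j - 1L]) * (tau_b - tau_a) / (s[j] - s[j - 1L])
  else (tau_a + tau_b) / 2
  list(tau_a = tau_a, tau_b = tau_b, tau_half = tau_half, immobile = FALSE)
}

#' Full FRAP analysis of an image series
#'
#' Runs the complete chain: trace extraction, photobleaching correction,
#' double normalization, final recovery level and half recovery time, and
#' converts the final level into mobile / immobile percentages
#' (`mobile = 100 * clip(I_f, 0, 1)`).
#'
#' @param series a [frap_series()].
#' @param rois a [roi_set()].
#' @param options list; recognised entries `tail_frames` (default 10),
#'   `smoothing_window` (default 11), `method`, `rule` (see
#'   [half_recovery_time()]).
#' @return object of class `frap_result` with `i_f`, `tau_a`, `tau_b`,
#'   `tau_half`, `mobile_fraction`, `immobile_fraction` (percent), the full
#'   `curve`, and a `provenance` record.
#' @export
analyze_frap <- function(series, rois, options = list()) {
  opt <- utils::modifyList(list(tail_frames = 10, smoothing_window = 11,
                                method = "interpolate", rule = "crossing"),
                           options)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  curve <- stage("extract_traces", extract_traces(series, rois))
  curve <- stage("correct_photobleach", correct_photobleach(curve))
  curve <- stage("normalize_prebleach", normalize_prebleach(curve))
  curve <- stage("renormalize_postbleach", renormalize_postbleach(curve))
  i_f <- stage("final_recovery", final_recovery(curve, opt$tail_frames))
  tau <- stage("half_recovery_time",
               half_recovery_time(curve, opt$smoothing_window, i_f = i_f,
                                  method = opt$method, rule = opt$rule))
  mobile <- 100 * min(max(i_f, 0), 1)
  structure(list(
    i_f = i_f, tau_a = tau$tau_a, tau_b = tau$tau_b, tau_half = tau$tau_half,
    mobile_fraction = mobile, immobile_fraction = 100 - mobile,
    smoothing_window = opt$smoothing_window, tail_frames = opt$tail_frames,
    curve = curve,
    provenance = list(rois = rois, options = opt,
                      config = series$metadata$config)
  ), class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("FRAP result: I_f = %.4f, mobile = %.1f%%, immobile = %.1f%%\n",
              x$i_f, x$mobile_fraction, x$immobile_fraction))
  if (is.na(x$tau_half)) {
    cat("  tau_1/2: undefined (immobile)\n")
  } else {
    cat(sprintf("  tau_1/2 = %.2f s (tau_a = %.2f, tau_b = %.2f)\n",
                x$tau_half, x$tau_a, x$tau_b))
  }
  invisible(x)
}
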