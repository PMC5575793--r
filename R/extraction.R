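#' ROI specification for trace extraction
#'
#' Geometry of the signal and background regions. The signal statistic
#' is the mean of the `top_k` brightest pixels within a disc of `radius`
#' pixels around the tracked soma center — robust to sub-pixel tracking
#' error and partial soma coverage. The background is the plain mean of
#' a fixed disc in a neuron-free region.
#'
#' @param radius Signal ROI disc radius, pixels (default 10).
#' @param top_k Number of brightest pixels averaged (default 100).
#' @param background_center `(row, col)` of the background disc.
#' @param background_radius Background disc radius, pixels (default 10).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(radius = 10, top_k = 100,
                     background_center, background_radius = 10) {
  stopifnot(radius > 0, top_k >= 1,
            length(background_center) == 2, background_radius > 0)
  structure(list(radius = radius, top_k = as.integer(top_k),
                 background_center = as.numeric(background_center),
                 background_radius = background_radius),
            class = "roi_spec")
}

#' Pick a background ROI from the first frame
#'
#' Chooses a neuron-free background disc center: among the pixels in
#' the lowest intensity decile that keep the disc inside the frame, the
#' one farthest from `avoid` (the neuron position).
#'
#' @param frame First frame of a stack.
#' @param avoid `(row, col)` to keep away from (the neuron position).
#' @param radius Background disc radius.
#' @param min_dist Minimum distance from `avoid`, pixels.
#' @return `(row, col)` background disc center.
#' @export
pick_background <- function(frame, avoid, radius = 10, min_dist = 30) {
  thr <- stats::quantile(frame, 0.1)
  idx <- which(frame <= thr, arr.ind = TRUE)
  inside <- idx[, 1] > radius & idx[, 1] <= nrow(frame) - radius &
    idx[, 2] > radius & idx[, 2] <= ncol(frame) - radius
  idx <- idx[inside, , drop = FALSE]
  d <- sqrt((idx[, 1] - avoid[1])^2 + (idx[, 2] - avoid[2])^2)
  idx <- idx[d >= min_dist, , drop = FALSE]
  if (nrow(idx) == 0) stop("no background region away from the neuron")
  d <- d[d >= min_dist]
  unname(as.numeric(idx[which.max(d), ]))
}

# pixels whose center lies within `radius` of the rounded center;
# returns in-frame coordinates in (row, col) scan order
disc_pixels <- function(frame_dim, center, radius) {
  ctr <- round(center)
  g <- expand.grid(row = (ctr[1] - floor(radius)):(ctr[1] + floor(radius)),
                   col = (ctr[2] - floor(radius)):(ctr[2] + floor(radius)))
  g <- g[(g$row - ctr[1])^2 + (g$col - ctr[2])^2 <= radius^2, ]
  g <- g[g$row >= 1 & g$row <= frame_dim[1] &
           g$col >= 1 & g$col <= frame_dim[2], ]
  g <- g[order(g$row, g$col), ]
  as.matrix(g)
}

#' Signal ROI intensity: mean of the top-k brightest pixels
#'
#' Mean pixel intensity of the `spec$top_k` brightest pixels of a disc
#' of `spec$radius` pixels around `center`. If the in-frame part of the
#' disc holds fewer than `top_k` pixels, all available pixels are used
#' and the result carries attribute `truncated = TRUE`. Ties at the
#' cutoff are resolved by (row, col) scan order, so the statistic is
#' bit-for-bit reproducible.
#'
#' @param frame Numeric matrix.
#' @param center `(row, col)` ROI center (rounded internally).
#' @param spec A [roi_spec()].
#' @return Mean intensity (scalar), possibly with attribute `truncated`.
#' @export
roi_intensity <- function(frame, center, spec) {
  px <- disc_pixels(dim(frame), center, spec$radius)
  if (nrow(px) == 0) stop("ROI disc lies fully outside the frame")
  vals <- frame[px]
  k <- min(spec$top_k, length(vals))
  # stable order: descending value, ties by scan order (px is scan-ordered)
  top <- vals[order(-vals)[seq_len(k)]]
  out <- mean(top)
  if (k < spec$top_k) attr(out, "truncated") <- TRUE
  out
}

#' Background ROI intensity
#'
#' Plain mean over all pixels of the background disc (not top-k): the
#' per-frame lighting reference subtracted from the signal ROI.
#'
#' @param frame Numeric matrix.
#' @param spec A [roi_spec()].
#' @param signal_center Optional `(row, col)`; if given, an error is
#'   raised when the signal and background discs overlap.
#' @return Mean background intensity (scalar).
#' @export
background_intensity <- function(frame, spec, signal_center = NULL) {
  if (!is.null(signal_center)) {
    d <- sqrt(sum((round(signal_center) -
                     round(spec$background_center))^2))
    if (d <= spec$radius + spec$background_radius) {
      stop("background ROI overlaps the signal ROI")
    }
  }
  px <- disc_pixels(dim(frame), spec$background_center,
                    spec$background_radius)
  if (nrow(px) == 0) stop("background ROI lies fully outside the frame")
  mean(frame[px])
}

# shared per-frame extraction loop over one stack
extract_channel <- function(stack, traj, spec) {
  nf <- n_frames(stack)
  roi <- numeric(nf); back <- numeric(nf)
  for (k in seq_len(nf)) {
    fr <- stack[, , k]
    ctr <- c(traj$row[k], traj$col[k])
    roi[k] <- roi_intensity(fr, ctr, spec)
    back[k] <- background_intensity(fr, spec, signal_center = ctr)
  }
  list(roi = roi, back = back)
}

new_calcium_trace <- function(time, mode, protocol, df) {
  structure(list(time = time, mode = mode, protocol = protocol,
                 data = df, baseline = NA_real_),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %s, %d frames (%d valid)",
              x$mode, length(x$time), sum(x$data$valid)))
  if (!is.na(x$baseline)) {
    cat(sprintf(", baseline = %.4g", x$baseline))
  }
  cat("\n")
  invisible(x)
}

#' Ratiometric calcium trace
#'
#' Per frame, computes the background-subtracted green/red intensity
#' ratio \eqn{R = (I_{G,ROI} - I_{G,back}) / (I_{R,ROI} - I_{R,back})}
#' along the trajectory. Because motion, focus and illumination
#' artifacts multiply both channels identically, they cancel in the
#' ratio. Frames where the red denominator is not positive are flagged
#' invalid and excluded from downstream metrics.
#'
#' @param traj A `trajectory` from [track_neuron()].
#' @param green,red Aligned [image_stack()]s of equal length.
#' @param spec A [roi_spec()].
#' @param protocol A [stim_protocol()] carried along for normalization
#'   and metrics.
#' @param subtract_red_background Subtract the background in the red
#'   channel before dividing (default `TRUE`); set `FALSE` for the
#'   dialect that divides by the raw red ROI intensity.
#' @return A `calcium_trace` (mode `"ratiometric"`, not yet normalized).
#' @export
ratio_trace <- function(traj, green, red, spec, protocol,
                        subtract_red_background = TRUE) {
  stopifnot(inherits(green, "image_stack"), inherits(red, "image_stack"))
  if (n_frames(green) != n_frames(red)) stop("stacks differ in length")
  if (nrow(traj) != n_frames(green)) {
    stop("trajectory does not match the stacks")
  }
  g <- extract_channel(green, traj, spec)
  r <- extract_channel(red, traj, spec)
  denom <- if (subtract_red_background) r$roi - r$back else r$roi
  R <- (g$roi - g$back) / denom
  valid <- denom > 0
  df <- data.frame(frame = seq_len(nrow(traj)),
                   I_G_roi = g$roi, I_G_back = g$back,
                   I_R_roi = r$roi, I_R_back = r$back,
                   R_or_F = R, valid = valid)
  new_calcium_trace(frame_times(green), "ratiometric", protocol, df)
}

#' Single-channel fluorescence trace
#'
#' When only the GCaMP channel is available:
#' \eqn{F = I_{G,ROI} - I_{G,back}} per frame.
#'
#' @inheritParams ratio_trace
#' @return A `calcium_trace` (mode `"single_channel"`, not yet
#'   normalized).
#' @export
fluor_trace <- function(traj, green, spec, protocol) {
  stopifnot(inherits(green, "image_stack"))
  if (nrow(traj) != n_frames(green)) {
    stop("trajectory does not match the stack")
  }
  g <- extract_channel(green, traj, spec)
  df <- data.frame(frame = seq_len(nrow(traj)),
                   I_G_roi = g$roi, I_G_back = g$back,
                   I_R_roi = NA_real_, I_R_back = NA_real_,
                   R_or_F = g$roi - g$back, valid = TRUE)
  new_calcium_trace(frame_times(green), "single_channel", protocol, df)
}

#' Normalize a trace to its pre-stimulus baseline
#'
#' The baseline \eqn{R_0} (or \eqn{F_0}) is the mean of `R_or_F` over
#' all valid frames before the first stimulus onset; the normalized
#' trace is \eqn{\Delta R/R_0 = (R - R_0)/R_0}.
#'
#' @param trace A `calcium_trace` from [ratio_trace()] or
#'   [fluor_trace()].
#' @param min_baseline_frames Minimum number of valid pre-stimulus
#'   frames required (default 5).
#' @return The trace with `baseline` set and a `dRR` column added.
#' @export
normalize_trace <- function(trace, min_baseline_frames = 5) {
  stopifnot(inherits(trace, "calcium_trace"))
  onset <- trace$protocol$onsets[1]
  pre <- trace$time < onset & trace$data$valid
  if (sum(pre) < min_baseline_frames) {
    stop(sprintf("only %d valid pre-stimulus frames (need %d)",
                 sum(pre), min_baseline_frames))
  }
  baseline <- mean(trace$data$R_or_F[pre])
  if (trace$mode == "ratiometric" && baseline <= 0) {
    stop("non-positive baseline ratio")
  }
  if (baseline == 0) stop("zero baseline")
  trace$baseline <- baseline
  trace$data$dRR <- (trace$data$R_or_F - baseline) / baseline
  trace
}

#' Build a calcium trace directly from a dR/R0 series
#'
#' Constructs a normalized `calcium_trace` from an already-computed
#' \eqn{\Delta R/R_0} series (e.g. the trace-level simulator), so the
#' metric layer can be exercised without rendering images.
#'
#' @param time Sample times, seconds.
#' @param dRR \eqn{\Delta R/R_0} values.
#' @param protocol A [stim_protocol()].
#' @param valid Optional logical validity flags.
#' @return A normalized `calcium_trace`.
#' @export
trace_from_dRR <- function(time, dRR, protocol, valid = TRUE) {
  stopifnot(length(time) == length(dRR))
  valid <- rep_len(valid, length(time))
  df <- data.frame(frame = seq_along(time),
                   I_G_roi = NA_real_, I_G_back = NA_real_,
                   I_R_roi = NA_real_, I_R_back = NA_real_,
                   R_or_F = 1 + dRR, valid = valid, dRR = dRR)
  tr <- new_calcium_trace(time, "synthetic", protocol, df)
  tr$baseline <- 1
  tr
}
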