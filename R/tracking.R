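#' Locate the labeled neuron in a single frame
#'
#' Finds the intensity-weighted centroid of the brightest connected
#' region of the frame: the frame is thresholded halfway between its
#' minimum and maximum, the connected component containing the global
#' maximum is extracted (4-connectivity), and its intensity-weighted
#' centroid is returned. With a `hint`, the search is restricted to a
#' square window around the hint, so a dimmer but nearer landmark can be
#' selected over a brighter distant one.
#'
#' @param frame Numeric matrix (one image frame).
#' @param hint Optional `(row, col)` near the expected position.
#' @param hint_radius Half-width of the search window around `hint`,
#'   pixels.
#' @return Numeric `(row, col)` centroid (sub-pixel).
#' @export
locate_neuron <- function(frame, hint = NULL, hint_radius = 15) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  r0 <- 1L; c0 <- 1L
  if (!is.null(hint)) {
    stopifnot(length(hint) == 2)
    r0 <- max(1L, as.integer(round(hint[1] - hint_radius)))
    c0 <- max(1L, as.integer(round(hint[2] - hint_radius)))
    r1 <- min(nrow(frame), as.integer(round(hint[1] + hint_radius)))
    c1 <- min(ncol(frame), as.integer(round(hint[2] + hint_radius)))
    frame <- frame[r0:r1, c0:c1, drop = FALSE]
  }
  lo <- min(frame); hi <- max(frame)
  if (hi <= lo) stop("no landmark: frame is flat")
  mask <- frame >= lo + 0.5 * (hi - lo)
  peak <- peak_pixel(frame)
  comp <- flood_component(mask, peak)
  w <- frame[comp] - lo
  if (sum(w) <= 0) w <- rep(1, nrow(comp))
  ctr <- c(sum(comp[, 1] * w), sum(comp[, 2] * w)) / sum(w)
  ctr + c(r0 - 1L, c0 - 1L)
}

# brightest pixel; ties broken by smallest row, then smallest column
peak_pixel <- function(m) {
  idx <- which(m == max(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  idx[1, ]
}

# 4-connected component of `mask` containing `seed`; returns a matrix of
# (row, col) member coordinates. Queue-based flood fill.
flood_component <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  queue <- matrix(as.integer(seed), ncol = 2)
  seen[seed[1], seed[2]] <- TRUE
  out <- queue
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          !seen[q[1], q[2]] && mask[q[1], q[2]]) {
        seen[q[1], q[2]] <- TRUE
        queue <- rbind(queue, q)
        out <- rbind(out, q)
      }
    }
  }
  unname(out)
}

#' Track the neuron through an image stack
#'
#' Frame by frame, finds the brightest pixel within `search_radius`
#' (Chebyshev) of the previous position and refines it to the
#' intensity-weighted centroid over a disc of radius 5 px. If the
#' candidate peak (3x3-smoothed) does not clear the local background
#' (mean + 3 SD of a ring around the search window) the frame is marked
#' `coasted` and the
#' previous position is held — robust to blinking or defocus without
#' drifting onto noise. Consecutive locked positions never move more
#' than `search_radius` apart.
#'
#' Track on the red (calcium-independent) channel when available: its
#' signal is stable through the stimulus.
#'
#' @param stack An [image_stack()].
#' @param start `(row, col)` starting position (e.g. from
#'   [locate_neuron()] on the first frame).
#' @param search_radius Maximum per-frame displacement, pixels;
#'   default 15 px at 10 Hz.
#' @param channel Label recorded in the output, `"red"` or `"green"`.
#' @return A `data.frame` of class `trajectory` with columns `frame`,
#'   `time_s`, `row`, `col`, `confidence` (`"locked"`/`"coasted"`).
#' @export
track_neuron <- function(stack, start, search_radius = 15,
                         channel = c("red", "green")) {
  channel <- match.arg(channel)
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf == 0) stop("empty stack")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  if (start[1] < 1 || start[1] > nr || start[2] < 1 || start[2] > nc) {
    stop("`start` is outside the frame")
  }
  pos <- matrix(NA_real_, nf, 2)
  conf <- character(nf)
  prev <- as.numeric(start)
  centroid_offsets <- disc_offsets(5)
  for (k in seq_len(nf)) {
    fr <- stack[, , k]
    r0 <- max(1L, as.integer(round(prev[1] - search_radius)))
    r1 <- min(nr, as.integer(round(prev[1] + search_radius)))
    c0 <- max(1L, as.integer(round(prev[2] - search_radius)))
    c1 <- min(nc, as.integer(round(prev[2] + search_radius)))
    win <- fr[r0:r1, c0:c1, drop = FALSE]
    pk <- peak_pixel(win)
    pk_abs0 <- pk + c(r0 - 1L, c0 - 1L)
    # candidate peak intensity: 3x3 mean around the peak pixel, so one
    # bright noise pixel cannot defeat the contrast test
    peak_val <- mean(fr[max(1, pk_abs0[1] - 1):min(nr, pk_abs0[1] + 1),
                        max(1, pk_abs0[2] - 1):min(nc, pk_abs0[2] + 1)])
    ring <- ring_values(fr, c(r0, r1, c0, c1))
    bg_mean <- mean(ring); bg_sd <- stats::sd(ring)
    if (!is.finite(bg_sd)) bg_sd <- 0
    if (peak_val < bg_mean + 3 * bg_sd) {
      pos[k, ] <- prev
      conf[k] <- "coasted"
      next
    }
    pk_abs <- pk + c(r0 - 1L, c0 - 1L)
    cand <- refine_centroid(fr, pk_abs, centroid_offsets, bg_mean)
    # keep the locked-jump contract: clip displacement to search_radius
    delta <- cand - prev
    dist <- sqrt(sum(delta^2))
    if (dist > search_radius) cand <- prev + delta * search_radius / dist
    cand[1] <- min(max(cand[1], 1), nr)
    cand[2] <- min(max(cand[2], 1), nc)
    pos[k, ] <- cand
    conf[k] <- "locked"
    prev <- cand
  }
  structure(
    data.frame(frame = seq_len(nf), time_s = frame_times(stack),
               row = pos[, 1], col = pos[, 2], confidence = conf,
               stringsAsFactors = FALSE),
    class = c("trajectory", "data.frame"),
    source_channel = channel)
}

# pixel offsets (row, col) of a disc of given radius around the origin
disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  as.matrix(g)
}

# values of a one-pixel ring just outside the given [r0,r1,c0,c1] box
ring_values <- function(frame, box) {
  nr <- nrow(frame); nc <- ncol(frame)
  r0 <- max(1L, box[1] - 1L); r1 <- min(nr, box[2] + 1L)
  c0 <- max(1L, box[3] - 1L); c1 <- min(nc, box[4] + 1L)
  vals <- c(frame[r0, c0:c1], frame[r1, c0:c1])
  if (r1 - r0 > 1) {
    vals <- c(vals, frame[(r0 + 1):(r1 - 1), c0],
              frame[(r0 + 1):(r1 - 1), c1])
  }
  vals
}

# background-floored intensity-weighted centroid over a disc around the peak
refine_centroid <- function(frame, peak, offsets, bg) {
  pts <- sweep(offsets, 2, as.integer(peak), "+")
  keep <- pts[, 1] >= 1 & pts[, 1] <= nrow(frame) &
    pts[, 2] >= 1 & pts[, 2] <= ncol(frame)
  pts <- pts[keep, , drop = FALSE]
  w <- pmax(frame[pts] - bg, 0)
  if (sum(w) <= 0) return(as.numeric(peak))
  c(sum(pts[, 1] * w), sum(pts[, 2] * w)) / sum(w)
}
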