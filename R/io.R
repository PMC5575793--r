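# Intensities are stored in TIFF files as 32-bit float samples scaled
# into [0, 1] by this factor; read/write round-trips exactly.
TIFF_SCALE <- 65536

#' Write an image stack as a multi-page TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_frames(stack)),
                  function(k) stack[, , k] / TIFF_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param frame_interval Seconds per frame of the recording.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, frame_interval = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- pg * TIFF_SCALE
  }
  image_stack(arr, frame_interval)
}

#' Write a split-frame two-channel stack
#'
#' Emulates a beamsplitter acquisition: each page holds the green
#' channel in the left half and the red channel in the right half of
#' one camera frame. The fixed channel offset (the column where the red
#' half starts) is recorded in the JSON sidecar written next to the
#' TIFF.
#'
#' @param green,red Aligned [image_stack()]s with identical dimensions.
#' @param path Output TIFF path; the sidecar is `path` + `".json"`.
#' @param metadata Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_split_stack <- function(green, red, path, metadata = list()) {
  stopifnot(identical(dim(green), dim(red)))
  d <- dim(green)
  combined <- array(0, c(d[1], 2 * d[2], d[3]))
  combined[, seq_len(d[2]), ] <- green
  combined[, d[2] + seq_len(d[2]), ] <- red
  write_stack(image_stack(combined, attr(green, "frame_interval")), path)
  side <- c(list(layout = "split_frame", green_half = "left",
                 red_half = "right", channel_col_offset = d[2],
                 frame_interval = attr(green, "frame_interval"),
                 intensity_scale = TIFF_SCALE),
            metadata)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split-frame stack back into two channels
#'
#' @param path TIFF path written by [write_split_stack()]; the sidecar
#'   `path` + `".json"` supplies the channel offset and frame interval.
#' @return List with `green` and `red` [image_stack()]s and the sidecar
#'   `metadata`.
#' @export
read_split_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  combined <- read_stack(path, frame_interval = side$frame_interval)
  off <- side$channel_col_offset
  list(green = image_stack(combined[, seq_len(off), , drop = FALSE],
                           side$frame_interval),
       red = image_stack(combined[, off + seq_len(dim(combined)[2] - off), ,
                                  drop = FALSE],
                         side$frame_interval),
       metadata = side)
}

#' Write a trajectory as CSV
#'
#' Columns: `frame`, `time_s`, `row`, `col`, `confidence`.
#'
#' @param traj A `trajectory` from [track_neuron()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV path written by [write_trajectory()].
#' @return A `trajectory` data.frame.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("trajectory", "data.frame"))
}

#' Write a calcium trace as CSV plus JSON metadata
#'
#' The CSV holds the per-frame series (`frame`, `time_s`, intensities,
#' `R_or_F`, `dRR` when normalized, `valid`); the sidecar JSON records
#' the mode, baseline and stimulus protocol.
#'
#' @param trace A `calcium_trace`.
#' @param path Output CSV path; metadata goes to `path` + `".json"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- cbind(data.frame(frame = trace$data$frame, time_s = trace$time),
              trace$data[setdiff(names(trace$data), "frame")])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(mode = trace$mode, baseline = trace$baseline,
               protocol = unclass(trace$protocol))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calcium trace CSV written by [write_trace()]
#'
#' @param path CSV path; expects the JSON sidecar next to it.
#' @return A `calcium_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- do.call(stim_protocol, meta$protocol[
    c("onsets", "durations", "pressures", "baseline_window",
      "record_duration")])
  tr <- new_calcium_trace(df$time_s, meta$mode, proto,
                          df[setdiff(names(df), "time_s")])
  if (!is.null(meta$baseline) && !is.na(meta$baseline)) {
    tr$baseline <- meta$baseline
  }
  tr
}

#' Write scene ground truth as CSV
#'
#' Columns: `frame`, `time_s`, `row`, `col`, `true_dRR`.
#'
#' @param ground_truth The `ground_truth` element of [render_scene()].
#' @param frame_interval Seconds per frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, frame_interval, path) {
  n <- length(ground_truth$true_trace)
  utils::write.csv(
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) * frame_interval,
               row = ground_truth$true_path[, 1],
               col = ground_truth$true_path[, 2],
               true_dRR = ground_truth$true_trace),
    path, row.names = FALSE)
  invisible(path)
}
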