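#' Time-lapse frame stack
#'
#' Container for an ordered sequence of single-channel 2-D intensity frames
#' with acquisition metadata, the unit of morphodynamics analysis. Frames
#' are stored as an `H x W x T` numeric array; `frames[, , t]` is the image
#' at time point `t`. When the acquisition used a z-stack per time point,
#' `z_slices_per_timepoint` and `medial_index` record which medial slice
#' the frames were taken from (see [select_medial_slice()]).
#'
#' @param frames numeric array `H x W x T`, nonnegative intensities, `T >= 2`.
#' @param frame_interval_s time between frames in seconds (default 10, the
#'   cadence used for vacuole imaging).
#' @param z_slices_per_timepoint 1, 3 or 5.
#' @param medial_index 1-based index of the slice the frames came from.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval_s = 10,
                        z_slices_per_timepoint = 1L,
                        medial_index = medial_slice_index(z_slices_per_timepoint)) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  if (dim(frames)[3] < 2L) stop("a frame stack needs at least 2 frames")
  if (dim(frames)[1] < 1L || dim(frames)[2] < 1L)
    stop("frame dimensions must be positive")
  if (any(frames < 0)) stop("intensities must be nonnegative")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be positive")
  if (!z_slices_per_timepoint %in% c(1L, 3L, 5L))
    stop("`z_slices_per_timepoint` must be 1, 3 or 5")
  if (medial_index < 1L || medial_index > z_slices_per_timepoint)
    stop("`medial_index` out of range")
  structure(list(frames = frames,
                 frame_interval_s = frame_interval_s,
                 z_slices_per_timepoint = as.integer(z_slices_per_timepoint),
                 medial_index = as.integer(medial_index)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px, %.3g s interval (%.1f min)\n",
              d[3], d[1], d[2], x$frame_interval_s,
              (d[3] - 1) * x$frame_interval_s / 60))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Acquisition times of a stack
#' @param stack a [frame_stack()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s
}

#' Read / write a frame stack as multi-page TIFF
#'
#' @param stack a [frame_stack()].
#' @param path TIFF file path.
#' @param bits bits per sample (8 or 16).
#' @param frame_interval_s cadence to attach on read (TIFF carries none).
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns a [frame_stack()].
#' @export
write_frame_stack <- function(stack, path, bits = 8L) {
  stopifnot(inherits(stack, "frame_stack"))
  write_tiff_stack(stack$frames, path, bits = bits)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, frame_interval_s = 10) {
  frame_stack(read_tiff_stack(path), frame_interval_s = frame_interval_s)
}
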