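#' Medial slice index for a z-stack
#'
#' Imaging acquires 1, 3 or 5 z-slices per time point; analysis uses the
#' medial slice: the second of three or the third of five (1-based).
#'
#' @param n_slices 1, 3 or 5.
#' @return 1-based index of the medial slice.
#' @export
medial_slice_index <- function(n_slices) {
  n_slices <- as.integer(n_slices)
  if (!n_slices %in% c(1L, 3L, 5L))
    stop("slice count must be 1, 3 or 5, got ", n_slices)
  c(`1` = 1L, `3` = 2L, `5` = 3L)[[as.character(n_slices)]]
}

#' Select the medial z-slice
#'
#' @param zstack numeric array `H x W x Z` (one time point) or
#'   `H x W x Z x T` (a whole acquisition); `Z` must be 1, 3 or 5. A 2-D
#'   matrix is treated as a single slice and returned unchanged.
#' @return `H x W` matrix, or `H x W x T` array for 4-D input.
#' @export
select_medial_slice <- function(zstack) {
  d <- dim(zstack)
  if (is.null(d) || length(d) == 2L) return(zstack)
  if (length(d) == 3L) {
    k <- medial_slice_index(d[3])
    return(zstack[, , k, drop = TRUE])
  }
  if (length(d) == 4L) {
    k <- medial_slice_index(d[3])
    return(zstack[, , k, , drop = FALSE][, , 1, ])
  }
  stop("`zstack` must have 2, 3 or 4 dimensions")
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood, the standard
#' salt-and-pepper noise removal step applied before frame correlation.
#' Borders are handled by reflection padding.
#'
#' @param frame numeric matrix, at least 3x3.
#' @return filtered matrix of the same size.
#' @export
median_filter3 <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 3 || ncol(frame) < 3)
    stop("`frame` must be a matrix of at least 3 x 3")
  .median_filter3_cpp(frame)
}

#' Percentile-capped intensity normalization
#'
#' Rescales a frame so that the p-th intensity percentile (and everything
#' above it) maps to the dynamic-range maximum and the frame minimum maps
#' to 0, i.e. a histogram adjustment where the 97th percentile becomes the
#' display maximum. The mapping is affine below the percentile and clipped
#' above it, hence monotone non-decreasing. Output is floating point in
#' `[0, max_out]`.
#'
#' @param frame numeric matrix.
#' @param p percentile in (0, 100); default 97.
#' @param max_out output maximum; default 1.
#' @return normalized matrix; a constant (zero-variance) input returns all
#'   zeros with attribute `degenerate = TRUE`.
#' @export
normalize_percentile <- function(frame, p = 97, max_out = 1) {
  if (!is.numeric(p) || p <= 0 || p >= 100) stop("`p` must be in (0, 100)")
  lo <- min(frame)
  hi <- stats::quantile(frame, p / 100, names = FALSE)
  if (hi <= lo) {
    out <- array(0, dim(frame))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (frame - lo) / (hi - lo) * max_out
  out[out > max_out] <- max_out
  out
}

#' Normalized correlation coefficient between two frames
#'
#' Pearson correlation of pixel intensities,
#' \deqn{\mathrm{NCC}(A,B) = \frac{\sum_{x,y}(A-\bar A)(B-\bar B)}
#'   {\sqrt{\sum_{x,y}(A-\bar A)^2 \sum_{x,y}(B-\bar B)^2}},}
#' used as a frame-similarity measure: values near 1 mean the morphology is
#' unchanged relative to the reference frame. Symmetric in its arguments
#' and invariant to positive affine intensity transforms.
#'
#' @param A,B numeric matrices of identical dimensions.
#' @param mask optional logical matrix restricting the sum to a region
#'   (e.g. the papilla cell); `NULL` uses all pixels.
#' @return correlation in `[-1, 1]`, or `NA` with attribute
#'   `degenerate = TRUE` if either frame has zero intensity variance.
#' @export
ncc <- function(A, B, mask = NULL) {
  if (!identical(dim(A), dim(B))) stop("`A` and `B` must have the same shape")
  a <- as.numeric(A); b <- as.numeric(B)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(A))) stop("`mask` shape mismatch")
    keep <- as.logical(mask)
    a <- a[keep]; b <- b[keep]
  }
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va <= 0 || vb <= 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sum(a * b) / sqrt(va * vb)
}

#' Preprocess a frame stack for correlation analysis
#'
#' Applies, per frame and in this order, the 3x3 median filter and the
#' percentile-capped normalization. (Medial-slice selection, when needed,
#' happens before the stack is built; see [select_medial_slice()].) With
#' `per_frame = FALSE` the percentile and minimum are computed once from
#' the whole sequence and applied to every frame.
#'
#' @param stack a [frame_stack()].
#' @param p percentile for [normalize_percentile()].
#' @param per_frame logical; normalize each frame by its own histogram
#'   (default) or by the pooled sequence histogram.
#' @return a [frame_stack()] with floating-point frames in `[0, 1]`.
#' @export
preprocess_stack <- function(stack, p = 97, per_frame = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  for (t in seq_len(dim(fr)[3])) fr[, , t] <- median_filter3(fr[, , t])
  if (per_frame) {
    for (t in seq_len(dim(fr)[3])) fr[, , t] <- normalize_percentile(fr[, , t], p = p)
  } else {
    lo <- min(fr)
    hi <- stats::quantile(fr, p / 100, names = FALSE)
    if (hi > lo) {
      fr <- pmin((fr - lo) / (hi - lo), 1)
    } else {
      fr[] <- 0
    }
  }
  out <- stack
  out$frames <- fr
  out
}

#' NCC time series of a frame stack
#'
#' Computes the normalized correlation coefficient between the first frame
#' and the frame at each time point, quantifying how far the morphology has
#' drifted from its state at the start of imaging. The stack is expected to
#' be preprocessed (see [preprocess_stack()]); set `preprocess = TRUE` to
#' run the standard chain here.
#'
#' @param stack a [frame_stack()].
#' @param cell_id,condition labels stored in the output.
#' @param mask optional logical matrix passed to [ncc()].
#' @param preprocess run [preprocess_stack()] first (default `FALSE`).
#' @param p percentile used when `preprocess = TRUE`.
#' @return data frame with columns `cell_id`, `condition`, `time_s`, `ncc`;
#'   `ncc[1]` is 1 by construction; degenerate frames give `NA` entries.
#' @export
ncc_series <- function(stack, cell_id = "cell1", condition = "unspecified",
                       mask = NULL, preprocess = FALSE, p = 97) {
  stopifnot(inherits(stack, "frame_stack"))
  if (preprocess) stack <- preprocess_stack(stack, p = p)
  TT <- n_frames(stack)
  ref <- stack$frames[, , 1]
  vals <- vapply(seq_len(TT), function(t) {
    as.numeric(ncc(ref, stack$frames[, , t], mask = mask))
  }, numeric(1))
  data.frame(cell_id = cell_id, condition = condition,
             time_s = frame_times(stack), ncc = vals,
             stringsAsFactors = FALSE)
}
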