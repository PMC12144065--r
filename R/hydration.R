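#' Pollen width by moment-based ellipse fit
#'
#' Fits the ellipse with the same normalized second central moments as the
#' mask (the "fit ellipse" approach of ImageJ/Fiji) and returns the length
#' of its minor axis, the standard width measure for a hydrating pollen
#' grain. For a pixel set with central covariance eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2}, the axes are \eqn{4\sqrt{\lambda_1}} and
#' \eqn{4\sqrt{\lambda_2}}.
#'
#' @param mask logical (or 0/1) matrix; must be nonempty and a single
#'   4-connected component.
#' @param pixel_size_um physical pixel size.
#' @return minor-axis length in micrometres; attribute `major_um` carries
#'   the major axis.
#' @export
fit_ellipse_minor_axis <- function(mask, pixel_size_um = 1) {
  mask <- mask > 0
  if (!any(mask)) stop("`mask` is empty")
  lab <- .label4_cpp(mask)
  if (attr(lab, "n") > 1L)
    stop("`mask` has multiple connected components; segment first ",
         "(see segment_largest_component())")
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  # add the 1/12 variance of a unit pixel so single-pixel-wide shapes have
  # nonzero extent (same convention as moment-based ellipse fitting in
  # image-analysis toolkits)
  cyy <- stats::var(y) * (length(y) - 1) / length(y) + 1 / 12
  cxx <- stats::var(x) * (length(x) - 1) / length(x) + 1 / 12
  cxy <- stats::cov(x, y) * (length(y) - 1) / length(y)
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  minor <- 4 * sqrt(max(l2, 0)) * pixel_size_um
  structure(minor, major_um = 4 * sqrt(max(l1, 0)) * pixel_size_um)
}

#' Keep the largest connected component of a binary frame
#'
#' Thresholds a grayscale frame (Otsu) if needed and keeps the largest
#' 4-connected foreground component, the standard segmentation step before
#' ellipse fitting on rendered or brightfield-like pollen images.
#'
#' @param frame numeric matrix (grayscale) or logical mask.
#' @return logical matrix with a single component.
#' @export
segment_largest_component <- function(frame) {
  mask <- if (is.logical(frame)) frame else frame > otsu_threshold(as.numeric(frame))
  if (!any(mask)) stop("nothing above threshold to segment")
  lab <- .label4_cpp(mask)
  if (attr(lab, "n") > 1L) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  mask
}

#' Pollen hydration rate
#'
#' Percentage change in pollen width relative to the width at pollination:
#' `(Lt - L0) / L0 * 100`.
#'
#' @param L0 width at t = 0 (micrometres, > 0).
#' @param Lt width at the evaluation time.
#' @return hydration rate in percent (negative if the grain shrank).
#' @export
hydration_rate <- function(L0, Lt) {
  if (any(L0 <= 0)) stop("`L0` must be positive")
  (Lt - L0) / L0 * 100
}

#' Hydration rates of a pollen track at requested times
#'
#' Computes the hydration rate against the width at t = 0 for each
#' requested time point (default 5, 10 and 15 min after pollination),
#' matching each request to the nearest recorded sample within `tol`
#' minutes.
#'
#' @param track data frame with columns `pollen_id`, `condition`,
#'   `time_min` (starting at 0) and `width_um` (all positive).
#' @param time_points requested times in minutes.
#' @param tol matching tolerance in minutes (default 0.5, half the usual
#'   1-min acquisition interval).
#' @return data frame with `pollen_id`, `condition`, `time_min`,
#'   `rate_percent`.
#' @export
hydration_timecourse <- function(track, time_points = c(5, 10, 15), tol = 0.5) {
  need <- c("pollen_id", "condition", "time_min", "width_um")
  if (!all(need %in% names(track))) stop("`track` needs columns ",
                                         paste(need, collapse = ", "))
  if (any(track$width_um <= 0)) stop("widths must be positive")
  do.call(rbind, lapply(split(track, track$pollen_id), function(tr) {
    tr <- tr[order(tr$time_min), , drop = FALSE]
    if (abs(tr$time_min[1]) > 1e-9) stop("track must include t = 0 (L0)")
    L0 <- tr$width_um[1]
    rates <- vapply(time_points, function(tp) {
      j <- which.min(abs(tr$time_min - tp))
      if (abs(tr$time_min[j] - tp) > tol)
        stop("requested time ", tp, " min not within ", tol,
             " min of any sample for pollen ", tr$pollen_id[1])
      hydration_rate(L0, tr$width_um[j])
    }, numeric(1))
    data.frame(pollen_id = tr$pollen_id[1], condition = tr$condition[1],
               time_min = time_points, rate_percent = rates,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Measure a pollen track from rendered frames
#'
#' Segments each frame ([segment_largest_component()]) and measures the
#' ellipse-fit minor axis, producing a width track ready for
#' [hydration_timecourse()].
#'
#' @param frames `H x W x T` array of grayscale frames.
#' @param times_min acquisition times in minutes (length `T`).
#' @param pixel_size_um physical pixel size.
#' @param pollen_id,condition labels.
#' @return pollen track data frame.
#' @export
measure_pollen_frames <- function(frames, times_min, pixel_size_um = 0.5,
                                  pollen_id = "pollen1", condition = "mock") {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == length(times_min))
  widths <- vapply(seq_along(times_min), function(k) {
    m <- segment_largest_component(frames[, , k])
    as.numeric(fit_ellipse_minor_axis(m, pixel_size_um))
  }, numeric(1))
  data.frame(pollen_id = pollen_id, condition = condition,
             time_min = times_min, width_um = widths,
             stringsAsFactors = FALSE)
}
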