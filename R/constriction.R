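#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance-maximizing threshold on a 256-bin
#' histogram, used to separate bright membrane signal from cytoplasmic
#' background inside the cell mask.
#'
#' @param x numeric vector of intensities.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(as.integer((x - lo) / (hi - lo) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_tot <- mu[n_bins]
  sigma_b <- (mu_tot * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + k / n_bins * (hi - lo)
}

#' Detect vacuole constriction events in a movie
#'
#' Automates the manual counting rule for vacuole constriction: an event is
#' the appearance of a new vacuole border completely across the papilla
#' cell. Per frame, pixels above an Otsu threshold (computed on masked
#' intensities of that frame) are scanned row-wise; a candidate border is a
#' run of rows in which the bright pixels span at least `span_frac` of the
#' local cell width. An event is recorded when a candidate appears at an
#' axial position (within `merge_dist` px) where no candidate existed in
#' the previous `persistence` frames. Candidates in the first
#' `persistence` frames are treated as baseline structure, not events.
#' A border that disappears and reappears at the same site after the
#' persistence window is counted again and flagged (`reappearance`).
#'
#' @param stack a preprocessed [frame_stack()] (see [preprocess_stack()]).
#' @param cell_mask logical matrix marking the cell.
#' @param span_frac minimum fraction of the local cell width a border must
#'   span (default 0.9). Raising it can only remove candidates.
#' @param persistence frames a site must have been border-free before an
#'   appearance counts (default 2).
#' @param merge_dist axial tolerance in px for matching candidates across
#'   frames (default 5).
#' @param threshold fixed intensity threshold; `NULL` (default) uses the
#'   per-frame Otsu threshold on masked pixels.
#' @param window_s counting window in seconds (default 600, the 10-min
#'   observation window); only events with onset inside it are counted.
#' @param cell_id label for the result.
#' @return object of class `constriction_result`: list with `cell_id`,
#'   `window_s`, `count`, and `detections` (data frame `time_s`, `kind`,
#'   `position`, `frame`, `row`, `reappearance`).
#' @export
detect_constrictions <- function(stack, cell_mask, span_frac = 0.9,
                                 persistence = 2L, merge_dist = 5,
                                 threshold = NULL, window_s = 600,
                                 cell_id = "cell1") {
  stopifnot(inherits(stack, "frame_stack"))
  if (!identical(dim(cell_mask), dim(stack$frames)[1:2]))
    stop("`cell_mask` shape does not match the stack")
  if (!any(cell_mask)) stop("`cell_mask` is empty")
  TT <- n_frames(stack)
  H <- dim(stack$frames)[1]
  row_width <- rowSums(cell_mask)
  scan_rows <- which(row_width >= 3)

  # candidate border centroids (axial px) per frame
  candidates <- vector("list", TT)
  for (t in seq_len(TT)) {
    fr <- stack$frames[, , t]
    thr <- if (is.null(threshold)) otsu_threshold(fr[cell_mask]) else threshold
    bright <- fr > thr & cell_mask
    frac <- rowSums(bright)[scan_rows] / row_width[scan_rows]
    hit <- frac >= span_frac
    if (!any(hit)) { candidates[[t]] <- numeric(0); next }
    # merge contiguous runs of hit rows into one candidate each
    hit_rows <- scan_rows[hit]
    breaks <- c(0, which(diff(hit_rows) > 1), length(hit_rows))
    candidates[[t]] <- vapply(seq_len(length(breaks) - 1), function(k) {
      mean(hit_rows[(breaks[k] + 1):breaks[k + 1]])
    }, numeric(1))
  }

  det <- data.frame(time_s = numeric(0), kind = character(0),
                    position = numeric(0), frame = integer(0),
                    row = numeric(0), reappearance = logical(0),
                    stringsAsFactors = FALSE)
  seen_sites <- numeric(0)   # rows where an event was already recorded
  for (t in seq.int(persistence + 1L, TT)) {
    prev <- unlist(candidates[seq.int(t - persistence, t - 1L)])
    for (y in candidates[[t]]) {
      if (length(prev) && any(abs(prev - y) <= merge_dist)) next
      reap <- length(seen_sites) > 0 && any(abs(seen_sites - y) <= merge_dist)
      det <- rbind(det, data.frame(
        time_s = (t - 1) * stack$frame_interval_s, kind = "constriction",
        position = y / H, frame = t, row = y, reappearance = reap,
        stringsAsFactors = FALSE))
      seen_sites <- c(seen_sites, y)
    }
  }
  count <- sum(det$time_s <= window_s)
  structure(list(cell_id = cell_id, window_s = window_s,
                 count = as.integer(count), detections = det),
            class = "constriction_result")
}

#' @export
print.constriction_result <- function(x, ...) {
  cat(sprintf("constriction_result '%s': %d events in %g s window (%d detections total)\n",
              x$cell_id, x$count, x$window_s, nrow(x$detections)))
  invisible(x)
}

#' Summarize constriction counts per condition
#'
#' @param counts data frame with columns `condition` and `count` (one row
#'   per cell), e.g. assembled from [detect_constrictions()] results or
#'   read from a manual-count CSV.
#' @return data frame with per-condition `mean`, `sem` (sd / sqrt(n), 0
#'   for n = 1) and `n`.
#' @export
compare_counts <- function(counts) {
  if (!all(c("condition", "count") %in% names(counts)))
    stop("`counts` needs columns `condition` and `count`")
  if (!nrow(counts)) stop("`counts` is empty")
  out <- do.call(rbind, lapply(split(counts$count, counts$condition), function(v) {
    data.frame(mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))
  }))
  out <- cbind(condition = rownames(out), out)
  rownames(out) <- NULL
  out
}
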