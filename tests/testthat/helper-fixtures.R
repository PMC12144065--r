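# shared fixtures, all generated in code

# a seeded random intensity frame
random_frame <- function(h = 8, w = 8, seed = 1, maxval = 255) {
  set.seed(seed)
  matrix(runif(h * w, 0, maxval), h, w)
}

# brute-force scalar implementation of the normalized correlation
# coefficient, straight from its definition (the oracle for ncc())
ncc_bruteforce <- function(A, B) {
  ma <- mean(A); mb <- mean(B)
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    num <- num + (A[i, j] - ma) * (B[i, j] - mb)
    da <- da + (A[i, j] - ma)^2
    db <- db + (B[i, j] - mb)^2
  }
  num / sqrt(da * db)
}

# exhaustive per-frame scan for full-width transverse borders; independent
# of detect_constrictions() internals. Returns onset (frame, row) pairs of
# newly appearing borders, using the same counting rule as the field protocol:
# a border spanning (almost) the whole local cell width that was absent
# in the preceding `persist` frames.
scan_borders_bruteforce <- function(frames, mask, thr = 120, span = 0.9,
                                    persist = 2, merge_px = 5) {
  TT <- dim(frames)[3]
  cand <- vector("list", TT)
  rw <- rowSums(mask)
  rows <- which(rw >= 3)
  for (t in seq_len(TT)) {
    hit <- sapply(rows, function(y) {
      sum(frames[y, , t] > thr & mask[y, ]) / rw[y] >= span
    })
    hr <- rows[hit]
    if (!length(hr)) { cand[[t]] <- numeric(0); next }
    runs <- split(hr, cumsum(c(1, diff(hr) > 1)))
    cand[[t]] <- vapply(runs, mean, numeric(1))
  }
  events <- NULL
  for (t in seq.int(persist + 1, TT)) {
    prev <- unlist(cand[seq.int(t - persist, t - 1)])
    for (y in cand[[t]]) {
      if (length(prev) && any(abs(prev - y) <= merge_px)) next
      events <- rbind(events, c(frame = t, row = y))
    }
  }
  events
}

# greedy matching of detections to ground-truth events
match_events <- function(detections, truth, row_tol = 6, frame_tol = 1) {
  used <- rep(FALSE, nrow(detections))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    ok <- which(!used &
                  abs(detections$row - truth$row[i]) <= row_tol &
                  abs(detections$frame - truth$frame[i]) <= frame_tol)
    if (length(ok)) { used[ok[1]] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}
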