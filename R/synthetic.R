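# Synthetic tonoplast time-lapse generator.
#
# Emulates what a medial confocal slice of a stigma papilla cell looks
# like: an elongated (capsule-shaped) cell whose large central vacuole is
# outlined by a bright tonoplast membrane, small satellite/tubular vacuoles
# near the apex that jiggle and occasionally fuse into the central vacuole,
# and constriction events in which a new bright border appears completely
# across the cell for a few frames. Every event is logged, so detector
# performance can be scored against exact ground truth.

#' Scenario describing a synthetic vacuole movie
#'
#' @param name condition label.
#' @param constriction_rate expected constriction events per 10 min.
#' @param fusion_rate expected fusion events per 10 min.
#' @param satellite_vacuole_count number of small vacuoles near the apex.
#' @param invagination render static tonoplast invagination rings
#'   (wortmannin-like morphology: abnormal but frozen structure).
#' @param noise_sd Gaussian read-noise SD in intensity units; 0 disables
#'   all noise (including shot noise) so renders are fully deterministic
#'   pixel geometry.
#' @param frame_count number of time points (>= 2); default 60, a 10-min
#'   movie at 10-s cadence.
#' @param frame_interval_s frame cadence in seconds.
#' @param seed RNG seed; identical scenarios with identical seeds give
#'   bit-identical output.
#' @param width_px,height_px frame size in pixels (transverse x axial).
#' @return an object of class `scenario`.
#' @export
scenario <- function(name = "custom", constriction_rate = 8, fusion_rate = 3,
                     satellite_vacuole_count = 4L, invagination = FALSE,
                     noise_sd = 6, frame_count = 60L, frame_interval_s = 10,
                     seed = 1L, width_px = 30L, height_px = 120L) {
  if (frame_count < 2) stop("`frame_count` must be at least 2")
  if (constriction_rate < 0 || fusion_rate < 0) stop("rates must be nonnegative")
  if (frame_interval_s <= 0) stop("`frame_interval_s` must be positive")
  if (satellite_vacuole_count < 0) stop("`satellite_vacuole_count` must be >= 0")
  if (width_px < 12 || height_px < 40)
    stop("frame dimensions too small to render a papilla cell")
  structure(list(name = name,
                 constriction_rate = constriction_rate,
                 fusion_rate = fusion_rate,
                 satellite_vacuole_count = as.integer(satellite_vacuole_count),
                 invagination = isTRUE(invagination),
                 noise_sd = noise_sd,
                 frame_count = as.integer(frame_count),
                 frame_interval_s = frame_interval_s,
                 seed = as.integer(seed),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("scenario '%s': %g constrictions / 10 min, %g fusions / 10 min,\n",
                     "  %d satellite vacuoles, invagination %s, noise sd %g,\n",
                     "  %d frames @ %g s (%d x %d px), seed %d\n"),
              x$name, x$constriction_rate, x$fusion_rate,
              x$satellite_vacuole_count, x$invagination, x$noise_sd,
              x$frame_count, x$frame_interval_s, x$width_px, x$height_px,
              x$seed))
  invisible(x)
}

# wortmannin dose-response helpers: smooth saturating suppression with
# half-effect around 33 uM, matching a concentration-dependent inhibition
# that is mild at 1 uM and strong at 100-500 uM.
.wm_constriction_rate <- function(dose_um) 8 - 6.5 * dose_um / (dose_um + 33)
.wm_fusion_rate <- function(dose_um) 3 - 2.2 * dose_um / (dose_um + 33)
.wm_satellites <- function(dose_um) max(1L, as.integer(round(4 - 3 * dose_um / (dose_um + 33))))

#' Preset scenarios for the studied conditions
#'
#' Parameter bundles encoding the qualitative behaviour of each condition:
#' untreated unpollinated cells constrict and fuse repeatedly; pollination
#' strongly reduces constriction; mock treatment behaves like untreated;
#' E-64d increases constriction frequency (stacked tubular vacuoles); PDMP
#' and high-dose wortmannin reduce it; wortmannin acts dose-dependently and
#' adds tonoplast invagination at 10 uM and above. Rates are free choices
#' that reproduce the orderings between conditions, not published values.
#'
#' @param name one of `"unpollinated"`, `"pollinated"`, `"mock"`, `"e64d"`,
#'   `"pdmp"`, `"wortmannin"`, `"rop2_unpollinated"`, `"rop2_pollinated"`.
#' @param dose_um wortmannin dose in micromolar (0-500); ignored for other
#'   presets. Dose 0 equals the mock preset.
#' @param seed,frame_count,frame_interval_s,noise_sd overrides passed to
#'   [scenario()].
#' @return a [scenario()].
#' @export
scenario_presets <- function(name, dose_um = 500, seed = 1L,
                             frame_count = 60L, frame_interval_s = 10,
                             noise_sd = 6) {
  base <- function(...) scenario(..., seed = seed, frame_count = frame_count,
                                 frame_interval_s = frame_interval_s,
                                 noise_sd = noise_sd)
  switch(name,
    unpollinated = base(name = "unpollinated", constriction_rate = 8,
                        fusion_rate = 3, satellite_vacuole_count = 4L),
    mock = base(name = "mock", constriction_rate = 8, fusion_rate = 3,
                satellite_vacuole_count = 4L),
    pollinated = base(name = "pollinated", constriction_rate = 1.5,
                      fusion_rate = 1, satellite_vacuole_count = 1L),
    e64d = base(name = "e64d", constriction_rate = 14, fusion_rate = 0.5,
                satellite_vacuole_count = 6L),
    pdmp = base(name = "pdmp", constriction_rate = 2, fusion_rate = 3,
                satellite_vacuole_count = 1L),
    wortmannin = {
      if (dose_um < 0) stop("`dose_um` must be nonnegative")
      if (dose_um == 0) {
        s <- base(name = "mock", constriction_rate = 8, fusion_rate = 3,
                  satellite_vacuole_count = 4L)
      } else {
        s <- base(name = sprintf("wortmannin_%g", dose_um),
                  constriction_rate = .wm_constriction_rate(dose_um),
                  fusion_rate = .wm_fusion_rate(dose_um),
                  satellite_vacuole_count = .wm_satellites(dose_um),
                  invagination = dose_um >= 10)
      }
      s
    },
    rop2_unpollinated = base(name = "rop2_unpollinated", constriction_rate = 4,
                             fusion_rate = 2, satellite_vacuole_count = 2L),
    rop2_pollinated = base(name = "rop2_pollinated", constriction_rate = 0.8,
                           fusion_rate = 0.8, satellite_vacuole_count = 1L),
    stop("unknown preset: ", name)
  )
}

# --- geometry helpers -------------------------------------------------------

.shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- seq_len(H); xs <- seq_len(W)
  ysrc <- ys - dy; xsrc <- xs - dx
  oky <- ysrc >= 1 & ysrc <= H; okx <- xsrc >= 1 & xsrc <= W
  out[ys[oky], xs[okx]] <- m[ysrc[oky], xsrc[okx]]
  out
}

.erode_box <- function(m, r) {
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- out & .shift_mat(m, dy, dx)
  }
  out
}

#' Capsule-shaped papilla cell mask
#'
#' Elongated cell rendered as a rectangle capped by a hemisphere at the tip
#' (image top). Used both by the generator and as the analysis mask.
#'
#' @param height_px,width_px frame size.
#' @return logical matrix, `TRUE` inside the cell.
#' @export
papilla_cell_mask <- function(height_px = 120L, width_px = 30L) {
  H <- height_px; W <- width_px
  cx <- (W + 1) / 2
  R <- (W - 2) / 2
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  (row > R + 1 & abs(col - cx) <= R) |
    (row <= R + 1 & (col - cx)^2 + (row - (R + 1))^2 <= R^2)
}

.ring_pixels <- function(H, W, cy, cx, r, width = 1.2) {
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((row - cy)^2 + (col - cx)^2)
  d >= r - 0.5 & d <= r + width - 0.5
}

# --- the generator ----------------------------------------------------------

#' Simulate a tonoplast time-lapse movie with ground-truth events
#'
#' Renders a synthetic medial-slice movie of a papilla cell: static bright
#' contour of the central vacuole, mobile satellite vacuoles near the apex,
#' constriction events drawn as a new bright border spanning the full
#' transverse width of the cell for at least 2 consecutive frames, and
#' fusion events in which a satellite vacuole disappears into the central
#' vacuole. Poisson shot noise and Gaussian read noise are added after
#' geometry rendering (disabled entirely when `noise_sd = 0`). Identical
#' scenarios and seeds give bit-identical output.
#'
#' Event counts are drawn as `qpois(u, rate * minutes / 10)` with a shared
#' uniform draw position in the RNG stream, so that for a fixed seed a
#' scenario with a higher rate never yields fewer events.
#'
#' @param scn a [scenario()].
#' @return list with components `stack` (a [frame_stack()]), `events`
#'   (data frame: `time_s`, `kind`, `position` as axial fraction, `frame`,
#'   `duration_frames`, `row`), `cell_mask`, and `scenario`.
#' @export
simulate_vacuole_sequence <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed)
  H <- scn$height_px; W <- scn$width_px; TT <- scn$frame_count
  duration_min <- (TT - 1) * scn$frame_interval_s / 60
  cx <- (W + 1) / 2; R <- (W - 2) / 2

  mask <- papilla_cell_mask(H, W)
  inner <- .erode_box(mask, 3L)
  membrane <- inner & !.erode_box(inner, 2L)   # 2-px tonoplast contour

  # event counts: comonotone across rates under a fixed seed
  u_con <- stats::runif(1); u_fus <- stats::runif(1)
  n_con <- stats::qpois(u_con, scn$constriction_rate * duration_min / 10)
  n_fus <- stats::qpois(u_fus, scn$fusion_rate * duration_min / 10)

  # schedule constrictions: full-width transverse borders, 2 rows thick.
  # Events closer than 14 px axially must not be active (or recently
  # active) at the same time, so one rendered border never explains two
  # logged events and each onset is preceded by border-free frames.
  persist <- 2L
  con <- list()
  if (n_con > 0 && TT >= 6) {
    y_min <- as.integer(ceiling(R + 7)); y_max <- H - 4L
    for (i in seq_len(n_con)) {
      placed <- FALSE
      for (attempt in 1:200) {
        f0 <- sample(4:(TT - 1L), 1L)
        dur <- min(sample(2:6, 1L), TT - f0 + 1L)
        y0 <- sample(y_min:y_max, 1L)
        ok <- TRUE
        for (e in con) {
          if (abs(e$row - y0) < 14) {
            if (!(f0 > e$frame + e$dur + persist || e$frame > f0 + dur + persist)) {
              ok <- FALSE; break
            }
          }
        }
        if (ok) { con[[length(con) + 1L]] <- list(frame = f0, dur = dur, row = y0); placed <- TRUE; break }
      }
      if (!placed) next  # congested movie: drop the event (stays unlogged)
    }
  }

  # satellite vacuoles near the apex; step size scales with how active the
  # condition is, so a scenario with zero rates renders static geometry
  n_sat <- scn$satellite_vacuole_count
  step_sd <- 0.4 * sqrt(scn$constriction_rate + scn$fusion_rate)
  sat <- NULL
  if (n_sat > 0) {
    sat <- data.frame(
      cy = stats::runif(n_sat, R + 4, min(H * 0.45, H - 10)),
      cx = stats::runif(n_sat, cx - R + 4, cx + R - 4),
      r = stats::runif(n_sat, 2, 3.2),
      gone = rep(NA_integer_, n_sat)   # frame at which it fuses away
    )
  }

  # fusion events: a satellite disappears; if none remain, a transient
  # bright blob at the contour stands in for the fusing vesicle
  fus <- list()
  if (n_fus > 0 && TT >= 5) {
    avail <- if (n_sat > 0) seq_len(n_sat) else integer(0)
    for (i in seq_len(n_fus)) {
      f0 <- sample(3:TT, 1L)
      if (length(avail)) {
        k <- avail[sample.int(length(avail), 1L)]
        avail <- setdiff(avail, k)
        sat$gone[k] <- f0
        fus[[length(fus) + 1L]] <- list(frame = f0, row = sat$cy[k], sat = k)
      } else {
        fus[[length(fus) + 1L]] <- list(frame = f0,
                                        row = stats::runif(1, R + 4, H - 6),
                                        sat = NA_integer_)
      }
    }
  }

  # invagination: static tonoplast rings inside the vacuole -- the
  # hallmark wortmannin morphology. They are rendered as frozen structure:
  # the treated cell shows abnormal shapes but little frame-to-frame
  # change, which is exactly what raises its NCC relative to mock.
  inv <- NULL
  if (scn$invagination) {
    inv <- data.frame(cy = stats::runif(2, H * 0.35, H * 0.7),
                      cx = stats::runif(2, cx - 4, cx + 4),
                      r = c(4.5, 6))
  }

  bg_out <- 5; bg_in <- 30; amp_mem <- 185; amp_sat <- 160; amp_con <- 215

  # pre-draw satellite random-walk tracks (reflected into the cell)
  sat_tracks <- NULL
  if (n_sat > 0) {
    sat_tracks <- vector("list", n_sat)
    for (k in seq_len(n_sat)) {
      cy <- numeric(TT); cxk <- numeric(TT)
      cy[1] <- sat$cy[k]; cxk[1] <- sat$cx[k]
      for (t in 2:TT) {
        cy[t] <- cy[t - 1] + stats::rnorm(1, 0, step_sd)
        cxk[t] <- cxk[t - 1] + stats::rnorm(1, 0, step_sd)
        cy[t] <- min(max(cy[t], R + 3), H - 8)
        cxk[t] <- min(max(cxk[t], cx - R + 3), cx + R - 3)
      }
      sat_tracks[[k]] <- cbind(cy, cxk)
    }
  }

  base <- matrix(bg_out, H, W)
  base[mask] <- bg_in
  base[membrane] <- amp_mem

  frames <- array(0, dim = c(H, W, TT))
  for (t in seq_len(TT)) {
    fr <- base
    if (!is.null(inv)) {
      for (k in seq_len(nrow(inv))) {
        ring <- .ring_pixels(H, W, inv$cy[k], inv$cx[k], inv$r[k]) & inner
        fr[ring] <- amp_mem
      }
    }
    if (n_sat > 0) {
      for (k in seq_len(n_sat)) {
        if (!is.na(sat$gone[k]) && t >= sat$gone[k]) next
        p <- sat_tracks[[k]][t, ]
        ring <- .ring_pixels(H, W, p[1], p[2], sat$r[k]) & mask
        fr[ring] <- amp_sat
      }
    }
    for (e in fus) {
      if (is.na(e$sat) && t >= e$frame && t < e$frame + 2) {
        blob <- .ring_pixels(H, W, e$row, cx, 2, width = 2.5) & mask
        fr[blob] <- amp_sat
      }
    }
    for (e in con) {
      if (t >= e$frame && t < e$frame + e$dur) {
        rows <- e$row:(e$row + 1L)
        sel <- matrix(FALSE, H, W); sel[rows, ] <- TRUE
        fr[sel & mask] <- amp_con
      }
    }
    if (scn$noise_sd > 0) {
      fr <- stats::rpois(length(fr), lambda = fr) +
        stats::rnorm(length(fr), 0, scn$noise_sd)
      dim(fr) <- c(H, W)
    }
    frames[, , t] <- pmin(pmax(round(fr), 0), 255)
  }

  ev <- data.frame(time_s = numeric(0), kind = character(0),
                   position = numeric(0), frame = integer(0),
                   duration_frames = integer(0), row = numeric(0),
                   stringsAsFactors = FALSE)
  for (e in con) {
    ev <- rbind(ev, data.frame(time_s = (e$frame - 1) * scn$frame_interval_s,
                               kind = "constriction", position = e$row / H,
                               frame = e$frame, duration_frames = e$dur,
                               row = e$row, stringsAsFactors = FALSE))
  }
  for (e in fus) {
    ev <- rbind(ev, data.frame(time_s = (e$frame - 1) * scn$frame_interval_s,
                               kind = "fusion", position = e$row / H,
                               frame = e$frame, duration_frames = NA_integer_,
                               row = e$row, stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$time_s, ev$row), , drop = FALSE]
  rownames(ev) <- NULL

  list(stack = frame_stack(frames, frame_interval_s = scn$frame_interval_s),
       events = ev, cell_mask = mask, scenario = scn)
}

#' Write / read an event log as CSV
#' @param events event data frame from [simulate_vacuole_sequence()] or
#'   [detect_constrictions()].
#' @param path CSV path.
#' @return the path (write) or the event data frame (read).
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
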