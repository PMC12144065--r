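#' Simulate a pollen hydration assay
#'
#' Generates a pollen-width trajectory following saturating hydration
#' kinetics
#' \deqn{L_t = L_0 \left(1 + \frac{r_\infty}{100}(1 - e^{-t/\tau})\right) + \epsilon_t,}
#' where `r_inf` (`plateau_rate`) is the asymptotic hydration rate in
#' percent and `tau` the hydration time constant in minutes. Widths are
#' sampled on the 0-inclusive acquisition grid `t = 0, interval, ...,
#' duration` (1-min cadence for 15 min by default, i.e. 16 samples).
#' Optionally renders each time point as a filled-ellipse mask frame whose
#' minor axis is `L_t`, for exercising segmentation and ellipse fitting.
#'
#' @param L0 initial pollen width in micrometres (> 0).
#' @param plateau_rate asymptotic hydration rate in percent.
#' @param tau hydration time constant in minutes.
#' @param interval acquisition interval in minutes.
#' @param duration total duration in minutes (>= interval).
#' @param noise_sd measurement noise SD in micrometres.
#' @param seed RNG seed.
#' @param pollen_id,condition labels stored in the track.
#' @param render if `TRUE`, also return rendered mask frames.
#' @param pixel_size_um pixel size for rendering.
#' @return list with `track` (data frame: `pollen_id`, `condition`,
#'   `time_min`, `width_um`) and, if `render`, `frames` (`H x W x T`
#'   array of 0/255 masks) and `pixel_size_um`.
#' @export
simulate_pollen_assay <- function(L0 = 20, plateau_rate = 40, tau = 4,
                                  interval = 1, duration = 15, noise_sd = 0.3,
                                  seed = 1L, pollen_id = "pollen1",
                                  condition = "mock", render = FALSE,
                                  pixel_size_um = 0.5) {
  if (L0 <= 0) stop("`L0` must be positive")
  if (duration < interval) stop("`duration` must be at least `interval`")
  if (interval <= 0) stop("`interval` must be positive")
  set.seed(seed)
  t_min <- seq(0, duration, by = interval)
  width <- L0 * (1 + plateau_rate / 100 * (1 - exp(-t_min / tau)))
  if (noise_sd > 0) {
    noise <- stats::rnorm(length(width), 0, noise_sd)
    noise[1] <- 0   # L0 defines the reference width exactly
    width <- width + noise
  }
  track <- data.frame(pollen_id = pollen_id, condition = condition,
                      time_min = t_min, width_um = width,
                      stringsAsFactors = FALSE)
  out <- list(track = track)
  if (render) {
    # frame large enough for the fully hydrated grain; major axis fixed at
    # 1.3 * L0 (hydration widens the grain mostly along its minor axis)
    major <- 1.3 * L0
    side <- ceiling((max(major, max(width)) / pixel_size_um + 16) / 2) * 2
    frames <- array(0, dim = c(side, side, length(t_min)))
    for (k in seq_along(t_min)) {
      frames[, , k] <- render_ellipse_mask(side, side,
                                           a_px = major / 2 / pixel_size_um,
                                           b_px = width[k] / 2 / pixel_size_um,
                                           angle_deg = 30) * 255
    }
    out$frames <- frames
    out$pixel_size_um <- pixel_size_um
  }
  out
}

#' Rasterize a filled ellipse
#'
#' @param H,W frame size in pixels.
#' @param a_px,b_px semi-major and semi-minor axes in pixels.
#' @param angle_deg rotation of the major axis, degrees counter-clockwise.
#' @param cy,cx centre (defaults to the frame centre).
#' @return logical matrix, `TRUE` inside the ellipse.
#' @export
render_ellipse_mask <- function(H, W, a_px, b_px, angle_deg = 0,
                                cy = (H + 1) / 2, cx = (W + 1) / 2) {
  th <- angle_deg * pi / 180
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  u <- (col - cx) * cos(th) + (row - cy) * sin(th)
  v <- -(col - cx) * sin(th) + (row - cy) * cos(th)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

#' Hydration-kinetics presets per condition
#'
#' Asymptotic hydration rate and time constant used by the pipeline for
#' each condition. Wortmannin suppresses the plateau dose-dependently
#' (monotone non-increasing in dose); other treatments leave hydration
#' essentially unchanged.
#'
#' @param condition `"mock"`, `"e64d"`, `"pdmp"`, `"wortmannin"`, or
#'   `"rop2"`.
#' @param dose_um wortmannin dose in micromolar.
#' @return list with `plateau_rate` (percent) and `tau` (minutes).
#' @export
hydration_preset <- function(condition, dose_um = 500) {
  switch(condition,
    mock = list(plateau_rate = 40, tau = 4),
    e64d = list(plateau_rate = 38, tau = 4),
    pdmp = list(plateau_rate = 38, tau = 4),
    wortmannin = {
      if (dose_um < 0) stop("`dose_um` must be nonnegative")
      list(plateau_rate = 40 * (1 - 0.72 * dose_um / (dose_um + 60)), tau = 4)
    },
    rop2 = list(plateau_rate = 48, tau = 3),
    stop("unknown condition: ", condition)
  )
}
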