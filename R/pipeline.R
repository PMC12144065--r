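#' Group comparison tests
#'
#' Two-sided multiple-comparison tests as used for constriction counts and
#' hydration rates: Dunnett's many-to-one test against a control group
#' (single-step adjusted p-values from the exact multivariate-t
#' distribution), Tukey's HSD over all pairs (studentized range), or
#' pairwise Welch t tests against the control (unadjusted). Significance
#' stars follow the usual convention: `**` p < 0.01, `***` p < 0.001.
#'
#' @param values numeric vector of observations.
#' @param groups factor or character vector of group labels.
#' @param method `"dunnett"`, `"tukey"` or `"welch"`.
#' @param control control-group label (required for dunnett and welch).
#' @return data frame with one row per comparison: `comparison`,
#'   `estimate` (difference in means), `statistic`, `df`, `p`, `stars`.
#' @export
compare_groups <- function(values, groups, method = c("dunnett", "tukey", "welch"),
                           control = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  g <- split(values, groups)
  if (length(g) < 2) stop("need at least 2 groups")
  ns <- vapply(g, length, integer(1))
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  means <- vapply(g, mean, numeric(1))
  vars <- vapply(g, stats::var, numeric(1))
  labs <- names(g)
  stars <- function(p) ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "N.S.")))

  if (method == "welch") {
    if (is.null(control)) stop("welch comparisons need a `control` label")
    if (!control %in% labs) stop("unknown control group: ", control)
    others <- setdiff(labs, control)
    out <- do.call(rbind, lapply(others, function(lb) {
      tt <- stats::t.test(g[[lb]], g[[control]])
      data.frame(comparison = paste(lb, "-", control),
                 estimate = means[lb] - means[control],
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  } else if (method == "tukey") {
    k <- length(g)
    nu <- sum(ns) - k
    s2 <- sum((ns - 1) * vars) / nu          # pooled variance
    pairs <- utils::combn(labs, 2)
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt(s2 / 2 * (1 / ns[a] + 1 / ns[b]))
      qstat <- abs(means[a] - means[b]) / se
      data.frame(comparison = paste(a, "-", b),
                 estimate = unname(means[a] - means[b]),
                 statistic = unname(qstat), df = nu,
                 p = stats::ptukey(qstat, k, nu, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  } else {
    if (is.null(control)) stop("dunnett comparisons need a `control` label")
    if (!control %in% labs) stop("unknown control group: ", control)
    others <- setdiff(labs, control)
    k <- length(others)
    nu <- sum(ns) - length(g)
    s2 <- sum((ns - 1) * vars) / nu
    se <- sqrt(s2 * (1 / ns[others] + 1 / ns[control]))
    tstat <- (means[others] - means[control]) / se
    # correlation of the comparisons: rho_ij = lambda_i * lambda_j
    lam <- sqrt(ns[others] / (ns[others] + ns[control]))
    R <- outer(lam, lam)
    diag(R) <- 1
    p <- vapply(seq_len(k), function(j) {
      # single-step adjusted two-sided p: P(max_i |T_i| > |t_j|)
      pr <- mvtnorm::pmvt(lower = rep(-abs(tstat[j]), k),
                          upper = rep(abs(tstat[j]), k),
                          df = as.integer(nu), corr = R, sigma = NULL,
                          algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                         maxpts = 100000),
                          seed = 1L)
      max(1 - as.numeric(pr), 0)
    }, numeric(1))
    out <- data.frame(comparison = paste(others, "-", control),
                      estimate = unname(means[others] - means[control]),
                      statistic = unname(tstat), df = nu, p = p,
                      stringsAsFactors = FALSE)
  }
  out$stars <- stars(out$p)
  rownames(out) <- NULL
  out
}

#' Validate a pipeline run configuration
#'
#' @param config list; see [run_pipeline()] for recognized fields.
#' @return the config with defaults filled in; errors describe the first
#'   invalid field.
#' @export
validate_config <- function(config) {
  defaults <- list(
    conditions = c("mock", "wortmannin"), dose_um = 500,
    control = "mock", n_cells = 5L, n_pollen = 5L, seed = 1L,
    frame_count = 60L, frame_interval_s = 10, noise_sd = 6,
    percentile = 97, per_frame = TRUE,
    span_frac = 0.9, persistence = 2L, merge_dist = 5,
    ssm = list(chains = 4L, warmup = 1000L, draws = 1000L),
    write_movies = FALSE, make_plots = TRUE, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out_dir)) stop("config needs `out_dir`")
  if (length(config$conditions) < 2) stop("config needs >= 2 conditions")
  if (is.null(config$control) || !config$control %in% config$conditions)
    stop("config needs a `control` label among `conditions`")
  if (is.null(config$seed)) stop("config needs a `seed`")
  config
}

#' Run the full synthetic analysis pipeline
#'
#' End-to-end orchestration on synthetic data: simulate tonoplast movies
#' for each condition, preprocess and compute NCC series, detect and
#' summarize constriction events, simulate and summarize pollen hydration,
#' fit the Bayesian state-space model of the control vs each experimental
#' condition, run the group tests, and write CSV tables, plots, and a
#' manifest to `out_dir`. Everything is seeded from `config$seed`;
#' repeated runs write identical tables.
#'
#' @param config list (or path to a JSON file) with fields `conditions`
#'   (first-class preset names; `"wortmannin"` uses `dose_um`), `control`,
#'   `n_cells`, `n_pollen`, `seed`, `out_dir`, imaging parameters
#'   (`frame_count`, `frame_interval_s`, `noise_sd`, `percentile`,
#'   `per_frame`), detector parameters (`span_frac`, `persistence`,
#'   `merge_dist`), `ssm` settings (`chains`, `warmup`, `draws`),
#'   `write_movies`, `make_plots`.
#' @return invisibly, a list with the assembled tables (`ncc`,
#'   `constriction_counts`, `constriction_summary`, `hydration`,
#'   `hydration_rates`, `ssm_summaries`, `tests`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(config$make_plots))
    dir.create(file.path(config$out_dir, "plots"), showWarnings = FALSE)

  conds <- config$conditions
  ncc_all <- list(); counts <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    for (cell in seq_len(config$n_cells)) {
      scn <- scenario_presets(cond, dose_um = config$dose_um,
                              seed = config$seed + 101L * ci + cell,
                              frame_count = config$frame_count,
                              frame_interval_s = config$frame_interval_s,
                              noise_sd = config$noise_sd)
      sim <- simulate_vacuole_sequence(scn)
      if (isTRUE(config$write_movies))
        write_frame_stack(sim$stack,
                          file.path(config$out_dir,
                                    sprintf("movie_%s_cell%d.tif", cond, cell)))
      pre <- preprocess_stack(sim$stack, p = config$percentile,
                              per_frame = config$per_frame)
      id <- sprintf("%s_cell%d", cond, cell)
      ncc_all[[id]] <- ncc_series(pre, cell_id = id, condition = cond,
                                  mask = sim$cell_mask)
      det <- detect_constrictions(pre, sim$cell_mask,
                                  span_frac = config$span_frac,
                                  persistence = config$persistence,
                                  merge_dist = config$merge_dist,
                                  cell_id = id)
      counts[[id]] <- data.frame(cell_id = id, condition = cond,
                                 count = det$count, stringsAsFactors = FALSE)
    }
  }
  ncc_tab <- do.call(rbind, ncc_all); rownames(ncc_tab) <- NULL
  count_tab <- do.call(rbind, counts); rownames(count_tab) <- NULL
  count_summary <- compare_counts(count_tab)

  # pollen hydration per condition
  hyd <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    hp_name <- if (cond %in% c("mock", "e64d", "pdmp", "wortmannin")) cond
               else "mock"
    hp <- hydration_preset(hp_name, dose_um = config$dose_um)
    for (gi in seq_len(config$n_pollen)) {
      sim <- simulate_pollen_assay(plateau_rate = hp$plateau_rate, tau = hp$tau,
                                   seed = config$seed + 977L * ci + gi,
                                   pollen_id = sprintf("%s_pollen%d", cond, gi),
                                   condition = cond)
      hyd[[length(hyd) + 1L]] <- sim$track
    }
  }
  hyd_tab <- do.call(rbind, hyd); rownames(hyd_tab) <- NULL
  hyd_rates <- hydration_timecourse(hyd_tab)

  # state-space model: control vs each experimental condition (pairwise)
  ssm_summaries <- list()
  for (cond in setdiff(conds, config$control)) {
    sdat <- ssm_data(ncc_tab, control = config$control, experimental = cond)
    post <- sample_posterior(sdat, chains = config$ssm$chains,
                             warmup = config$ssm$warmup,
                             draws = config$ssm$draws, seed = config$seed)
    sm <- summarize_posterior(post)
    sm$comparison <- paste(cond, "-", config$control)
    ssm_summaries[[cond]] <- sm
  }
  ssm_tab <- do.call(rbind, ssm_summaries); rownames(ssm_tab) <- NULL

  tests <- compare_groups(count_tab$count, count_tab$condition,
                          method = if (length(conds) > 2) "dunnett" else "welch",
                          control = config$control)

  wr <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                        row.names = FALSE)
  wr(ncc_tab, "ncc.csv")
  wr(count_tab, "constriction_counts.csv")
  wr(count_summary, "constriction_summary.csv")
  wr(hyd_tab, "hydration_widths.csv")
  wr(hyd_rates, "hydration_rates.csv")
  wr(ssm_tab, "ssm_summary.csv")
  wr(tests, "group_tests.csv")

  if (isTRUE(config$make_plots)) {
    plot_ncc_band(ncc_tab, ssm_tab, config$control,
                  file.path(config$out_dir, "plots", "ncc_band.png"))
    plot_delta_band(ssm_tab, file.path(config$out_dir, "plots", "delta_band.png"))
    plot_count_bars(count_summary,
                    file.path(config$out_dir, "plots", "constriction_counts.png"))
  }

  manifest <- list(package = "vacmorph",
                   version = as.character(utils::packageVersion("vacmorph")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(ncc = ncc_tab, constriction_counts = count_tab,
                 constriction_summary = count_summary, hydration = hyd_tab,
                 hydration_rates = hyd_rates, ssm_summaries = ssm_tab,
                 tests = tests, manifest = manifest))
}

# --- plots ------------------------------------------------------------------

#' Band plot of NCC series with the posterior mean band
#' @param ncc_tab long NCC table.
#' @param ssm_tab output of [summarize_posterior()] (possibly stacked).
#' @param control control condition label.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @keywords internal
#' @export
plot_ncc_band <- function(ncc_tab, ssm_tab, control, path) {
  p <- ggplot2::ggplot(ncc_tab,
                       ggplot2::aes(x = time_s, y = ncc,
                                    colour = condition)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_ribbon(data = ssm_tab,
                         ggplot2::aes(x = time_s, ymin = mu_lo,
                                      ymax = mu_hi),
                         inherit.aes = FALSE, alpha = 0.3) +
    ggplot2::geom_line(data = ssm_tab,
                       ggplot2::aes(x = time_s, y = mu_med),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "time (s)", y = "NCC vs first frame",
                  title = paste("posterior mean band:", control)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
  invisible(path)
}

#' Band plot of the posterior group difference
#' @inheritParams plot_ncc_band
#' @keywords internal
#' @export
plot_delta_band <- function(ssm_tab, path) {
  p <- ggplot2::ggplot(ssm_tab, ggplot2::aes(x = time_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = delta_lo,
                                      ymax = delta_hi,
                                      fill = comparison), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = delta_med,
                                    colour = comparison)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "difference in NCC (delta)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
  invisible(path)
}

#' Bar plot of constriction counts (mean +/- SEM)
#' @param count_summary output of [compare_counts()].
#' @param path output PNG path.
#' @keywords internal
#' @export
plot_count_bars <- function(count_summary, path) {
  p <- ggplot2::ggplot(count_summary,
                       ggplot2::aes(x = condition, y = mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                        ymax = mean + sem),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "constrictions / 10 min (mean ± SEM)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
  invisible(path)
}
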