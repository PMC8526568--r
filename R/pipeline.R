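#' Analysis options for the imaging arm
#'
#' Correction toggles and statistical parameters consumed by
#' [analyze_scene()] and [run_imaging_pipeline()]. All corrections default
#' to on; every constant the statistics depend on surfaces here.
#'
#' @param dark,shading,registration,background,bleedthrough,photobleach
#'   Logical toggles for the correction chain stages.
#' @param k Background-range width in background standard deviations
#'   ([background_range_mask()]).
#' @param min_pixels Minimum joint valid pixels per frame for the
#'   correlation ([framewise_pearson()]).
#' @param smooth_window Temporal window for segmentation threshold
#'   smoothing.
#' @return A list of class `analysis_options`.
#' @export
analysis_options <- function(dark = TRUE, shading = TRUE, registration = TRUE,
                             background = TRUE, bleedthrough = TRUE,
                             photobleach = TRUE, k = 2, min_pixels = 100,
                             smooth_window = 5L) {
  structure(list(dark = dark, shading = shading, registration = registration,
                 background = background, bleedthrough = bleedthrough,
                 photobleach = photobleach, k = k, min_pixels = min_pixels,
                 smooth_window = smooth_window),
            class = "analysis_options")
}

preprocess_stack <- function(stack, bundle, opts, mask = NULL) {
  log <- list()
  if (opts$dark) { stack <- subtract_dark(stack, bundle); log$dark <- TRUE }
  if (opts$shading) { stack <- shading_correct(stack, bundle); log$shading <- TRUE }
  if (opts$registration) {
    if (is.null(bundle$fiducials)) stop("registration enabled but no fiducials")
    tf <- estimate_affine_from_fiducials(bundle$fiducials$src,
                                         bundle$fiducials$dst)
    stack <- apply_affine(stack, tf)
    log$registration <- list(matrix = tf$matrix, residual = tf$residual)
  }
  bg_levels <- NULL
  if (opts$background) {
    bg <- subtract_background(stack, bundle, mask = mask)
    stack <- bg$stack; bg_levels <- bg$levels
    log$background <- TRUE
  }
  list(stack = stack, background_levels = bg_levels, log = log)
}

#' Analyze one dual-biosensor scene end to end
#'
#' Runs the fixed correction order (dark, shading, registration, background),
#' segments the cell from the donor channel, builds the background-range
#' validity mask, estimates bleed-through from the bundle's control stacks,
#' computes the FRET and GTP indices, photobleach-corrects both, and
#' summarizes the per-frame pixel-wise Pearson correlation.
#'
#' @param stack A [raw_stack()].
#' @param bundle A [correction_bundle()].
#' @param opts An [analysis_options()].
#' @return A list of class `scene_analysis`: `record`
#'   ([summarize_cell()]), `series`, `fret`, `gtp` (`index_stack`s),
#'   `mask`, `alpha`, `beta`, and the stage `log`.
#' @export
analyze_scene <- function(stack, bundle, opts = analysis_options()) {
  stopifnot(inherits(stack, "raw_stack"), inherits(bundle, "correction_bundle"))
  pre <- preprocess_stack(stack, bundle, opts)
  stack <- pre$stack
  masks <- segment_cells(stack, smooth_window = opts$smooth_window)
  valid <- if (!is.null(pre$background_levels))
    background_range_mask(stack, pre$background_levels, k = opts$k)
  else !is.na(get_channel(stack, "donor")) & masks$mask
  valid <- valid & masks$mask

  alpha <- 0; beta <- 0
  if (opts$bleedthrough) {
    if (is.null(bundle$donor_only) || is.null(bundle$acceptor_only))
      stop("bleed-through correction enabled but control stacks missing")
    d_ctrl <- preprocess_stack(bundle$donor_only, bundle,
                               within_opts_no_register(opts))$stack
    a_ctrl <- preprocess_stack(bundle$acceptor_only, bundle,
                               within_opts_no_register(opts))$stack
    bt <- estimate_bleedthrough(d_ctrl, a_ctrl)
    alpha <- bt$alpha; beta <- bt$beta
  }

  fret <- compute_fret_index(get_channel(stack, "fret"),
                             get_channel(stack, "donor"),
                             get_channel(stack, "acceptor"),
                             alpha = alpha, beta = beta, valid = valid)
  gtp <- compute_gtp_index(get_channel(stack, "ex409"),
                           get_channel(stack, "ex494"), valid = valid)
  if (opts$photobleach && n_frames(stack) >= 6) {
    fret <- photobleach_correct(fret, masks, stack$frame_interval)
    gtp <- photobleach_correct(gtp, masks, stack$frame_interval)
  }
  series <- correlation_series(fret, gtp, min_pixels = opts$min_pixels)
  record <- summarize_cell(series)
  structure(list(record = record, series = series, fret = fret, gtp = gtp,
                 mask = masks, alpha = alpha, beta = beta, log = pre$log),
            class = "scene_analysis")
}

# Control stacks are acquired on the reference camera; the GEVAL
# registration step does not apply to them.
within_opts_no_register <- function(opts) {
  opts$registration <- FALSE
  opts
}

#' Imaging-arm run configuration
#'
#' @param n_cells Cells per group.
#' @param groups Named list of [sensor_model()]s, one group per entry
#'   (e.g. GEVAL30 and the null sensor); a single entry runs one group.
#' @param scene Base [scene_config()]; each cell gets `seed + cell index`.
#' @param opts [analysis_options()].
#' @param seed Base seed.
#' @return A list of class `imaging_config`.
#' @export
imaging_config <- function(n_cells = 10,
                           groups = list(geval30 = sensor_model(),
                                         null = sensor_model(is_null = TRUE)),
                           scene = scene_config(), opts = analysis_options(),
                           seed = 1L) {
  structure(list(n_cells = n_cells, groups = groups, scene = scene,
                 opts = opts, seed = seed),
            class = "imaging_config")
}

#' Run the imaging arm end to end
#'
#' For each group and cell: simulate a scene (seeded per cell), run
#' [analyze_scene()], collect the per-cell mean correlations; with two
#' groups the per-cell mean r values are compared by Mann-Whitney test.
#'
#' @param config An [imaging_config()].
#' @param progress Print one line per cell.
#' @return A list of class `imaging_run`: `cells` (data.frame of group,
#'   cell, mean/median r, frames), `records`, `comparison` (or `NULL`),
#'   and `manifest`.
#' @export
run_imaging_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "imaging_config"))
  rows <- list(); records <- list()
  for (g in names(config$groups)) {
    for (i in seq_len(config$n_cells)) {
      cfg <- config$scene
      cfg$seed <- config$seed + 131L * match(g, names(config$groups)) + i
      scene <- simulate_scene(cfg, sensor = config$groups[[g]])
      ana <- suppressWarnings(analyze_scene(scene$stack, scene$bundle,
                                            config$opts))
      rec <- ana$record
      records[[paste(g, i, sep = "_")]] <- rec
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, cell = i, mean_r = rec$mean_r,
                   median_r = rec$median_r, n_frames = rec$n_frames,
                   rho_true = cfg$rho, alpha_hat = ana$alpha,
                   beta_hat = ana$beta)
      if (progress)
        message(sprintf("[%s cell %d] mean r = %.3f (%d frames)",
                        g, i, rec$mean_r, rec$n_frames))
    }
  }
  cells <- do.call(rbind, rows)
  comparison <- NULL
  if (length(config$groups) == 2) {
    gs <- names(config$groups)
    comparison <- mann_whitney(cells$mean_r[cells$group == gs[1]],
                               cells$mean_r[cells$group == gs[2]])
  }
  manifest <- list(arm = "imaging", seed = config$seed,
                   n_cells = config$n_cells, groups = names(config$groups),
                   scene = unclass(config$scene)[setdiff(names(config$scene),
                                                         c("bleach", "misreg"))],
                   opts = unclass(config$opts),
                   version = as.character(utils::packageVersion("gtpcoupling")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  structure(list(cells = cells, records = records, comparison = comparison,
                 manifest = manifest),
            class = "imaging_run")
}

#' Run the coevolution arm end to end
#'
#' Simulates (or loads) a pair of ortholog sets, scores inter-protein
#' couplings, convolves, thresholds, and runs the species-shuffle
#' randomization test.
#'
#' @param set_a,set_b [ortholog_set()]s; when `NULL` they are simulated
#'   with `sim` via [generate_coevolving_msa()].
#' @param sim List of arguments for [generate_coevolving_msa()].
#' @param n_replicates,sigma,fraction,statistic,method See
#'   [randomization_test()].
#' @param seed Integer seed.
#' @return A list of class `coevolution_run`: `coupling_map`, `threshold`,
#'   `outcome`, `top_pairs`, `truth` (when simulated) and `manifest`.
#' @export
run_coevolution_pipeline <- function(set_a = NULL, set_b = NULL,
                                     sim = list(), n_replicates = 100,
                                     sigma = 2, fraction = 0.05,
                                     statistic = "max",
                                     method = "mean_field", seed = 1L) {
  truth <- NULL
  if (is.null(set_a) || is.null(set_b)) {
    simargs <- utils::modifyList(list(seed = seed), sim)
    gen <- do.call(generate_coevolving_msa, simargs)
    set_a <- gen$set_a; set_b <- gen$set_b; truth <- gen$truth
  }
  rt <- randomization_test(set_a, set_b, n_replicates = n_replicates,
                           sigma = sigma, fraction = fraction,
                           statistic = statistic, method = method,
                           seed = seed + 7L)
  n_top <- if (!is.null(truth$pairs)) nrow(truth$pairs) else 10L
  manifest <- list(arm = "coevolution", seed = seed,
                   n_replicates = n_replicates, sigma = sigma,
                   fraction = fraction, statistic = statistic,
                   method = method,
                   version = as.character(utils::packageVersion("gtpcoupling")))
  structure(list(coupling_map = rt$coupling_map, threshold = rt$threshold,
                 outcome = rt$outcome,
                 top_pairs = top_coupling_pairs(rt$coupling_map, n_top),
                 truth = truth, manifest = manifest),
            class = "coevolution_run")
}

#' Compare paired CB/CP GEVAL ratios
#'
#' Per-cell GEVAL ratios measured in the cell body (CB) and the matched
#' protrusion (CP) are compared by a two-tailed paired t-test (default) or
#' an unpaired Welch t-test.
#'
#' @param table Data.frame with `cb` and `cp` columns (one row per cell).
#' @param test `"paired"` or `"unpaired"`.
#' @return A `group_comparison`.
#' @export
cbcp_quantification <- function(table, test = c("paired", "unpaired")) {
  test <- match.arg(test)
  stopifnot(all(c("cb", "cp") %in% names(table)))
  if (test == "paired") {
    if (anyNA(table$cb) || anyNA(table$cp))
      stop("paired test requires complete pairs")
    paired_t(table$cb, table$cp)
  } else {
    unpaired_t(table$cp, table$cb)
  }
}
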