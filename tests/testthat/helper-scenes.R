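# Small-scene helpers shared across tests: unit tests run on reduced grids
# and frame counts; acceptance-level checks use the generator defaults.

tiny_config <- function(...) {
  args <- list(...)
  base <- list(dim = c(96, 96), n_frames = 8)
  do.call(scene_config, utils::modifyList(base, args))
}

# Artifact-free scene: the forward model reduces to the pure signal.
clean_config <- function(...) {
  args <- list(...)
  base <- list(dim = c(96, 96), n_frames = 8,
               alpha = 0, beta = 0, shading_amplitude = 0, dark_offset = 0,
               background_level = 0, background_drift = 0,
               shot_gain = 0, read_sd = 0, bleach = NULL, misreg = NULL)
  do.call(scene_config, utils::modifyList(base, args))
}

all_corrections_off <- function() {
  analysis_options(dark = FALSE, shading = FALSE, registration = FALSE,
                   background = FALSE, bleedthrough = FALSE,
                   photobleach = FALSE)
}

# Mean per-cell correlation from a freshly simulated scene.
recovered_mean_r <- function(cfg, sensor = sensor_model(),
                             opts = analysis_options()) {
  sc <- simulate_scene(cfg, sensor)
  suppressWarnings(analyze_scene(sc$stack, sc$bundle, opts))$record$mean_r
}

precision_at_k <- function(gen, k = 5, method = "mean_field") {
  cm <- compute_couplings(concat_by_species(gen$set_a, gen$set_b),
                          method = method)
  tp <- top_coupling_pairs(cm, k)
  truth_key <- paste(gen$truth$pairs[, 1], gen$truth$pairs[, 2])
  mean(paste(tp$i, tp$j) %in% truth_key)
}
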