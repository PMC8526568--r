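#' Configuration of a synthetic dual-biosensor scene
#'
#' Parameterizes the forward model that renders ground-truthed five-channel
#' time-lapse stacks: a cell-shaped mask (ellipse body plus a protrusion
#' lobe), smooth latent GTP and RAC1-activity fields with a target pixel
#' correlation `rho`, the GEVAL saturating response, FRET bleed-through,
#' per-wavelength shading, dark current, per-fluorophore double-exponential
#' photobleaching, shot/read noise, background fluorescence, and a small
#' affine misregistration of the GEVAL camera.
#'
#' Defaults emulate a motile cell imaged at 1-min intervals for 30 min with
#' a few thousand counts of signal per channel (moderate-noise sCMOS-like
#' regime): latent GTP fluctuates around the GEVAL30 Keff (mean 32.3 µM,
#' s.d. 8 µM, well inside the sensor's 4-100 µM responsive range).
#'
#' @param dim Image size in pixels, `c(rows, cols)`.
#' @param n_frames Number of frames (1-min spacing by default).
#' @param frame_interval Minutes between frames.
#' @param rho Target in-mask pixel correlation of the latent GTP and
#'   activity fields, in `[-1, 1]`; enforced exactly per frame.
#' @param gtp_mean,gtp_sd Latent free-GTP level, µM.
#' @param activity_mean,activity_sd Latent RAC1 activity (dimensionless
#'   FRET-ratio units).
#' @param smooth_sigma Spatial Gaussian scale of the latent fields, px.
#' @param ar1 Temporal AR(1) coefficient of the latent fields.
#' @param alpha,beta Bleed-through fractions of donor / directly excited
#'   acceptor emission into the FRET channel, in `[0, 1)`.
#' @param shading_amplitude Relative amplitude of the per-channel
#'   illumination shading fields (0 disables shading).
#' @param dark_offset Dark-current offset, counts (per channel, recycled).
#' @param background_level Mean background fluorescence, counts.
#' @param background_drift Peak-to-peak slow temporal drift of the
#'   background level, counts.
#' @param donor_base,acceptor_base,geval_base Peak in-cell signal, counts.
#' @param texture_sd Relative s.d. of the smooth static expression texture.
#' @param shot_gain Shot-noise gain g (variance = g * intensity); 0 disables.
#' @param read_sd Gaussian read-noise s.d., counts; 0 disables.
#' @param bleach Named list of per-fluorophore double-exponential decay
#'   parameters `c(a1, k1, a2, k2)` with `a1 + a2 = 1` (rates per minute);
#'   `NULL` disables photobleaching.
#' @param misreg 2x3 affine matrix mapping reference coordinates to GEVAL
#'   camera coordinates (translations <= 2 px), or `NULL` for none.
#' @param protrusion_gtp_offset Extra GTP (µM) added inside the protrusion
#'   lobe, mimicking protrusion enrichment; 0 by default so `rho` is exact.
#' @param seed Integer seed; every stochastic draw derives from it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(dim = c(144, 144), n_frames = 30, frame_interval = 1,
                         rho = 0.5,
                         gtp_mean = 32.3, gtp_sd = 8,
                         activity_mean = 1.5, activity_sd = 0.25,
                         smooth_sigma = 3, ar1 = 0.8,
                         alpha = 0.2, beta = 0.1,
                         shading_amplitude = 0.15,
                         dark_offset = 100,
                         background_level = 30, background_drift = 6,
                         donor_base = 3000, acceptor_base = 2000,
                         geval_base = 5000, texture_sd = 0.15,
                         shot_gain = 0.5, read_sd = 2,
                         bleach = list(
                           donor    = c(0.60, 0.030, 0.40, 0.004),
                           fret     = c(0.55, 0.035, 0.45, 0.003),
                           acceptor = c(0.65, 0.025, 0.35, 0.003),
                           ex409    = c(0.60, 0.028, 0.40, 0.004),
                           ex494    = c(0.55, 0.022, 0.45, 0.003)),
                         misreg = rbind(c(1, 0, 1.0), c(0, 1, -0.7)),
                         protrusion_gtp_offset = 0,
                         seed = 1L) {
  stopifnot(length(dim) == 2L, all(dim >= 32), n_frames >= 1,
            abs(rho) <= 1, gtp_sd >= 0, activity_sd >= 0,
            alpha >= 0, alpha < 1, beta >= 0, beta < 1,
            shading_amplitude >= 0, shot_gain >= 0, read_sd >= 0)
  if (!is.null(bleach)) {
    stopifnot(all(CHANNELS %in% names(bleach)))
    for (b in bleach) {
      stopifnot(length(b) == 4L, all(is.finite(b)), all(b[c(2, 4)] >= 0))
      if (abs(b[1] + b[3] - 1) > 1e-8)
        stop("bleach amplitudes must satisfy a1 + a2 = 1")
    }
  }
  if (!is.null(misreg)) stopifnot(is.matrix(misreg), all(dim(misreg) == c(2, 3)))
  cfg <- as.list(environment())
  class(cfg) <- "scene_config"
  cfg
}

# Double-exponential bleach multiplier at times t (minutes); p = (a1,k1,a2,k2).
bleach_curve <- function(p, t) p[1] * exp(-p[2] * t) + p[3] * exp(-p[4] * t)

# Smooth periodic Gaussian random field, standardized later in-mask.
smooth_noise_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) z <- EBImage::gblur(z, sigma = sigma)
  z
}

# Cell mask: ellipse body + half-ellipse protrusion lobe reaching to the
# right edge. Sized so the default 144 px grid holds >= 1e4 in-mask pixels.
make_cell_mask <- function(nr, nc) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  body <- ((rr - 0.50 * nr) / (0.42 * nr))^2 +
          ((cc - 0.44 * nc) / (0.36 * nc))^2 <= 1
  lobe <- ((rr - 0.46 * nr) / (0.24 * nr))^2 +
          ((cc - 0.80 * nc) / (0.185 * nc))^2 <= 1
  body | lobe
}

# Fixed per-channel illumination profiles: off-centre Gaussian vignettes with
# channel-specific optical centres, scaled to the requested amplitude and
# normalized to mean 1 (the same normalization a uniform-dye reference gets).
shading_field <- function(nr, nc, channel, amplitude) {
  centres <- list(donor = c(0.30, 0.30), fret = c(0.70, 0.40),
                  acceptor = c(0.50, 0.70), ex409 = c(0.35, 0.65),
                  ex494 = c(0.75, 0.75))
  if (amplitude == 0) return(matrix(1, nr, nc))
  ctr <- centres[[channel]]
  rr <- matrix(seq_len(nr) / nr, nr, nc)
  cc <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
  s <- exp(-d2 / (2 * 0.45^2))
  s <- 1 + amplitude * (s - mean(s)) / max(abs(s - mean(s)))
  s / mean(s)
}

#' Generate latent GTP and activity fields with known pixel correlation
#'
#' Builds the cell mask and two smooth latent fields — free GTP (µM) and
#' RAC1 activity (ratio units) — whose in-mask pixel correlation equals
#' `rho` exactly in every frame: the activity field is constructed as
#' `rho * standardized(gtp) + sqrt(1 - rho^2) * orthogonalized noise`, with
#' the noise component projected orthogonal to the GTP component within the
#' mask before mixing. Both underlying fields evolve as spatially smoothed
#' AR(1) processes so consecutive frames resemble 1-min live-cell dynamics.
#'
#' @param config A [scene_config()].
#' @return A list of class `ground_truth` with elements `mask` (logical
#'   matrix), `gtp_field` and `activity_field` (`row x col x frame` arrays,
#'   `NA` outside the mask), and `config`.
#' @export
generate_latent_fields <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (abs(config$rho) > 1) stop("rho must lie in [-1, 1]")
  set.seed(config$seed)
  nr <- config$dim[1]; nc <- config$dim[2]; nt <- config$n_frames
  mask <- make_cell_mask(nr, nc)
  idx <- which(mask)
  gtp <- array(NA_real_, c(nr, nc, nt))
  act <- array(NA_real_, c(nr, nc, nt))
  g_prev <- e_prev <- NULL
  phi <- config$ar1
  for (t in seq_len(nt)) {
    g_new <- smooth_noise_field(nr, nc, config$smooth_sigma)
    e_new <- smooth_noise_field(nr, nc, config$smooth_sigma)
    if (t == 1L || phi == 0) {
      g_t <- g_new; e_t <- e_new
    } else {
      g_t <- phi * g_prev + sqrt(1 - phi^2) * g_new
      e_t <- phi * e_prev + sqrt(1 - phi^2) * e_new
    }
    g_prev <- g_t; e_prev <- e_t
    g <- g_t[idx]; e <- e_t[idx]
    # Exact-correlation construction: centre both, project the noise
    # component orthogonal to g within the mask, equalize norms, then mix.
    g <- g - mean(g)
    e <- e - mean(e)
    e <- e - g * sum(e * g) / sum(g * g)
    g <- g / sqrt(mean(g^2))
    e <- e / sqrt(mean(e^2))
    a <- config$rho * g + sqrt(1 - config$rho^2) * e
    if (config$rho^2 < 1) a <- a / sqrt(mean(a^2))
    gf <- pmax(config$gtp_mean + config$gtp_sd * g, 0.5)
    if (config$protrusion_gtp_offset != 0)
      gf <- gf + config$protrusion_gtp_offset * (col(mask)[idx] > 0.72 * nc)
    af <- config$activity_mean + config$activity_sd * a
    slab_g <- matrix(NA_real_, nr, nc); slab_g[idx] <- gf
    slab_a <- matrix(NA_real_, nr, nc); slab_a[idx] <- af
    gtp[, , t] <- slab_g
    act[, , t] <- slab_a
  }
  structure(list(mask = mask, gtp_field = gtp, activity_field = act,
                 config = config),
            class = "ground_truth")
}

# Bilinear sample of matrix `m` at (r, c) positions; outside -> NA.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  r0 <- pmin(floor(r[ok]), nr - 1L); c0 <- pmin(floor(c[ok]), nc - 1L)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
       fr * (1 - fc)       * m[cbind(r0 + 1L, c0)] +
       (1 - fr) * fc       * m[cbind(r0, c0 + 1L)] +
       fr * fc             * m[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v
  out
}

# Sample a reference-frame image as seen by a camera whose pixel u maps to
# reference position M %*% (u, 1). NA-safe: NA source values propagate.
warp_from_reference <- function(img, M) {
  nr <- nrow(img); nc <- ncol(img)
  u_r <- rep(seq_len(nr), nc)
  u_c <- rep(seq_len(nc), each = nr)
  ref_r <- M[1, 1] * u_r + M[1, 2] * u_c + M[1, 3]
  ref_c <- M[2, 1] * u_r + M[2, 2] * u_c + M[2, 3]
  matrix(bilinear_sample(img, ref_r, ref_c), nr, nc)
}

is_identity_affine <- function(M, tol = 1e-12) {
  !is.null(M) && max(abs(M - rbind(c(1, 0, 0), c(0, 1, 0)))) < tol
}

#' Render a five-channel raw stack from latent ground truth
#'
#' Forward model of the acquisition. In-cell signal levels (counts) are:
#' donor `= D0 * E * bD(t)`, acceptor `= A0 * E * bA(t)`, FRET
#' `= activity * D0 * E * bF(t) + alpha * donor + beta * acceptor`
#' (bleed-through contaminates the measured FRET channel), and the GEVAL
#' pair `ex494 = G0 * Eg * b494(t)`, `ex409 = response(gtp) * G0 * Eg *
#' b409(t)`, so the 409/494 ratio encodes the sensor response. GEVAL
#' channels are resampled through the true misregistration affine. Each
#' channel is then degraded as `shading * (signal + background(t)) + dark +
#' noise`. The returned bundle carries the matching correction assets (dark
#' frames, mean-1 shading references, background region, fiducial beads
#' consistent with the true affine, and donor-only / acceptor-only control
#' stacks).
#'
#' @param truth A [generate_latent_fields()] result.
#' @param config The same [scene_config()].
#' @param sensor A [sensor_model()] for the GEVAL channels (use
#'   `is_null = TRUE` for the GTP-insensitive control sensor).
#' @return A list of class `scene` with `stack` ([raw_stack()]), `bundle`
#'   ([correction_bundle()]) and `truth` (augmented with the true alpha,
#'   beta, shading fields, affine, bleach curves and background series).
#' @export
render_channels <- function(truth, config, sensor = sensor_model()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "scene_config"),
            inherits(sensor, "sensor_model"))
  set.seed(config$seed + 1000003L)
  nr <- config$dim[1]; nc <- config$dim[2]; nt <- config$n_frames
  tt <- (seq_len(nt) - 1L) * config$frame_interval
  mask <- truth$mask
  shading <- lapply(stats::setNames(CHANNELS, CHANNELS), function(ch)
    shading_field(nr, nc, ch, config$shading_amplitude))
  dark <- lapply(stats::setNames(seq_along(CHANNELS), CHANNELS), function(i)
    matrix(rep_len(config$dark_offset, length(CHANNELS))[i], nr, nc))
  bl <- function(ch, t) if (is.null(config$bleach)) 1
        else bleach_curve(config$bleach[[ch]], t)
  bg_series <- config$background_level +
    0.5 * config$background_drift * sin(pi * tt / max(tt[nt], 1))
  tex_rac <- 1 + config$texture_sd * {
    z <- smooth_noise_field(nr, nc, 2 * config$smooth_sigma); z / stats::sd(z)
  }
  tex_gev <- 1 + config$texture_sd * {
    z <- smooth_noise_field(nr, nc, 2 * config$smooth_sigma); z / stats::sd(z)
  }
  tex_rac <- pmax(tex_rac, 0.2); tex_gev <- pmax(tex_gev, 0.2)

  add_noise <- function(x) {
    if (config$shot_gain > 0)
      x <- config$shot_gain * stats::rpois(length(x), pmax(x, 0) / config$shot_gain)
    if (config$read_sd > 0) x <- x + stats::rnorm(length(x), 0, config$read_sd)
    x
  }

  data <- array(0, c(nr, nc, length(CHANNELS), nt))
  for (t in seq_len(nt)) {
    act <- truth$activity_field[, , t]; gtp <- truth$gtp_field[, , t]
    D <- ifelse(mask, config$donor_base * tex_rac * bl("donor", tt[t]), 0)
    A <- ifelse(mask, config$acceptor_base * tex_rac * bl("acceptor", tt[t]), 0)
    Ftrue <- ifelse(mask, act * config$donor_base * tex_rac * bl("fret", tt[t]), 0)
    Fobs <- Ftrue + config$alpha * D + config$beta * A
    resp <- sensor_response(sensor, ifelse(mask, gtp, 0))
    G494 <- ifelse(mask, config$geval_base * tex_gev * bl("ex494", tt[t]), 0)
    G409 <- ifelse(mask, resp * config$geval_base * tex_gev * bl("ex409", tt[t]), 0)
    if (!is.null(config$misreg) && !is_identity_affine(config$misreg)) {
      G494 <- warp_from_reference(G494, config$misreg)
      G409 <- warp_from_reference(G409, config$misreg)
      G494[is.na(G494)] <- 0; G409[is.na(G409)] <- 0
    }
    sig <- list(donor = D, fret = Fobs, acceptor = A, ex409 = G409, ex494 = G494)
    for (ci in seq_along(CHANNELS)) {
      ch <- CHANNELS[ci]
      x <- shading[[ch]] * (sig[[ch]] + bg_series[t]) + dark[[ch]]
      data[, , ci, t] <- matrix(add_noise(x), nr, nc)
    }
  }
  stack <- raw_stack(data, CHANNELS, config$frame_interval)

  # Fiducial beads: positions in the reference frame; the GEVAL camera sees
  # bead k at the pre-image of the true affine (src = GEVAL coords).
  n_beads <- 8L
  dst <- cbind(stats::runif(n_beads, 8, nr - 8), stats::runif(n_beads, 8, nc - 8))
  Mfull <- if (is.null(config$misreg)) rbind(c(1, 0, 0), c(0, 1, 0)) else config$misreg
  # src solves M (src,1) = position seen; camera pixel u maps to reference
  # M(u); a bead at reference x therefore appears at u = M^{-1}(x).
  Alin <- Mfull[, 1:2]; off <- Mfull[, 3]
  src <- t(solve(Alin, t(dst) - off))
  fiducials <- list(src = src, dst = dst)

  ctrl <- function(kind) {
    nfr <- 3L
    d2 <- array(0, c(nr, nc, length(CHANNELS), nfr))
    for (t in seq_len(nfr)) {
      if (kind == "donor") {
        D <- ifelse(mask, config$donor_base * tex_rac * bl("donor", tt[t]), 0)
        sig <- list(donor = D, fret = config$alpha * D,
                    acceptor = matrix(0, nr, nc),
                    ex409 = matrix(0, nr, nc), ex494 = matrix(0, nr, nc))
      } else {
        A <- ifelse(mask, config$acceptor_base * tex_rac * bl("acceptor", tt[t]), 0)
        sig <- list(donor = matrix(0, nr, nc), fret = config$beta * A,
                    acceptor = A,
                    ex409 = matrix(0, nr, nc), ex494 = matrix(0, nr, nc))
      }
      for (ci in seq_along(CHANNELS)) {
        ch <- CHANNELS[ci]
        x <- shading[[ch]] * (sig[[ch]] + bg_series[t]) + dark[[ch]]
        d2[, , ci, t] <- matrix(add_noise(x), nr, nc)
      }
    }
    raw_stack(d2, CHANNELS, config$frame_interval)
  }

  bundle <- correction_bundle(
    dark = dark, shading = shading,
    background_region = list(rows = 2:12, cols = 2:12),
    alpha = config$alpha, beta = config$beta,
    fiducials = fiducials,
    donor_only = ctrl("donor"), acceptor_only = ctrl("acceptor"))

  truth$alpha <- config$alpha; truth$beta <- config$beta
  truth$shading <- shading; truth$affine <- Mfull
  truth$bleach <- config$bleach; truth$background <- bg_series
  truth$texture <- list(rac = tex_rac, geval = tex_gev)
  structure(list(stack = stack, bundle = bundle, truth = truth,
                 sensor = sensor, config = config), class = "scene")
}

#' Simulate one complete scene
#'
#' Convenience wrapper: [generate_latent_fields()] then [render_channels()].
#' @inheritParams render_channels
#' @param config A [scene_config()].
#' @return A `scene` list (`stack`, `bundle`, `truth`).
#' @export
simulate_scene <- function(config, sensor = sensor_model()) {
  render_channels(generate_latent_fields(config), config, sensor)
}

#' Paired cell-body / cell-protrusion GEVAL ratio dataset
#'
#' Emulates the transwell experiment in which GEVAL ratios are measured in
#' the cell body (CB) above a 3 µm-pore filter and in the matched cell's
#' protrusion (CP) below it: per cell, `CP = CB + offset + noise`. Thirty
#' cells per experiment matches the quantification design.
#'
#' @param n_cells Number of cells (>= 2).
#' @param offset True mean CP - CB ratio difference.
#' @param cell_sd Between-cell s.d. of the CB baseline ratio.
#' @param noise_sd Within-cell measurement s.d. of the paired difference.
#' @param cb_mean Mean CB ratio.
#' @param seed Integer seed.
#' @return A data.frame with columns `cell`, `cb`, `cp`.
#' @export
generate_cbcp_dataset <- function(n_cells = 30, offset = 0.15,
                                  cell_sd = 0.15, noise_sd = 0.08,
                                  cb_mean = 1.3, seed = 1L) {
  stopifnot(n_cells >= 2)
  set.seed(seed)
  cb <- stats::rnorm(n_cells, cb_mean, cell_sd)
  cp <- cb + offset + stats::rnorm(n_cells, 0, noise_sd)
  data.frame(cell = seq_len(n_cells), cb = cb, cp = cp)
}
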