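#' Estimate bleed-through coefficients from control stacks
#'
#' From cells expressing the donor alone, the fraction `alpha` of donor
#' emission contaminating the FRET channel is the slope of the
#' zero-intercept regression of FRET-channel on donor-channel intensity
#' over in-cell pixels; `beta` is estimated likewise from acceptor-only
#' cells. Control stacks must already be dark/shading/background corrected.
#'
#' @param donor_only,acceptor_only Preprocessed control [raw_stack()]s.
#' @param min_pixels Minimum number of in-cell pixels required per fit.
#' @return A list with `alpha`, `beta`, and the pixel counts used.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only, min_pixels = 500) {
  fit_one <- function(stack, signal_ch) {
    sig <- get_channel(stack, signal_ch)
    fr <- get_channel(stack, "fret")
    # In-cell pixels: Otsu split of the expressed channel, pooled over frames
    rng <- range(sig, na.rm = TRUE)
    if (diff(rng) <= 0) stop("control stack has no intensity contrast")
    u <- (sig - rng[1]) / diff(rng); u[is.na(u)] <- 0
    thr <- rng[1] + diff(rng) * EBImage::otsu(u, range = c(0, 1), levels = 256)
    sel <- !is.na(sig) & !is.na(fr) & sig > thr
    n <- sum(sel)
    if (n < min_pixels)
      stop(sprintf("only %d control pixels (need >= %d)", n, min_pixels))
    slope <- sum(fr[sel] * sig[sel]) / sum(sig[sel]^2)
    if (slope < 0 || slope >= 1)
      stop(sprintf("implausible bleed-through slope %.4f", slope))
    list(coef = slope, n = n)
  }
  a <- fit_one(donor_only, "donor")
  b <- fit_one(acceptor_only, "acceptor")
  list(alpha = a$coef, beta = b$coef, n_alpha = a$n, n_beta = b$n)
}

new_index_stack <- function(index, valid, kind) {
  structure(list(index = index, valid = valid, kind = kind,
                 photobleach_corrected = FALSE, bleach_fit = NULL),
            class = "index_stack")
}

#' @export
print.index_stack <- function(x, ...) {
  d <- dim(x$index)
  cat(sprintf("index_stack (%s): %d x %d px, %d frame(s); %s\n", x$kind,
              d[1], d[2], d[3],
              if (x$photobleach_corrected) "photobleach-corrected" else "uncorrected"))
  invisible(x)
}

#' Bleed-through-corrected FRET index
#'
#' Per-pixel RAC1 activity proxy
#' `R = (FRET - alpha * Donor - beta * Acceptor) / Donor`, where FRET,
#' Donor and Acceptor are the corrected channel intensities as measured and
#' `alpha`, `beta` the bleed-through fractions from single-fluorophore
#' controls. Pixels whose donor intensity falls below `eps_frac` times the
#' frame maximum are invalidated (ratio instability guard).
#'
#' @param fret_map,donor_map,acceptor_map `row x col x frame` arrays (or
#'   matrices for a single frame) of corrected intensities.
#' @param alpha,beta Bleed-through fractions in `[0, 1)`.
#' @param valid Optional prior validity array to intersect.
#' @param eps_frac Relative denominator guard.
#' @return An `index_stack` of kind `"fret"`.
#' @export
compute_fret_index <- function(fret_map, donor_map, acceptor_map,
                               alpha = 0, beta = 0, valid = NULL,
                               eps_frac = 1e-6) {
  as3 <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  fret_map <- as3(fret_map); donor_map <- as3(donor_map)
  acceptor_map <- as3(acceptor_map)
  if (!all(dim(fret_map) == dim(donor_map)) ||
      !all(dim(fret_map) == dim(acceptor_map)))
    stop("channel maps must share dimensions")
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1)
  nt <- dim(fret_map)[3]
  idx <- array(NA_real_, dim(fret_map))
  ok <- array(FALSE, dim(fret_map))
  for (t in seq_len(nt)) {
    d <- donor_map[, , t]
    eps <- eps_frac * max(d, na.rm = TRUE)
    good <- !is.na(d) & !is.na(fret_map[, , t]) & !is.na(acceptor_map[, , t]) &
      d > eps
    if (!is.null(valid)) good <- good & valid[, , t]
    r <- (fret_map[, , t] - alpha * d - beta * acceptor_map[, , t]) / d
    r[!good] <- NA_real_
    idx[, , t] <- r; ok[, , t] <- good
  }
  new_index_stack(idx, ok, "fret")
}

#' GEVAL GTP index
#'
#' Per-pixel free-GTP proxy: the ratio of GEVAL fluorescence excited at
#' 409 nm to that excited at 494 nm. Near-zero denominators are invalidated.
#'
#' @param ex409_map,ex494_map `row x col x frame` arrays (or matrices).
#' @inheritParams compute_fret_index
#' @return An `index_stack` of kind `"gtp"`.
#' @export
compute_gtp_index <- function(ex409_map, ex494_map, valid = NULL,
                              eps_frac = 1e-6) {
  as3 <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  ex409_map <- as3(ex409_map); ex494_map <- as3(ex494_map)
  if (!all(dim(ex409_map) == dim(ex494_map)))
    stop("channel maps must share dimensions")
  nt <- dim(ex409_map)[3]
  idx <- array(NA_real_, dim(ex409_map))
  ok <- array(FALSE, dim(ex409_map))
  for (t in seq_len(nt)) {
    den <- ex494_map[, , t]
    eps <- eps_frac * max(den, na.rm = TRUE)
    good <- !is.na(den) & !is.na(ex409_map[, , t]) & den > eps
    if (!is.null(valid)) good <- good & valid[, , t]
    r <- ex409_map[, , t] / den
    r[!good] <- NA_real_
    idx[, , t] <- r; ok[, , t] <- good
  }
  new_index_stack(idx, ok, "gtp")
}

# Double-exponential fit of a positive decaying series m(t); multi-start
# nonlinear least squares over log-spaced rate pairs, non-negative
# amplitudes and rates; returns NULL if everything fails.
fit_double_exponential <- function(tt, m) {
  best <- NULL
  grid <- 10^seq(-4, 0, length.out = 5)
  starts <- expand.grid(k1 = grid, k2 = grid)
  starts <- starts[starts$k1 >= starts$k2, ]
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        m ~ a1 * exp(-k1 * tt) + a2 * exp(-k2 * tt),
        start = list(a1 = m[1] / 2, a2 = m[1] / 2,
                     k1 = starts$k1[i], k2 = starts$k2[i]),
        lower = c(0, 0, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse, pars = stats::coef(fit),
                     model = "double")
    }
  }
  if (is.null(best)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(m ~ a1 * exp(-k1 * tt),
                        start = list(a1 = m[1], k1 = 0.01),
                        lower = c(0, 0)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      warning("double-exponential fit failed; using single exponential")
      p <- stats::coef(fit)
      best <- list(fit = fit, sse = sum(stats::resid(fit)^2),
                   pars = c(a1 = unname(p["a1"]), a2 = 0,
                            k1 = unname(p["k1"]), k2 = 0),
                   model = "single")
    }
  }
  best
}

#' Photobleach correction of an index stack
#'
#' Fits the whole-cell mean index per frame to a double exponential
#' `m(t) = a1 exp(-k1 t) + a2 exp(-k2 t)` and divides every frame by
#' `m(t)/m(0)`, flattening acquisition-long decay while leaving each
#' frame's spatial pattern untouched (the correction is a per-frame
#' scalar). A constant mean series short-circuits to the identity. If the
#' double-exponential fit fails, a single exponential is tried; if that
#' also fails the stack is returned uncorrected with a warning flag.
#'
#' @param index_stack An `index_stack`.
#' @param mask_stack Optional [segment_cells()] result restricting the
#'   whole-cell mean to in-mask pixels.
#' @param frame_interval Minutes between frames.
#' @return The corrected `index_stack` with `bleach_fit` recording the
#'   fitted parameters.
#' @export
photobleach_correct <- function(index_stack, mask_stack = NULL,
                                frame_interval = 1) {
  stopifnot(inherits(index_stack, "index_stack"))
  nt <- dim(index_stack$index)[3]
  if (nt < 6) stop("photobleach fit needs at least 6 frames (4 parameters)")
  tt <- (seq_len(nt) - 1) * frame_interval
  m <- vapply(seq_len(nt), function(t) {
    x <- index_stack$index[, , t]
    sel <- index_stack$valid[, , t]
    if (!is.null(mask_stack)) sel <- sel & mask_stack$mask[, , t]
    mean(x[sel], na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(m))) stop("whole-cell mean undefined on some frames")
  if (max(abs(m - m[1])) <= 1e-9 * abs(m[1])) {
    index_stack$photobleach_corrected <- TRUE
    index_stack$bleach_fit <- list(pars = c(a1 = m[1], a2 = 0, k1 = 0, k2 = 0),
                                   model = "constant", mean_series = m)
    return(index_stack)
  }
  best <- fit_double_exponential(tt, m)
  if (is.null(best)) {
    warning("photobleach fit failed; returning uncorrected stack")
    index_stack$bleach_fit <- list(model = "failed", mean_series = m)
    return(index_stack)
  }
  p <- best$pars
  curve <- p["a1"] * exp(-p["k1"] * tt) + p["a2"] * exp(-p["k2"] * tt)
  if (any(curve <= 0)) {
    warning("fitted bleach curve non-positive; returning uncorrected stack")
    index_stack$bleach_fit <- list(model = "failed", mean_series = m)
    return(index_stack)
  }
  for (t in seq_len(nt))
    index_stack$index[, , t] <- index_stack$index[, , t] / (curve[t] / curve[1])
  index_stack$photobleach_corrected <- TRUE
  index_stack$bleach_fit <- list(pars = p, model = best$model,
                                 mean_series = m, curve = curve)
  index_stack
}

#' Display scale bounds for pseudocolor rendering
#'
#' Returns the 5th/95th percentile bounds of the valid index values
#' (discarding the lowest and highest 5% to suppress spurious pixels),
#' shifted so the lower bound maps to 1. For GEVAL rendering the lower
#' bound is taken from the GTP-insensitive null-sensor stack when supplied.
#' Rendering-only: these bounds never feed back into statistics.
#'
#' @param index_stack An `index_stack`.
#' @param low_q,high_q Percentile bounds (defaults 0.05 and 0.95).
#' @param null_stack Optional null-sensor `index_stack` supplying the lower
#'   percentile.
#' @return A list with raw percentiles `lo` and `hi`, the additive `offset`
#'   mapping `lo` to 1, shifted `bounds`, and a `degenerate` flag when
#'   `lo == hi`.
#' @export
display_scale <- function(index_stack, low_q = 0.05, high_q = 0.95,
                          null_stack = NULL) {
  vals <- index_stack$index[index_stack$valid]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 100) stop("need at least 100 valid pixels")
  lo_src <- if (is.null(null_stack)) vals else {
    nv <- null_stack$index[null_stack$valid]
    nv[is.finite(nv)]
  }
  lo <- unname(stats::quantile(lo_src, low_q, type = 7))
  hi <- unname(stats::quantile(vals, high_q, type = 7))
  degenerate <- isTRUE(all.equal(lo, hi))
  offset <- 1 - lo
  list(lo = lo, hi = hi, offset = offset,
       bounds = c(1, hi + offset), degenerate = degenerate)
}
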