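#' Subtract per-channel dark frames
#'
#' Removes the camera's dark current: for each channel the dark frame
#' (acquired without excitation) is subtracted pixel-wise from every frame.
#' Negative results are clipped to zero for downstream ratio stability.
#'
#' @param stack A [raw_stack()].
#' @param bundle A [correction_bundle()] with a `dark` entry per channel.
#' @return The corrected stack.
#' @export
subtract_dark <- function(stack, bundle) {
  stopifnot(inherits(stack, "raw_stack"), inherits(bundle, "correction_bundle"))
  assert_step_order(stack, "dark",
                    must_precede = c("shading", "background", "register"))
  missing <- setdiff(stack$channels, names(bundle$dark))
  if (length(missing))
    stop("no dark frame for channel(s): ", paste(missing, collapse = ", "))
  for (ch in stack$channels) {
    d <- bundle$dark[[ch]]
    stopifnot(all(dim(d) == dim(stack$data)[1:2]))
    stack$data[, , ch, ] <- pmax(stack$data[, , ch, ] - as.vector(d), 0)
  }
  mark_step(stack, "dark")
}

#' Divide by per-channel shading references
#'
#' Corrects uneven illumination: each channel is divided pixel-wise by its
#' unit-mean reference image (from a uniform dye solution imaged under the
#' same conditions). A stack can only be shading-corrected once.
#'
#' @inheritParams subtract_dark
#' @return The corrected stack.
#' @export
shading_correct <- function(stack, bundle) {
  stopifnot(inherits(stack, "raw_stack"), inherits(bundle, "correction_bundle"))
  assert_step_order(stack, "shading", must_precede = c("background", "register"))
  missing <- setdiff(stack$channels, names(bundle$shading))
  if (length(missing))
    stop("no shading reference for channel(s): ", paste(missing, collapse = ", "))
  for (ch in stack$channels) {
    s <- bundle$shading[[ch]]
    if (any(s == 0)) stop("shading reference contains zeros")
    stack$data[, , ch, ] <- stack$data[, , ch, ] / as.vector(s)
  }
  mark_step(stack, "shading")
}

#' Least-squares affine from fiducial bead coordinates
#'
#' Estimates the 2x3 affine `dst ~ M %*% c(src, 1)` mapping one camera's
#' coordinates onto the reference frame from matched bead positions.
#'
#' @param points_src,points_dst n x 2 matrices of matched `(row, col)`
#'   coordinates, n >= 3 and not collinear.
#' @return A list of class `affine_transform` with the 2x3 `matrix` and the
#'   per-point RMS `residual`.
#' @export
estimate_affine_from_fiducials <- function(points_src, points_dst) {
  points_src <- as.matrix(points_src); points_dst <- as.matrix(points_dst)
  stopifnot(ncol(points_src) == 2, ncol(points_dst) == 2,
            nrow(points_src) == nrow(points_dst))
  if (nrow(points_src) < 3) stop("need at least 3 fiducial pairs")
  X <- cbind(points_src, 1)
  if (qr(X)$rank < 3) stop("fiducial points are collinear")
  B <- qr.solve(X, points_dst)           # 3 x 2
  M <- t(B)                              # 2 x 3
  fit <- X %*% B
  res <- sqrt(mean((fit - points_dst)^2))
  if (abs(det(M[, 1:2])) < 1e-12) stop("estimated affine is singular")
  structure(list(matrix = M, residual = res), class = "affine_transform")
}

#' Resample channels through an affine transform
#'
#' Warps the given channels onto the reference frame by inverse-mapped
#' bilinear resampling: output pixel `x` takes the value of the input at
#' `M^{-1}(x)`. Pixels mapping outside the input are set to `NA` and are
#' treated as invalid downstream. An identity transform is a no-op.
#'
#' @param stack A [raw_stack()].
#' @param transform An `affine_transform` (or bare 2x3 matrix).
#' @param channels Channels to warp (default: the GEVAL pair present).
#' @return The registered stack.
#' @export
apply_affine <- function(stack, transform,
                         channels = intersect(c("ex409", "ex494"), stack$channels)) {
  stopifnot(inherits(stack, "raw_stack"))
  M <- if (inherits(transform, "affine_transform")) transform$matrix else transform
  stopifnot(is.matrix(M), all(dim(M) == c(2, 3)))
  assert_step_order(stack, "register", must_precede = "background")
  if (!is_identity_affine(M, tol = 1e-9)) {
    Alin <- M[, 1:2]; off <- M[, 3]
    if (abs(det(Alin)) < 1e-12) stop("affine transform is singular")
    nr <- dim(stack$data)[1]; nc <- dim(stack$data)[2]
    x_r <- rep(seq_len(nr), nc)
    x_c <- rep(seq_len(nc), each = nr)
    uv <- solve(Alin, rbind(x_r - off[1], x_c - off[2]))
    for (ch in channels) for (t in seq_len(n_frames(stack))) {
      img <- stack$data[, , ch, t]
      stack$data[, , ch, t] <- matrix(bilinear_sample(img, uv[1, ], uv[2, ]),
                                      nr, nc)
    }
  }
  mark_step(stack, "register")
}

#' Subtract per-frame background levels
#'
#' Removes residual background fluorescence: for every frame and channel the
#' mean intensity of a cell-free region is subtracted from the whole frame.
#' The region's per-frame standard deviation is also recorded; it defines
#' the "background range" used by [background_range_mask()].
#'
#' @inheritParams subtract_dark
#' @param mask Optional cell mask; a warning is issued (and the subtraction
#'   proceeds) if the region overlaps it.
#' @return A list with the corrected `stack` and `levels`, a data.frame of
#'   `frame`, `channel`, `level`, `sd`.
#' @export
subtract_background <- function(stack, bundle, mask = NULL) {
  stopifnot(inherits(stack, "raw_stack"), inherits(bundle, "correction_bundle"))
  assert_step_order(stack, "background")
  reg <- bundle$background_region
  if (is.null(reg)) stop("bundle has no background region")
  if (length(reg$rows) * length(reg$cols) < 25)
    stop("background region must contain at least 25 pixels")
  if (!is.null(mask) && any(mask[reg$rows, reg$cols]))
    warning("background region overlaps the cell mask; proceeding")
  nt <- n_frames(stack)
  levels <- expand.grid(frame = seq_len(nt), channel = stack$channels,
                        stringsAsFactors = FALSE)
  levels$level <- NA_real_; levels$sd <- NA_real_
  for (ch in stack$channels) for (t in seq_len(nt)) {
    px <- stack$data[reg$rows, reg$cols, ch, t]
    lv <- mean(px, na.rm = TRUE); sdv <- stats::sd(px, na.rm = TRUE)
    stack$data[, , ch, t] <- stack$data[, , ch, t] - lv
    i <- which(levels$frame == t & levels$channel == ch)
    levels$level[i] <- lv; levels$sd[i] <- sdv
  }
  list(stack = mark_step(stack, "background"), levels = levels)
}

# Edge-truncated running median used to smooth the per-frame Otsu
# threshold series (odd window).
running_median <- function(x, window = 5L) {
  h <- window %/% 2L
  vapply(seq_along(x), function(i)
    stats::median(x[max(1L, i - h):min(length(x), i + h)]), numeric(1))
}

#' Segment the cell from the donor channel
#'
#' Per-frame Otsu thresholding of the donor channel (the channel with the
#' best signal-to-noise at the cell edge), optional temporal median
#' smoothing of the threshold series, and retention of the largest
#' connected component per frame. Degenerate (constant) frames yield an
#' empty mask with a warning.
#'
#' @param stack A [raw_stack()] containing a `donor` channel.
#' @param smooth_window Odd temporal window for threshold smoothing; `0` or
#'   `1` disables smoothing.
#' @return A list of class `mask_stack`: `mask` (`row x col x frame` logical
#'   array) and `threshold` (per-frame values actually applied).
#' @export
segment_cells <- function(stack, smooth_window = 5L) {
  stopifnot(inherits(stack, "raw_stack"))
  if (!"donor" %in% stack$channels) stop("donor channel required for segmentation")
  donor <- get_channel(stack, "donor")
  nt <- dim(donor)[3]
  thr <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    fr <- donor[, , t]
    rng <- range(fr, na.rm = TRUE)
    if (diff(rng) <= 0) { thr[t] <- NA_real_; next }
    u <- (fr - rng[1]) / diff(rng)
    u[is.na(u)] <- 0
    thr[t] <- rng[1] + diff(rng) * EBImage::otsu(u, range = c(0, 1), levels = 256)
  }
  if (smooth_window >= 3L && nt >= 2L) {
    ok <- !is.na(thr)
    if (any(ok)) thr[ok] <- running_median(thr[ok], smooth_window)
  }
  mask <- array(FALSE, dim(donor))
  for (t in seq_len(nt)) {
    if (is.na(thr[t])) {
      warning(sprintf("frame %d is constant; empty mask", t))
      next
    }
    bw <- donor[, , t] > thr[t]
    bw[is.na(bw)] <- FALSE
    if (!any(bw)) { warning(sprintf("frame %d: empty mask", t)); next }
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    mask[, , t] <- as.integer(lab) == which.max(tab)
  }
  structure(list(mask = mask, threshold = thr), class = "mask_stack")
}

#' Per-pixel validity from the background range
#'
#' A pixel is retained only if, in *every* channel, its intensity exceeds
#' that channel's background level plus `k` background standard deviations;
#' failing the range in any single channel excludes the pixel (ratios are
#' numerically unstable where any fluorophore is near background).
#'
#' @param stack A background-subtracted [raw_stack()].
#' @param background_levels The `levels` data.frame from
#'   [subtract_background()].
#' @param k Number of background standard deviations above the (subtracted,
#'   hence zero) background level a pixel must exceed.
#' @return Logical `row x col x frame` validity array.
#' @export
background_range_mask <- function(stack, background_levels, k = 2) {
  stopifnot(inherits(stack, "raw_stack"), k >= 0)
  nt <- n_frames(stack)
  d <- dim(stack$data)
  valid <- array(TRUE, c(d[1], d[2], nt))
  for (ch in stack$channels) for (t in seq_len(nt)) {
    i <- which(background_levels$frame == t & background_levels$channel == ch)
    cutoff <- k * background_levels$sd[i]   # levels already subtracted
    x <- stack$data[, , ch, t]
    valid[, , t] <- valid[, , t] & !is.na(x) & (x > cutoff)
  }
  valid
}
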