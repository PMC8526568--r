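# Canonical channel order for five-channel acquisitions: three channels for
# the FRET-based RAC1 biosensor and two excitations for the GEVAL GTP sensor.
CHANNELS <- c("donor", "fret", "acceptor", "ex409", "ex494")

#' Construct a multi-channel time-lapse stack
#'
#' Thin container for a `row x col x channel x frame` intensity array with
#' channel-role metadata. Channel roles must be unique and drawn from
#' `donor`, `fret`, `acceptor`, `ex409`, `ex494` (any subset).
#'
#' @param data Numeric 4-D array, dims `(row, col, channel, frame)`.
#' @param channels Character vector of channel roles, one per slice.
#' @param frame_interval Frame spacing in minutes (default 1).
#' @return An object of class `raw_stack`.
#' @export
raw_stack <- function(data, channels = CHANNELS, frame_interval = 1) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            dim(data)[3] == length(channels),
            !anyDuplicated(channels), all(channels %in% CHANNELS),
            dim(data)[4] >= 1L, frame_interval > 0)
  dimnames(data) <- list(NULL, NULL, channels, NULL)
  structure(list(data = data, channels = channels,
                 frame_interval = frame_interval),
            class = "raw_stack", steps = character(0))
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("raw_stack: %d x %d px, %d channel(s) [%s], %d frame(s), dt = %g min\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "), d[4],
              x$frame_interval))
  st <- attr(x, "steps")
  if (length(st)) cat("  corrections applied:", paste(st, collapse = " -> "), "\n")
  invisible(x)
}

#' Extract one channel as a `row x col x frame` array
#' @param stack A [raw_stack()].
#' @param channel Channel role name.
#' @return 3-D numeric array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "raw_stack"), channel %in% stack$channels)
  a <- stack$data[, , channel, , drop = FALSE]
  dim(a) <- dim(stack$data)[c(1, 2, 4)]
  a
}

#' Number of frames in a stack
#' @param stack A [raw_stack()].
#' @export
n_frames <- function(stack) dim(stack$data)[4]

# Record that a correction step ran; steps are consulted to forbid repeats
# and out-of-order application.
mark_step <- function(stack, step) {
  attr(stack, "steps") <- c(attr(stack, "steps"), step)
  stack
}

assert_step_order <- function(stack, step, forbid_repeat = TRUE,
                              must_precede = character(0)) {
  steps <- attr(stack, "steps")
  if (forbid_repeat && step %in% steps)
    stop(sprintf("correction '%s' already applied to this stack", step))
  bad <- intersect(must_precede, steps)
  if (length(bad))
    stop(sprintf("correction '%s' must be applied before %s", step,
                 paste(sQuote(bad), collapse = ", ")))
  invisible(TRUE)
}

#' Bundle of correction assets for one acquisition session
#'
#' Holds the auxiliary measurements the correction chain consumes: per-channel
#' dark frames (acquired without excitation), per-channel unit-mean shading
#' references (uniform dye solution), a cell-free background region,
#' donor-only / acceptor-only control stacks for bleed-through estimation, and
#' fiducial bead coordinates relating the GEVAL camera to the reference frame.
#'
#' @param dark Named list of dark frames (matrices), one per channel.
#' @param shading Named list of strictly positive mean-1 reference matrices.
#' @param background_region List with `rows` and `cols` index vectors.
#' @param alpha,beta Optional known bleed-through fractions in `[0, 1)`.
#' @param fiducials Optional list with `src` and `dst` n x 2 matrices of
#'   matched bead coordinates (rows = points, cols = row/col position);
#'   `src` in the frame to be warped, `dst` in the reference frame.
#' @param donor_only,acceptor_only Optional [raw_stack()] control stacks.
#' @return An object of class `correction_bundle`.
#' @export
correction_bundle <- function(dark = NULL, shading = NULL,
                              background_region = NULL,
                              alpha = NULL, beta = NULL, fiducials = NULL,
                              donor_only = NULL, acceptor_only = NULL) {
  if (!is.null(shading)) {
    for (nm in names(shading)) {
      s <- shading[[nm]]
      if (any(s <= 0)) stop("shading reference contains non-positive values")
      if (abs(mean(s) - 1) > 1e-6)
        stop(sprintf("shading reference '%s' must have mean 1 (found %.8f)",
                     nm, mean(s)))
    }
  }
  for (v in c(alpha, beta))
    if (!is.null(v) && (v < 0 || v >= 1))
      stop("bleed-through fractions must lie in [0, 1)")
  structure(list(dark = dark, shading = shading,
                 background_region = background_region,
                 alpha = alpha, beta = beta, fiducials = fiducials,
                 donor_only = donor_only, acceptor_only = acceptor_only),
            class = "correction_bundle")
}
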