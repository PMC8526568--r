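#' Pixel-wise Pearson correlation for one frame
#'
#' Sample Pearson correlation between the FRET index and GTP index over the
#' jointly valid pixels of one image. Frames with fewer than `min_pixels`
#' valid pixels, or with zero variance in either index, are skipped.
#'
#' @param x,y Numeric matrices (index maps for one frame).
#' @param valid Optional logical matrix; pixels must additionally be
#'   non-`NA` in both maps.
#' @param min_pixels Minimum joint pixel count.
#' @return A list with `r`, `n`, and `retained` (FALSE when skipped, with a
#'   warning).
#' @export
framewise_pearson <- function(x, y, valid = NULL, min_pixels = 100) {
  stopifnot(all(dim(x) == dim(y)))
  sel <- !is.na(x) & !is.na(y)
  if (!is.null(valid)) sel <- sel & valid
  n <- sum(sel)
  if (n < min_pixels) {
    warning(sprintf("frame skipped: %d valid pixels < %d", n, min_pixels))
    return(list(r = NA_real_, n = n, retained = FALSE))
  }
  xs <- x[sel]; ys <- y[sel]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    warning("frame skipped: zero variance in an index")
    return(list(r = NA_real_, n = n, retained = FALSE))
  }
  list(r = stats::cor(xs, ys), n = n, retained = TRUE)
}

#' Per-frame correlation series for a cell
#'
#' Applies [framewise_pearson()] to every frame of a pair of index stacks.
#'
#' @param fret_stack,gtp_stack `index_stack`s of equal dimensions.
#' @param min_pixels Minimum joint pixel count per frame.
#' @return A data.frame with `frame`, `r`, `n`, `retained`.
#' @export
correlation_series <- function(fret_stack, gtp_stack, min_pixels = 100) {
  stopifnot(inherits(fret_stack, "index_stack"),
            inherits(gtp_stack, "index_stack"),
            all(dim(fret_stack$index) == dim(gtp_stack$index)))
  nt <- dim(fret_stack$index)[3]
  out <- data.frame(frame = seq_len(nt), r = NA_real_, n = NA_integer_,
                    retained = FALSE)
  for (t in seq_len(nt)) {
    res <- suppressWarnings(framewise_pearson(
      fret_stack$index[, , t], gtp_stack$index[, , t],
      valid = fret_stack$valid[, , t] & gtp_stack$valid[, , t],
      min_pixels = min_pixels))
    out$r[t] <- res$r; out$n[t] <- res$n; out$retained[t] <- res$retained
  }
  out
}

#' Summarize a cell's per-frame correlation series
#'
#' Mean, median and quartile bounds of the retained per-frame Pearson r
#' values — the per-cell quantities drawn as bar-and-whiskers (whiskers:
#' first and fourth quartiles; the median splits the bar). Records with
#' fewer than 5 retained frames are flagged insufficient.
#'
#' @param series Data.frame from [correlation_series()] (columns `r`,
#'   `retained`), or a numeric vector of per-frame r values.
#' @return A list of class `cell_correlation_record`.
#' @export
summarize_cell <- function(series) {
  if (is.numeric(series)) series <- data.frame(r = series, retained = !is.na(series))
  r <- series$r[series$retained]
  insufficient <- length(r) < 5
  q <- if (length(r)) unname(stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), type = 7))
       else rep(NA_real_, 5)
  structure(list(r_values = r, n_frames = length(r),
                 mean_r = if (length(r)) mean(r) else NA_real_,
                 median_r = q[3], quartiles = q,
                 insufficient = insufficient),
            class = "cell_correlation_record")
}

#' @export
print.cell_correlation_record <- function(x, ...) {
  cat(sprintf("cell correlation: %d frames, mean r = %.3f, median = %.3f [Q1 %.3f, Q3 %.3f]%s\n",
              x$n_frames, x$mean_r, x$median_r, x$quartiles[2], x$quartiles[4],
              if (x$insufficient) " (insufficient frames)" else ""))
  invisible(x)
}

new_group_comparison <- function(test, statistic, p, n, estimates = NULL,
                                 flag = NULL, extra = NULL) {
  structure(c(list(test = test, statistic = statistic, p = p, n = n,
                   estimates = estimates, flag = flag), extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, two-sided p = %s (n = %s)%s\n", x$test,
              format(x$statistic, digits = 4), format(x$p, digits = 4),
              paste(x$n, collapse = ", "),
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small samples (both
#' n <= 8) the permutation distribution of U is enumerated exactly over all
#' arrangements, using mid-ranks so ties are handled; the two-sided p is
#' twice the smaller tail, capped at 1. For larger samples the
#' tie-corrected normal approximation is used.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param exact_max Largest per-group size for exact enumeration.
#' @return A `group_comparison` (statistic = U of sample `a`).
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)                  # mid-ranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    base <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(rk[combs], nrow = n1)) - base
    tol <- 1e-9
    p <- 2 * min(mean(Us <= U + tol), mean(Us >= U - tol))
    p <- min(1, p)
    method <- "mann-whitney (exact)"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      return(new_group_comparison("mann-whitney (normal approx.)", U, NA_real_,
                                  c(n1, n2), flag = "all values tied"))
    }
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "mann-whitney (normal approx.)"
  }
  new_group_comparison(method, U, p, c(n1, n2),
                       estimates = c(median_a = stats::median(a),
                                     median_b = stats::median(b)))
}

#' Two-tailed paired Student's t-test
#'
#' Wraps [stats::t.test()] on the paired differences; zero-variance
#' differences yield a flagged record instead of an error.
#'
#' @param cb_values,cp_values Equal-length paired samples (n >= 2).
#' @return A `group_comparison`.
#' @export
paired_t <- function(cb_values, cp_values) {
  if (length(cb_values) != length(cp_values))
    stop("paired samples must have equal length")
  stopifnot(length(cb_values) >= 2)
  d <- cp_values - cb_values
  if (stats::sd(d) == 0)
    return(new_group_comparison("paired t", NA_real_, NA_real_,
                                length(d), estimates = c(mean_diff = mean(d)),
                                flag = "zero-variance differences"))
  ht <- stats::t.test(cp_values, cb_values, paired = TRUE)
  new_group_comparison("paired t", unname(ht$statistic), ht$p.value,
                       length(d),
                       estimates = c(mean_diff = unname(ht$estimate)),
                       extra = list(df = unname(ht$parameter)))
}

#' Two-tailed unpaired (Welch) t-test
#'
#' Welch's unequal-variance variant of the two-sample Student's t-test.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A `group_comparison`.
#' @export
unpaired_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(new_group_comparison("unpaired t (Welch)", NA_real_, NA_real_,
                                c(length(a), length(b)),
                                flag = "zero variance in both samples"))
  ht <- stats::t.test(a, b, var.equal = FALSE)
  new_group_comparison("unpaired t (Welch)", unname(ht$statistic), ht$p.value,
                       c(length(a), length(b)),
                       estimates = c(mean_a = unname(ht$estimate[1]),
                                     mean_b = unname(ht$estimate[2])),
                       extra = list(df = unname(ht$parameter)))
}
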