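#' Ratiometric GTP sensor model
#'
#' Saturating single-site response of a GEVAL-class ratiometric sensor of
#' free GTP. `keff` is the ligand concentration producing 50% of the maximal
#' ratiometric signal; GEVAL30 has an in vitro Keff of 32.3 µM, responds from
#' about 4 µM and saturates near 100 µM. A "null" variant cannot bind GTP and
#' returns its zero-ligand ratio at any concentration (negative control).
#'
#' @param keff Half-maximal concentration in µM (must be > 0).
#' @param r_min Ratio at zero ligand (dimensionless, > 0).
#' @param r_max Ratio at saturation (> `r_min`).
#' @param hill Hill coefficient; 1 gives the single-site hyperbola.
#' @param is_null If `TRUE` the sensor ignores its ligand.
#' @return An object of class `sensor_model`.
#' @examples
#' geval30 <- sensor_model(keff = 32.3)
#' sensor_response(geval30, 32.3) # exactly (r_min + r_max) / 2
#' @export
sensor_model <- function(keff = 32.3, r_min = 1, r_max = 3, hill = 1,
                         is_null = FALSE) {
  stopifnot(is.numeric(keff), length(keff) == 1L, is.finite(keff), keff > 0,
            is.finite(r_min), is.finite(r_max), r_min > 0, r_max > r_min,
            is.finite(hill), hill > 0)
  structure(list(keff = keff, r_min = r_min, r_max = r_max, hill = hill,
                 is_null = isTRUE(is_null)),
            class = "sensor_model")
}

#' Sensor ratio at a given GTP concentration
#'
#' For a responsive sensor the ratio is
#' `r_min + (r_max - r_min) * c^h / (keff^h + c^h)`, a monotone saturating
#' curve through `(r_min + r_max)/2` at `c = keff`. Null sensors return
#' `r_min` for all concentrations.
#'
#' @param model A [sensor_model()].
#' @param conc GTP concentration(s) in µM, all >= 0 (Inf allowed).
#' @return Ratio value(s), same length as `conc`.
#' @export
sensor_response <- function(model, conc) {
  stopifnot(inherits(model, "sensor_model"), is.numeric(conc))
  if (any(conc < 0, na.rm = TRUE))
    stop("concentration must be non-negative")
  if (model$is_null) return(rep(model$r_min, length(conc)))
  ch <- conc^model$hill
  r <- model$r_min + (model$r_max - model$r_min) * ch / (model$keff^model$hill + ch)
  r[is.infinite(conc)] <- model$r_max
  r
}

#' Invert a sensor response numerically
#'
#' Finds the concentration at which the sensor produces `ratio`, by root
#' bracketing on the monotone response curve. Used, e.g., to confirm that the
#' half-maximal signal sits at `keff`.
#'
#' @param model A non-null [sensor_model()].
#' @param ratio Target ratio strictly between `r_min` and `r_max`.
#' @param upper Upper bracket for the search in µM.
#' @return Concentration in µM.
#' @export
sensor_inverse <- function(model, ratio, upper = 1e6) {
  stopifnot(inherits(model, "sensor_model"), !model$is_null,
            ratio > model$r_min, ratio < model$r_max)
  stats::uniroot(function(c) sensor_response(model, c) - ratio,
                 lower = 0, upper = upper, tol = 1e-12)$root
}
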