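#' Construct a surface-quenching model
#'
#' The attenuation of a fluorophore a distance \eqn{d} above an absorbing
#' surface (here a graphene-oxide monolayer) follows a fourth-power law,
#' \deqn{I/I_0 = \frac{d^4}{d^4 + d_0^4},}
#' where \eqn{I_0} is the unquenched intensity and \eqn{d_0} the
#' characteristic quenching distance at which exactly half the intensity
#' remains. The exponent is fixed at 4 (point-to-plane coupling).
#'
#' @param d0 Characteristic quenching distance in nm (half-intensity
#'   distance). Must be positive. For GO monolayers a typical value is
#'   around 4 nm.
#' @param i0 Unquenched (free-fluorophore) intensity in arbitrary units.
#' @param d0_sd Optional standard deviation of `d0` in nm (filled in by
#'   [calibrate_d0()]).
#' @return An object of class `quench_model` with fields `d0`, `i0`,
#'   `exponent` (always 4) and `d0_sd`.
#' @examples
#' qm <- quench_model(d0 = 4)
#' relative_intensity(4, qm)   # exactly 0.5
#' @export
quench_model <- function(d0, i0 = 1, d0_sd = NA_real_) {
  stopifnot(is.numeric(d0), length(d0) == 1L, is.finite(d0), d0 > 0,
            is.numeric(i0), length(i0) == 1L, is.finite(i0), i0 > 0)
  structure(
    list(d0 = as.numeric(d0), i0 = as.numeric(i0), exponent = 4L,
         d0_sd = as.numeric(d0_sd)),
    class = "quench_model"
  )
}

#' @export
print.quench_model <- function(x, ...) {
  cat("Surface quenching model (d^-4 law)\n")
  if (is.finite(x$d0_sd)) {
    cat(sprintf("  d0: %.3g +/- %.2g nm\n", x$d0, x$d0_sd))
  } else {
    cat(sprintf("  d0: %.3g nm\n", x$d0))
  }
  cat(sprintf("  I0: %.4g a.u.\n", x$i0))
  rng <- sensitive_range(x)
  cat(sprintf("  sensitive range: %.2f - %.2f nm\n", rng[1], rng[2]))
  invisible(x)
}

#' Relative intensity at a given height above the quencher
#'
#' Evaluates \eqn{I/I_0 = d^4 / (d^4 + d_0^4)}: the fraction of the
#' unquenched intensity a fluorophore emits at height `d` above the surface.
#' Strictly increasing in `d`, tending to 0 at the surface and 1 far away;
#' equals 1/2 exactly at `d = d0`.
#'
#' @param d Height(s) above the surface, nm. All values must be positive.
#' @param model A [quench_model()].
#' @return Relative intensity in (0, 1), same length as `d`.
#' @export
relative_intensity <- function(d, model) {
  stopifnot(inherits(model, "quench_model"), is.numeric(d))
  if (any(!is.finite(d) | d <= 0)) {
    stop("relative_intensity: heights must be positive and finite", call. = FALSE)
  }
  d4 <- d^4
  d4 / (d4 + model$d0^4)
}

#' Invert the quenching law: relative intensity to height
#'
#' Exact inverse of [relative_intensity()]:
#' \eqn{d = d_0 \, (r / (1 - r))^{1/4}} for relative intensity `r`.
#' Values at or below 0 correspond to the blind region (indistinguishable
#' from background) and values at or above 1 to saturation; both are domain
#' errors here — callers that must handle them clamp or flag first (see
#' [trace_to_positions()]).
#'
#' @param rel_i Relative intensity values, strictly inside (0, 1).
#' @param model A [quench_model()].
#' @return Heights above the surface in nm.
#' @export
invert_intensity <- function(rel_i, model) {
  stopifnot(inherits(model, "quench_model"), is.numeric(rel_i))
  if (any(!is.finite(rel_i) | rel_i <= 0 | rel_i >= 1)) {
    stop("invert_intensity: relative intensity must lie strictly in (0, 1); ",
         "values outside are blind-region or saturated and must be clamped ",
         "or flagged by the caller", call. = FALSE)
  }
  model$d0 * (rel_i / (1 - rel_i))^0.25
}

#' Height from a measured intensity via a reference layer
#'
#' Converts a measured intensity to a height above the quencher without an
#' explicit \eqn{d_0}, using a reference point (a layer of known thickness
#' `ref_distance` whose measured intensity is `ref_intensity`):
#' \deqn{d = d^{*} \left[ \frac{I/(I_0 - I)}{I^{*}/(I_0 - I^{*})} \right]^{1/4}.}
#' Algebraically this equals [invert_intensity()] under the \eqn{d_0}
#' implied by the reference; eliminating \eqn{d_0} reflects that the method
#' measures relative, not absolute, position.
#'
#' @param intensity Measured intensity, a.u.; must satisfy 0 < intensity < i0.
#' @param ref_intensity Reference-layer intensity, a.u., also in (0, i0).
#' @param ref_distance Reference-layer thickness (fluorophore height), nm.
#' @param i0 Unquenched intensity, a.u.
#' @return Height in nm.
#' @export
relative_depth <- function(intensity, ref_intensity, ref_distance, i0) {
  stopifnot(is.numeric(intensity), is.numeric(ref_intensity),
            length(ref_intensity) == 1L, length(ref_distance) == 1L,
            length(i0) == 1L, i0 > 0, ref_distance > 0)
  if (any(intensity >= i0)) {
    stop("relative_depth: intensity at or above I0 (saturation)", call. = FALSE)
  }
  if (any(intensity <= 0)) {
    stop("relative_depth: non-positive intensity is in the blind region; ",
         "flag it upstream", call. = FALSE)
  }
  if (ref_intensity <= 0 || ref_intensity >= i0) {
    stop("relative_depth: reference intensity must lie in (0, I0)", call. = FALSE)
  }
  odds     <- intensity / (i0 - intensity)
  ref_odds <- ref_intensity / (i0 - ref_intensity)
  ref_distance * (odds / ref_odds)^0.25
}

#' A reference layer for d0 calibration
#'
#' A layer of known thickness whose relative intensity has been measured,
#' e.g. a supported lipid bilayer (~4.1 nm) or a BSA monolayer (~3.3 nm)
#' on the GO surface. A quartz-supported control with relative intensity 1
#' is the I0 normaliser, not an admissible reference here.
#'
#' @param name Label for the layer.
#' @param thickness Fluorophore height above the quencher, nm (> 0).
#' @param rel_intensity Measured I/I0, strictly in (0, 1).
#' @param rel_intensity_sd Standard deviation of `rel_intensity` (fraction).
#' @return An object of class `reference_layer`.
#' @export
reference_layer <- function(name, thickness, rel_intensity,
                            rel_intensity_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(thickness), thickness > 0,
            is.numeric(rel_intensity),
            is.numeric(rel_intensity_sd), rel_intensity_sd >= 0)
  if (rel_intensity <= 0 || rel_intensity >= 1) {
    stop("reference_layer: rel_intensity must lie strictly in (0, 1)",
         call. = FALSE)
  }
  structure(
    list(name = name, thickness = as.numeric(thickness),
         rel_intensity = as.numeric(rel_intensity),
         rel_intensity_sd = as.numeric(rel_intensity_sd)),
    class = "reference_layer"
  )
}

#' Calibrate the characteristic quenching distance from reference layers
#'
#' Each reference layer of thickness \eqn{t} with measured relative
#' intensity \eqn{r} pins the quenching distance through the inverted law
#' \eqn{d_0 = t \, ((1 - r)/r)^{1/4}}. The point estimate is the unweighted
#' mean of the per-reference solutions. The reported uncertainty is the
#' larger of (a) first-order (delta-method) propagation of the intensity
#' standard deviations through the inversion, combined across references,
#' and (b) the empirical spread (sd) of the per-reference solutions.
#'
#' @param references A list of [reference_layer()] objects (at least one),
#'   or a single `reference_layer`.
#' @param i0 Unquenched intensity, a.u.; carried into the returned model.
#' @return A [quench_model()] with `d0`, `d0_sd` and an extra attribute
#'   `"per_reference"`: a data frame of per-layer solutions.
#' @examples
#' refs <- list(
#'   reference_layer("bilayer", 4.1, 0.48, 0.06),
#'   reference_layer("BSA",     3.3, 0.31, 0.06)
#' )
#' calibrate_d0(refs)
#' @export
calibrate_d0 <- function(references, i0 = 1) {
  if (inherits(references, "reference_layer")) references <- list(references)
  stopifnot(is.list(references))
  if (length(references) == 0L) {
    stop("calibrate_d0: at least one reference layer is required", call. = FALSE)
  }
  ok <- vapply(references, inherits, logical(1), "reference_layer")
  if (!all(ok)) stop("calibrate_d0: references must be reference_layer objects",
                     call. = FALSE)

  t  <- vapply(references, `[[`, numeric(1), "thickness")
  r  <- vapply(references, `[[`, numeric(1), "rel_intensity")
  sr <- vapply(references, `[[`, numeric(1), "rel_intensity_sd")

  d0_i <- t * ((1 - r) / r)^0.25
  # delta method: |d d0 / d r| = d0 / (4 r (1 - r))
  sd_i <- d0_i * sr / (4 * r * (1 - r))
  d0_hat <- mean(d0_i)
  prop_sd <- sqrt(sum(sd_i^2)) / length(d0_i)
  spread_sd <- if (length(d0_i) > 1L) stats::sd(d0_i) else 0
  d0_sd <- max(prop_sd, spread_sd)

  model <- quench_model(d0 = d0_hat, i0 = i0, d0_sd = d0_sd)
  attr(model, "per_reference") <- data.frame(
    name = vapply(references, `[[`, character(1), "name"),
    thickness_nm = t, rel_intensity = r,
    d0_nm = d0_i, d0_sd_nm = sd_i,
    stringsAsFactors = FALSE
  )
  model
}

#' Sensitive range of the quenching ruler
#'
#' The method resolves distance changes only where the attenuation curve is
#' steep: between 0.5 d0 and 1.7 d0. Below the lower edge the dye is close
#' to the blind region; above the upper edge the curve saturates.
#'
#' @param model A [quench_model()].
#' @return Numeric vector `c(lower, upper)` in nm.
#' @export
sensitive_range <- function(model) {
  stopifnot(inherits(model, "quench_model"))
  c(lower = 0.5 * model$d0, upper = 1.7 * model$d0)
}

#' Read a calibration input JSON and run the calibration
#'
#' The JSON layout is
#' `{"references": [{"name", "thickness_nm", "rel_intensity",
#' "rel_intensity_sd"}], "i0": <number>}`. The output JSON (if `out` is
#' given) repeats the input and adds `"d0_nm"` and `"d0_sd_nm"`.
#'
#' @param path Input JSON file.
#' @param out Optional output JSON path.
#' @return The calibrated [quench_model()], invisibly if `out` is given.
#' @export
calibrate_d0_json <- function(path, out = NULL) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  refs_df <- as.data.frame(cfg$references)
  if (is.null(refs_df$rel_intensity_sd)) refs_df$rel_intensity_sd <- 0
  refs <- lapply(seq_len(nrow(refs_df)), function(i) {
    reference_layer(refs_df$name[i], refs_df$thickness_nm[i],
                    refs_df$rel_intensity[i], refs_df$rel_intensity_sd[i])
  })
  i0 <- if (is.null(cfg$i0)) 1 else cfg$i0
  model <- calibrate_d0(refs, i0 = i0)
  if (!is.null(out)) {
    res <- list(references = refs_df, i0 = i0,
                d0_nm = model$d0, d0_sd_nm = model$d0_sd)
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(model))
  }
  model
}
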