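#' Resistance-surface transformation hypothesis
#'
#' A `transform_spec` encodes one hypothesis about how a landscape variable
#' translates into movement resistance, in the two families used for
#' resistance-surface optimization:
#'
#' * `"classified"` — binary features (rivers, roads, a land-cover class):
#'   cells whose source value is in `class_values` get resistance `r_max`,
#'   all other cells get 1.
#' * `"power_deviation"` — continuous variables (aspect, slope, elevation):
#'   resistance rises from 1 at an `optimum` value to `r_max` at the maximal
#'   deviation, as `1 + (r_max - 1) * delta^x`, where `delta` is the deviation
#'   from the optimum normalized to `[0, 1]`. For circular variables
#'   (aspect, degrees) the deviation is angular distance divided by 180;
#'   otherwise `|v - optimum|` divided by the largest deviation on the raster
#'   (or by `max_dev`, when supplied).
#'
#' `r_max` controls the magnitude of the effect (`r_max = 1` is a flat,
#' isolation-by-resistance surface whatever the shape), `x` its contrast:
#' large `x` concentrates resistance near the maximal deviation.
#'
#' @param variable name of the landscape variable the spec applies to.
#' @param family `"classified"` or `"power_deviation"`.
#' @param r_max maximum resistance, >= 1.
#' @param x shape exponent (> 0), `power_deviation` only.
#' @param optimum value of the variable with minimum resistance
#'   (`power_deviation` only); degrees for aspect/slope, metres for elevation.
#' @param class_values source values mapped to `r_max` (`classified` only).
#' @param circular is the variable circular on `[0, 360)`? Defaults to `TRUE`
#'   when `variable` is `"aspect"`.
#' @param max_dev optional fixed normalization for the deviation
#'   (`power_deviation`, non-circular); default is the maximum deviation
#'   observed on the raster being transformed.
#'
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(variable,
                           family = c("classified", "power_deviation"),
                           r_max, x = 1, optimum = NULL, class_values = 1,
                           circular = identical(variable, "aspect"),
                           max_dev = NULL) {
  family <- match.arg(family)
  if (!is.numeric(r_max) || length(r_max) != 1L || r_max < 1)
    stop("r_max must be a single number >= 1")
  if (family == "power_deviation") {
    if (is.null(optimum))
      stop("power_deviation requires an optimum")
    if (!is.numeric(x) || x <= 0) stop("x must be > 0")
  }
  structure(
    list(variable = variable, family = family, r_max = r_max, x = x,
         optimum = optimum, class_values = class_values,
         circular = isTRUE(circular), max_dev = max_dev),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  if (x$family == "classified") {
    cat(sprintf("<transform_spec> %s: classified; R_max = %g\n",
                x$variable, x$r_max))
  } else {
    cat(sprintf("<transform_spec> %s: optimum %g; x = %g; R_max = %g%s\n",
                x$variable, x$optimum, x$x, x$r_max,
                if (x$circular) " (circular)" else ""))
  }
  invisible(x)
}

#' Apply a resistance transformation to a raster
#'
#' Turns a raw landscape variable into a resistance surface (all non-nodata
#' cells >= 1) according to a [transform_spec]. Nodata cells propagate.
#'
#' @param raster a [raster_grid] holding the raw variable.
#' @param spec a [transform_spec].
#' @return A [raster_grid] resistance surface.
#' @export
transform_raster <- function(raster, spec) {
  stopifnot(inherits(raster, "raster_grid"), inherits(spec, "transform_spec"))
  v <- raster$values
  out <- v
  ok <- !is.na(v)
  if (spec$family == "classified") {
    out[ok] <- ifelse(v[ok] %in% spec$class_values, spec$r_max, 1)
  } else {
    if (spec$circular) {
      if (any(v[ok] < 0 | v[ok] >= 360))
        stop("circular variable values must lie in [0, 360)")
      d <- abs(v[ok] - spec$optimum)
      delta <- pmin(d, 360 - d) / 180
    } else {
      d <- abs(v[ok] - spec$optimum)
      md <- if (!is.null(spec$max_dev)) spec$max_dev else max(d)
      delta <- if (md > 0) d / md else d * 0
      delta <- pmin(delta, 1)
    }
    out[ok] <- 1 + (spec$r_max - 1) * delta^spec$x
  }
  raster_grid(out, cell_size = raster$cell_size, xll = raster$xll,
              yll = raster$yll, nodata = raster$nodata)
}

#' Compose univariate resistance surfaces into a multivariate surface
#'
#' Cell-wise sum of aligned resistance rasters; nodata in any input yields
#' nodata in the output. Passing a single surface returns it unchanged.
#'
#' @param surfaces list of [raster_grid] objects on identical geometry.
#' @return A [raster_grid].
#' @export
compose_surfaces <- function(surfaces) {
  if (inherits(surfaces, "raster_grid")) surfaces <- list(surfaces)
  stopifnot(length(surfaces) >= 1L)
  base <- surfaces[[1L]]
  if (length(surfaces) == 1L) return(base)
  acc <- base$values
  for (s in surfaces[-1L]) {
    if (!same_geometry(base, s))
      stop(sprintf("misaligned grids: [%s] vs [%s]",
                   grid_header_string(base), grid_header_string(s)))
    acc <- acc + s$values   # NA propagates
  }
  raster_grid(acc, cell_size = base$cell_size, xll = base$xll,
              yll = base$yll, nodata = base$nodata)
}

#' Isolation-by-resistance null surface
#'
#' The IBR null model: every non-nodata cell of the template gets
#' resistance 1, so effective resistance reduces to a uniform-landscape
#' circuit distance and carries only the geometry of the study area.
#'
#' @param template a [raster_grid] providing geometry and nodata mask.
#' @return A [raster_grid] of ones.
#' @export
ibr_surface <- function(template) {
  stopifnot(inherits(template, "raster_grid"))
  v <- template$values
  v[!is.na(v)] <- 1
  raster_grid(v, cell_size = template$cell_size, xll = template$xll,
              yll = template$yll, nodata = template$nodata)
}
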