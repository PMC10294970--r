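#' Magnification between original specimen and printed model
#'
#' The magnification is `M = model length / original length`
#' (dimensionless): a scale bar of "1 cm printed : 10 um original" gives
#' `M = 1000`. The original scale is kept in the map so model-space
#' operations can always be traced back to specimen micrometres.
#'
#' @param original_length_um a key length on the specimen, in um.
#' @param model_length_mm the same length on the printed model, in mm.
#' @return A `scale_map` with element `M`.
#' @export
make_scale_map <- function(original_length_um, model_length_mm) {
  if (original_length_um <= 0 || model_length_mm <= 0)
    stop("lengths must be positive")
  M <- model_length_mm / (original_length_um * 1e-3)
  structure(list(M = M, original_unit = "um", model_unit = "mm"),
            class = "scale_map")
}

#' @export
print.scale_map <- function(x, ...) {
  cat("<scale_map> M = ", format(x$M), " (", x$model_unit, " model per ",
      x$original_unit, " original x 10^-3)\n", sep = "")
  invisible(x)
}

#' Apply a scale map: um mesh -> mm model mesh
#'
#' Coordinates are multiplied by `M * 1e-3`; lengths scale linearly and
#' volumes by `(M * 1e-3)^3`. Applying a map to a mesh already in mm (or
#' inverting a um mesh) is a unit error, which guards against double
#' scaling.
#'
#' @param mesh a [surface_mesh()] or [solid_part()] tagged `"um"`.
#' @param map a [make_scale_map()] result.
#' @return The mesh in mm.
#' @export
apply_scale <- function(mesh, map) {
  mesh <- as_surface_mesh(mesh)
  if (mesh$unit != "um")
    stop("apply_scale expects a um mesh (got '", mesh$unit, "')")
  mesh$vertices <- mesh$vertices * (map$M * 1e-3)
  mesh$unit <- "mm"
  mesh$provenance <- c(mesh$provenance, sprintf("apply_scale(M=%g)", map$M))
  mesh
}

#' @rdname apply_scale
#' @export
invert_scale <- function(mesh, map) {
  mesh <- as_surface_mesh(mesh)
  if (mesh$unit != "mm")
    stop("invert_scale expects a mm mesh (got '", mesh$unit, "')")
  mesh$vertices <- mesh$vertices / (map$M * 1e-3)
  mesh$unit <- "um"
  mesh$provenance <- c(mesh$provenance, sprintf("invert_scale(M=%g)", map$M))
  mesh
}

#' FDM print configuration
#'
#' @param layer_height printed layer height in mm (default 0.2, a fast PLA
#'   profile).
#' @param infill_percent infill density 0-100 (default 10).
#' @param infill_pattern infill pattern name (default `"triangular"`).
#' @param min_wall minimum stable wall thickness in mm (default 1).
#' @param supports generate supports flag.
#' @param build_volume printer build volume `(x, y, z)` in mm.
#' @return A `print_config` object.
#' @export
print_config <- function(layer_height = 0.2, infill_percent = 10,
                         infill_pattern = "triangular", min_wall = 1,
                         supports = TRUE,
                         build_volume = c(330, 240, 300)) {
  stopifnot(layer_height > 0, infill_percent >= 0, infill_percent <= 100)
  structure(list(layer_height = layer_height,
                 infill_percent = infill_percent,
                 infill_pattern = infill_pattern, min_wall = min_wall,
                 supports = supports, build_volume = build_volume),
            class = "print_config")
}

#' Original-scale print resolution
#'
#' The specimen-scale feature size that one printed layer represents:
#' `layer_height (mm) * 1e3 / M`, in um. Homogeneous in M: doubling the
#' magnification halves the resolution value.
#'
#' @param map a [make_scale_map()].
#' @param config a [print_config()].
#' @return resolution in um.
#' @export
print_resolution <- function(map, config) {
  config$layer_height * 1e3 / map$M
}

#' Printability report for a solid part
#'
#' Estimates the minimum wall thickness by inward ray casting from sampled
#' surface faces, flags the part stable when the minimum wall meets the
#' configured threshold, and records the bounding box against the build
#' volume.
#'
#' @param part a watertight [solid_part()] at model scale (mm).
#' @param config a [print_config()].
#' @param n_samples number of faces sampled for ray casting.
#' @return list with `min_wall`, `median_wall`, `stable`, `bbox_mm`,
#'   `fits_build_volume`, `layer_height`, `infill_percent`,
#'   `infill_pattern`, `supports`.
#' @export
printability_report <- function(part, config = print_config(),
                                n_samples = 200L) {
  part <- as_surface_mesh(part)
  nf <- nrow(part$faces)
  idx <- unique(as.integer(round(seq(1L, nf, length.out = min(n_samples, nf)))))
  bbox <- apply(part$vertices, 2L, range)
  diag <- sqrt(sum((bbox[2L, ] - bbox[1L, ])^2))
  th <- ray_thickness_cpp(part$vertices, part$faces, idx, diag * 1.01)
  th <- th[is.finite(th)]
  # trimmed minimum: robust to grazing-ray artefacts on faceted surfaces
  min_wall <- if (length(th))
    as.numeric(stats::quantile(th, 0.05, type = 1L)) else NA_real_
  size <- bbox[2L, ] - bbox[1L, ]
  list(min_wall = min_wall,
       median_wall = if (length(th)) stats::median(th) else NA_real_,
       stable = !is.na(min_wall) && min_wall >= config$min_wall,
       bbox_mm = size,
       fits_build_volume = all(sort(size) <= sort(config$build_volume)),
       layer_height = config$layer_height,
       infill_percent = config$infill_percent,
       infill_pattern = config$infill_pattern,
       supports = config$supports)
}
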