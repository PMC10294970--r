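#' Watertight printable solid part
#'
#' A [surface_mesh()] that encloses a positive volume, plus print metadata:
#' a part name, a color tag (mapped to filament color) and the wall
#' thickness it was solidified with (`"filled"` for fully solid parts).
#'
#' @param mesh a watertight [surface_mesh()].
#' @param name part name.
#' @param color_tag filament color label.
#' @param wall_thickness numeric thickness (shell mode) or `"filled"`.
#' @return A `solid_part` (inherits `surface_mesh`).
#' @export
solid_part <- function(mesh, name = "part", color_tag = "white",
                       wall_thickness = "filled") {
  mesh <- as_surface_mesh(mesh)
  if (!mesh_is_watertight(mesh))
    stop("solid_part requires a watertight mesh (part '", name, "')")
  vol <- mesh_signed_volume(mesh)
  if (vol < 0) { # flip to outward orientation
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
    vol <- -vol
  }
  if (vol <= 0) stop("solid_part requires positive enclosed volume")
  mesh$name <- name
  mesh$color_tag <- color_tag
  mesh$wall_thickness <- wall_thickness
  class(mesh) <- c("solid_part", "surface_mesh")
  mesh
}

#' Datum plane
#' @param point 3-vector on the plane (`x, y, z`).
#' @param normal 3-vector; normalized internally, must be non-zero.
#' @return A `plane3` object.
#' @export
plane3 <- function(point, normal = c(0, 0, 1)) {
  normal <- as.numeric(normal)
  n <- sqrt(sum(normal^2))
  if (n == 0) stop("plane normal must be non-zero")
  structure(list(point = as.numeric(point), normal = normal / n),
            class = "plane3")
}

plane_field <- function(plane, g) {
  ax <- grid_axes(g)
  nz <- g$dim[1L]; ny <- g$dim[2L]; nx <- g$dim[3L]
  n <- plane$normal; p <- plane$point
  fz <- (ax$z - p[3L]) * n[3L]
  fy <- (ax$y - p[2L]) * n[2L]
  fx <- (ax$x - p[1L]) * n[1L]
  array(fz, dim = g$dim) +
    array(rep(fy, each = nz), dim = g$dim) +
    array(rep(fx, each = nz * ny), dim = g$dim)
}

#' Solidify a surface into a printable part (uniform offset)
#'
#' Offsets the surface outward by `thickness`. `"filled"` mode returns the
#' outward offset surface with the interior filled; `"shell"` mode returns
#' the solid bounded by the original and the offset surface, i.e. a wall of
#' approximately uniform thickness. Open input surfaces are handled by
#' offsetting the surface sheet itself, which closes holes and always yields
#' a watertight solid.
#'
#' @param surface a [surface_mesh()] (typically at model scale, mm).
#' @param thickness positive offset distance in the mesh unit; walls of at
#'   least 1 mm print stably.
#' @param mode `"filled"` (default) or `"shell"`.
#' @param resolution voxel pitch of the distance-field engine; default
#'   `thickness/4`, bounded so the grid stays tractable.
#' @param name,color_tag part metadata.
#' @return A [solid_part()].
#' @export
solidify <- function(surface, thickness, mode = c("filled", "shell"),
                     resolution = NULL, name = "part", color_tag = "white") {
  mode <- match.arg(mode)
  surface <- as_surface_mesh(surface)
  if (thickness <= 0) stop("thickness must be > 0")
  ext <- apply(surface$vertices, 2L, function(v) diff(range(v)))
  if (is.null(resolution)) # shell walls need a finer pitch than filled solids
    resolution <- engine_resolution(
      ext, thickness = if (mode == "shell") thickness / 2 else thickness)
  g <- sdf_grid_for(list(surface), resolution,
                    pad = thickness + 4 * resolution)
  sdf <- mesh_sdf(surface, g)
  f <- if (mode == "filled") thickness - sdf else pmin(sdf, thickness - sdf)
  mesh <- field_mesh(f, g, surface$unit,
                     c(surface$provenance, sprintf("solidify(%s,%g)", mode,
                                                   thickness)))
  if (is.null(mesh))
    stop("offset surface collapsed to nothing (thickness ", thickness, ")")
  solid_part(mesh, name = name, color_tag = color_tag,
             wall_thickness = if (mode == "filled") "filled" else thickness)
}

#' Split a solid part by a datum plane
#'
#' Both halves are watertight with flat caps on the cut; their volumes sum
#' to the input volume within the engine tolerance. If the plane misses the
#' part, the whole part is returned as `upper` with an empty `lower` and the
#' `missed` flag set.
#'
#' @param part a [solid_part()].
#' @param plane a [plane3()]; default is the horizontal plane through the
#'   part's volume centroid (normal +z), which separates an adherent cell
#'   model into upper and lower halves.
#' @param resolution engine voxel pitch (default from part size).
#' @return list with `upper`, `lower` ([solid_part()] or `NULL`) and
#'   `missed` flag.
#' @export
plane_split <- function(part, plane = NULL, resolution = NULL) {
  part <- as_surface_mesh(part)
  if (is.null(plane)) plane <- plane3(part_centroid(part), c(0, 0, 1))
  ext <- apply(part$vertices, 2L, function(v) diff(range(v)))
  rng <- range((part$vertices - matrix(plane$point, nrow(part$vertices), 3L,
                                       byrow = TRUE)) %*% plane$normal)
  if (rng[1L] >= 0 || rng[2L] <= 0) {
    return(list(upper = part, lower = NULL, missed = TRUE))
  }
  if (is.null(resolution)) resolution <- engine_resolution(ext)
  g <- sdf_grid_for(list(part), resolution, pad = 4 * resolution)
  f_part <- -mesh_sdf(part, g)
  f_pl <- plane_field(plane, g)
  nm <- if (!is.null(part$name)) part$name else "part"
  up <- field_mesh(pmin(f_part, f_pl), g, part$unit,
                   c(part$provenance, "plane_split:upper"))
  lo <- field_mesh(pmin(f_part, -f_pl), g, part$unit,
                   c(part$provenance, "plane_split:lower"))
  list(upper = if (!is.null(up))
         solid_part(up, paste0(nm, "_upper"), part$color_tag %||% "white"),
       lower = if (!is.null(lo))
         solid_part(lo, paste0(nm, "_lower"), part$color_tag %||% "white"),
       missed = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

part_centroid <- function(mesh) {
  # volume centroid via divergence theorem over outward-oriented faces
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  det <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  vol <- sum(det) / 6
  cent <- colSums((a + b + cc) / 4 * det) / 6 / vol
  as.numeric(cent)
}

#' Boolean-subtract an insert with positive clearance
#'
#' Removes from `host` the insert dilated outward by `clearance`, producing
#' the cavity the physical insert part fits into after printing. The result
#' does not intersect the undilated insert (within the engine's voxel
#' tolerance).
#'
#' @param host,insert [solid_part()]s; both watertight.
#' @param clearance positive gap in the mesh unit (default 0.3 mm, a typical
#'   FDM fit tolerance).
#' @param resolution engine voxel pitch (default `clearance/4`, bounded).
#' @return A [solid_part()] (host with cavity).
#' @export
subtract_insert <- function(host, insert, clearance = 0.3,
                            resolution = NULL) {
  if (clearance <= 0) stop("clearance must be > 0")
  host <- as_surface_mesh(host); insert <- as_surface_mesh(insert)
  if (!mesh_is_watertight(host) || !mesh_is_watertight(insert))
    stop("subtract_insert requires watertight host and insert")
  vs <- rbind(host$vertices, insert$vertices)
  ext <- apply(vs, 2L, function(v) diff(range(v)))
  if (is.null(resolution))
    resolution <- engine_resolution(ext, clearance = clearance)
  g <- sdf_grid_for(list(host, insert), resolution,
                    pad = clearance + 4 * resolution)
  sdf_h <- mesh_sdf(host, g)
  sdf_i <- mesh_sdf(insert, g)
  f <- pmin(-sdf_h, sdf_i - clearance)
  mesh <- field_mesh(f, g, host$unit,
                     c(host$provenance,
                       sprintf("subtract_insert(clearance=%g)", clearance)))
  if (is.null(mesh)) stop("subtraction removed the entire host")
  solid_part(mesh, name = host$name %||% "host",
             color_tag = host$color_tag %||% "white",
             wall_thickness = host$wall_thickness %||% "filled")
}

#' Verify the fit between a cavity and its insert
#'
#' Reports the Boolean intersection volume between host and insert (zero
#' within voxel tolerance for a valid fit) and the minimum surface gap from
#' the insert to the host, and flags the fit as passing when the parts do
#' not interpenetrate and the gap does not exceed `clearance` plus the voxel
#' tolerance.
#'
#' @param host,insert [solid_part()]s.
#' @param clearance designed clearance.
#' @param resolution engine voxel pitch.
#' @return list with `intersection_volume`, `min_gap`, `voxel_tolerance`,
#'   `pass`.
#' @export
verify_fit <- function(host, insert, clearance = 0.3, resolution = NULL) {
  host <- as_surface_mesh(host); insert <- as_surface_mesh(insert)
  vs <- rbind(host$vertices, insert$vertices)
  ext <- apply(vs, 2L, function(v) diff(range(v)))
  if (is.null(resolution))
    resolution <- engine_resolution(ext, clearance = clearance)
  g <- sdf_grid_for(list(host, insert), resolution,
                    pad = clearance + 4 * resolution)
  h <- g$resolution
  occ_h <- voxelize_cpp(host$vertices, host$faces, g$dim, g$spacing, g$origin)
  occ_i <- voxelize_cpp(insert$vertices, insert$faces, g$dim, g$spacing,
                        g$origin)
  voxvol <- prod(g$spacing)
  inter <- sum(occ_h & occ_i) * voxvol
  vol_i <- sum(occ_i) * voxvol
  # minimum gap: distance from insert surface voxels to host solid
  d_host <- edt_cpp(occ_h, g$dim, g$spacing)
  dim(occ_i) <- g$dim
  boundary <- occ_i & !erode1(occ_i)
  min_gap <- if (any(boundary)) max(0, min(d_host[boundary]) - h) else NA_real_
  pass <- inter <= max(0.01 * vol_i, voxvol) &&
    !is.na(min_gap) && min_gap <= clearance + 2 * h
  list(intersection_volume = inter, min_gap = min_gap,
       voxel_tolerance = h, pass = pass)
}

# 6-connected binary erosion by one voxel (grid-edge treated as background)
erode1 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- (1 + by):n; idx_src[[ax]] <- 1:(n - by) }
    else { idx_dst[[ax]] <- 1:(n + by); idx_src[[ax]] <- (1 - by):n }
    r[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
      m[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
    r
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(m, ax, by)
  out
}

#' Build a dismountable assembly and write per-part STL files
#'
#' Applies the declared plane splits, then the clearance fits (Boolean
#' subtraction of each insert from its host and the host's split products),
#' and writes one binary STL per final part plus a JSON manifest. The final
#' part count equals the initial part count plus the number of splits.
#'
#' @param parts named list of [solid_part()].
#' @param splits list of `list(part = name, plane = plane3 or NULL)`; `NULL`
#'   planes use the horizontal centroid plane.
#' @param fits list of `list(host = name, insert = name, clearance = mm)`.
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @param model model name used as STL filename prefix.
#' @return An `assembly` object: `parts`, `fits`, `splits`, `files`,
#'   `manifest` (path or NULL).
#' @export
build_assembly <- function(parts, splits = list(), fits = list(),
                           dir = NULL, model = "model") {
  nms <- names(parts)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("parts must be uniquely named")
  origin_of <- as.list(stats::setNames(nms, nms))
  for (sp in splits) {
    if (!sp$part %in% names(parts))
      stop("split references unknown part '", sp$part, "'")
    halves <- plane_split(parts[[sp$part]], sp$plane %||% NULL)
    if (halves$missed)
      warning("split plane misses part '", sp$part, "'")
    new <- list()
    for (h in c("upper", "lower")) {
      if (is.null(halves[[h]])) next
      nm <- paste0(sp$part, "_", h)
      new[[nm]] <- halves[[h]]
      origin_of[[nm]] <- sp$part
    }
    parts <- c(parts[names(parts) != sp$part], new)
  }
  for (ft in fits) {
    clearance <- ft$clearance %||% 0.3
    if (!ft$insert %in% names(parts))
      stop("fit references unknown insert '", ft$insert, "'")
    hosts <- names(parts)[vapply(names(parts), function(nm)
      nm == ft$host || identical(origin_of[[nm]], ft$host), logical(1))]
    if (!length(hosts))
      stop("fit references unknown host '", ft$host, "'")
    for (hn in hosts)
      parts[[hn]] <- subtract_insert(parts[[hn]], parts[[ft$insert]],
                                     clearance = clearance)
  }
  files <- character(0)
  manifest <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(dir, paste0(model, "_", names(parts), ".stl"))
    for (i in seq_along(parts)) write_stl(parts[[i]], files[i])
    manifest <- file.path(dir, paste0(model, "_assembly.json"))
    info <- lapply(seq_along(parts), function(i) {
      st <- mesh_stats(parts[[i]])
      list(name = names(parts)[i], file = basename(files[i]),
           color = parts[[i]]$color_tag,
           volume = st$volume, n_faces = st$n_faces, unit = st$unit,
           watertight = st$watertight)
    })
    jsonlite::write_json(
      list(model = model, parts = info,
           splits = lapply(splits, function(s) s["part"]),
           fits = lapply(fits, function(f)
             list(host = f$host, insert = f$insert,
                  clearance = f$clearance %||% 0.3))),
      manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(parts = parts, fits = fits, splits = splits,
                 files = files, manifest = manifest, model = model),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly> '", x$model, "': ", length(x$parts), " part(s)\n", sep = "")
  for (nm in names(x$parts)) {
    st <- mesh_stats(x$parts[[nm]])
    cat(sprintf("  %-24s %8d faces  volume %.3f %s^3\n", nm, st$n_faces,
                st$volume, st$unit))
  }
  invisible(x)
}
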