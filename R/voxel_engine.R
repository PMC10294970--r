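# Signed-distance voxel engine backing solidification, plane splitting and
# clearance-aware Boolean subtraction. Meshes are voxelized by parity ray
# casting, converted to a signed distance field (SDF) via Euclidean distance
# transforms with a half-voxel surface correction, combined as min/max fields
# (CSG on SDFs), and re-extracted by interpolated marching tetrahedra, which
# gives subvoxel placement of offset surfaces and flat caps.

# choose the working resolution: the quarter-of-smallest-feature rule,
# bounded below so the longest grid axis stays around max_dim cells
engine_resolution <- function(extent, thickness = NULL, clearance = NULL,
                              max_dim = 192L) {
  feat <- c(thickness, clearance)
  r2 <- max(extent) / max_dim
  if (length(feat)) max(min(feat) / 4, r2) else r2
}

# grid covering the union bbox of meshes, padded; voxel centres are placed
# half a pitch off the bbox so axis-aligned faces fall exactly between
# centres (keeps the half-voxel EDT correction exact on flat geometry)
sdf_grid_for <- function(meshes, resolution, pad) {
  vs <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  lo <- apply(vs, 2L, min)  # (x, y, z)
  hi <- apply(vs, 2L, max)
  npad <- ceiling(pad / resolution)
  n <- ceiling((hi - lo) / resolution) + 2L * npad
  origin_xyz <- lo - npad * resolution + resolution / 2
  list(dim = as.integer(c(n[3L], n[2L], n[1L])),          # (nz, ny, nx)
       spacing = rep(resolution, 3L),
       origin = as.numeric(c(origin_xyz[3L], origin_xyz[2L], origin_xyz[1L])),
       resolution = resolution)
}

# voxel-centre coordinate arrays for a grid, as vectors along each axis
grid_axes <- function(g) {
  list(z = g$origin[1L] + (seq_len(g$dim[1L]) - 1L) * g$spacing[1L],
       y = g$origin[2L] + (seq_len(g$dim[2L]) - 1L) * g$spacing[2L],
       x = g$origin[3L] + (seq_len(g$dim[3L]) - 1L) * g$spacing[3L])
}

# signed distance field sampled at voxel centres; negative inside.
# Magnitudes within ~3 voxels of the surface come from exact point-triangle
# distances (subvoxel-accurate iso-surfaces at and near level 0); the far
# field is a half-voxel-corrected distance transform of the binary
# occupancy, adequate for CSG min/max combination. For non-watertight input
# the parity test is unreliable, so the mesh is treated as a thin sheet
# (unsigned distance) whose offsets are still watertight solids.
mesh_sdf <- function(mesh, g) {
  h <- g$resolution
  bd <- band_distance_cpp(mesh$vertices, mesh$faces, g$dim, g$spacing,
                          g$origin, 3 * h)
  if (mesh_is_watertight(mesh)) {
    occ <- voxelize_cpp(mesh$vertices, mesh$faces, g$dim, g$spacing, g$origin)
    dout <- edt_cpp(occ, g$dim, g$spacing)
    din <- edt_cpp(!occ, g$dim, g$spacing)
    mag <- pmin(bd, ifelse(occ, din, dout) - h / 2)
    sdf <- ifelse(occ, -mag, mag)
  } else {
    band <- mark_surface_cpp(mesh$vertices, mesh$faces, g$dim, g$spacing,
                             g$origin)
    if (!any(band) && all(is.infinite(bd)))
      stop("mesh lies outside the voxelization grid")
    sdf <- pmin(bd, edt_cpp(band, g$dim, g$spacing) - h / 2)
  }
  sdf
}

# extract the f > 0 region of a scalar field as a cleaned mesh
field_mesh <- function(field, g, unit, provenance) {
  res <- march_tets_cpp(as.numeric(field), g$dim, g$spacing, g$origin, 0)
  if (nrow(res$faces) == 0L) return(NULL)
  surface_mesh(res$vertices, res$faces, unit = unit, provenance = provenance)
}
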