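#' Binary voxel mask
#'
#' The segmentation currency: a logical `(z, y, x)` grid aligned to its
#' source stack, carrying the voxel size and an operation history.
#'
#' @param data logical array `(nz, ny, nx)`.
#' @param voxel_size numeric `(dz, dy, dx)` in um.
#' @param provenance character vector of operations applied so far.
#' @return A `vox_mask` object.
#' @export
vox_mask <- function(data, voxel_size, provenance = character()) {
  stopifnot(is.array(data), length(dim(data)) == 3L, is.logical(data))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, voxel_size = voxel_size,
                 provenance = provenance), class = "vox_mask")
}

#' @export
print.vox_mask <- function(x, ...) {
  d <- dim(x$data)
  cat("<vox_mask> ", d[1L], " x ", d[2L], " x ", d[3L], " (z,y,x), ",
      sum(x$data), " voxels set\n", sep = "")
  cat("  voxel size (um):", paste(x$voxel_size, collapse = " x "), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of set voxels
#' @param mask a [vox_mask()].
#' @return integer count.
#' @export
mask_count <- function(mask) sum(mask$data)

#' Physical volume of a mask in um^3
#' @param mask a [vox_mask()].
#' @return numeric volume.
#' @export
mask_volume <- function(mask) sum(mask$data) * prod(mask$voxel_size)

with_provenance <- function(mask, op) {
  mask$provenance <- c(mask$provenance, op)
  mask
}

#' Grey-value threshold parameters
#' @param gv_min,gv_max inclusive intensity band, `0 <= gv_min <= gv_max`.
#' @return A `threshold_params` object.
#' @export
threshold_params <- function(gv_min, gv_max) {
  stopifnot(gv_min >= 0, gv_min <= gv_max)
  structure(list(gv_min = gv_min, gv_max = gv_max),
            class = "threshold_params")
}

#' Threshold a channel into a binary mask
#'
#' A voxel is set iff `gv_min <= intensity <= gv_max` (inclusive band on the
#' grey value, GV).
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name.
#' @param params a [threshold_params()] or numeric `c(gv_min, gv_max)`.
#' @return A [vox_mask()].
#' @export
threshold_mask <- function(stack, channel, params) {
  if (is.numeric(params)) params <- threshold_params(params[1L], params[2L])
  if (params$gv_max > 2^stack$bit_depth - 1)
    stop("gv_max exceeds intensity maximum for ", stack$bit_depth, "-bit data")
  img <- get_channel(stack, channel)
  m <- img >= params$gv_min & img <= params$gv_max
  vox_mask(m, stack$voxel_size,
           sprintf("threshold(%s,[%g,%g])", channel,
                   params$gv_min, params$gv_max))
}

#' Dynamic region grow from a seed voxel
#'
#' Returns the 26-connected component of the intensity band
#' `[low, high]` that contains the seed.
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name.
#' @param seed integer `(z, y, x)` voxel index (1-based); its intensity must
#'   lie within `[low, high]`.
#' @param low,high inclusive intensity bounds.
#' @param connectivity 26 (default) or 6.
#' @return A [vox_mask()].
#' @export
region_grow <- function(stack, channel, seed, low, high, connectivity = 26L) {
  img <- get_channel(stack, channel)
  d <- dim(img)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3L, all(seed >= 1L), all(seed <= d))
  m <- region_grow_cpp(as.numeric(img), as.integer(d), seed - 1L,
                       low, high, as.integer(connectivity))
  dim(m) <- d
  vox_mask(m, stack$voxel_size,
           sprintf("region_grow(%s,seed=%s,[%g,%g])", channel,
                   paste(seed, collapse = ","), low, high))
}

#' Split a mask into connected components
#'
#' One mask per 26-connected component, ordered by descending voxel count.
#' The components are pairwise disjoint and their union is the input.
#'
#' @param mask a [vox_mask()].
#' @param connectivity 26 (default) or 6.
#' @return list of [vox_mask()]; empty list for an empty mask.
#' @export
split_mask <- function(mask, connectivity = 26L) {
  d <- dim(mask$data)
  lab <- label_cpp(as.vector(mask$data), as.integer(d),
                   as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(list())
  sizes <- tabulate(lab, nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  lapply(seq_len(k), function(i) {
    m <- array(lab == ord[i], dim = d)
    with_provenance(vox_mask(m, mask$voxel_size, mask$provenance),
                    sprintf("split_mask[%d/%d]", i, k))
  })
}

#' Axis-aligned region of interest
#'
#' Half-open index ranges `[lo, hi)` per axis, 1-based.
#'
#' @param z,y,x integer `c(lo, hi)` with `lo < hi`.
#' @return An `roi` object.
#' @export
roi <- function(z, y, x) {
  chk <- function(r, nm) {
    stopifnot(length(r) == 2L)
    if (r[1L] >= r[2L] || r[1L] < 1L)
      stop("invalid ROI range for ", nm, ": [", r[1L], ", ", r[2L], ")")
    as.integer(r)
  }
  structure(list(z = chk(z, "z"), y = chk(y, "y"), x = chk(x, "x")),
            class = "roi")
}

check_roi <- function(r, d) {
  if (!inherits(r, "roi")) stop("expected an roi object")
  lims <- rbind(r$z, r$y, r$x)
  if (any(lims[, 2L] > d + 1L))
    stop("ROI out of bounds for grid ", paste(d, collapse = "x"))
  lims
}

roi_slices <- function(r) {
  list(z = r$z[1L]:(r$z[2L] - 1L), y = r$y[1L]:(r$y[2L] - 1L),
       x = r$x[1L]:(r$x[2L] - 1L))
}

#' Crop a mask to a region of interest
#'
#' Voxels outside the ROI are cleared; the grid shape is unchanged so the
#' mask stays registered with its source stack.
#'
#' @param mask a [vox_mask()].
#' @param region an [roi()].
#' @return A [vox_mask()].
#' @export
crop_mask <- function(mask, region) {
  d <- dim(mask$data)
  check_roi(region, d)
  s <- roi_slices(region)
  m <- array(FALSE, dim = d)
  m[s$z, s$y, s$x] <- mask$data[s$z, s$y, s$x]
  with_provenance(vox_mask(m, mask$voxel_size, mask$provenance), "crop_mask")
}

fill_holes3d <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- m
  bg <- region_grow_cpp(as.numeric(!pad), as.integer(d + 2L),
                        c(0L, 0L, 0L), 1, 1, 6L)
  dim(bg) <- d + 2L
  filled <- !bg[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)]
  filled | m
}

fill_holes2d <- function(sl) {
  d <- dim(sl)
  m3 <- array(sl, dim = c(1L, d))
  pad <- array(FALSE, dim = c(1L, d + 2L))
  pad[1L, 2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- m3[1L, , ]
  bg <- region_grow_cpp(as.numeric(!pad), as.integer(c(1L, d + 2L)),
                        c(0L, 0L, 0L), 1, 1, 6L)
  dim(bg) <- c(1L, d + 2L)
  filled <- !bg[1L, 2:(d[1L] + 1L), 2:(d[2L] + 1L)]
  filled | sl
}

#' Close and fill a mask ("smart fill")
#'
#' Volumetric mode performs a 3D morphological closing with a ball of the
#' given voxel radius followed by a 3D hole fill; per-slice mode fills 2D
#' holes independently in every z-plane. Both are extensive (output contains
#' the input) and idempotent at fixed radius.
#'
#' @param mask a [vox_mask()].
#' @param mode `"volumetric"` (default) or `"per_slice"`.
#' @param radius closing ball radius in voxels (volumetric mode); default 2
#'   closes staining holes comparable to the PSF width.
#' @return A [vox_mask()].
#' @export
fill_mask <- function(mask, mode = c("volumetric", "per_slice"), radius = 2) {
  mode <- match.arg(mode)
  stopifnot(radius >= 0)
  d <- dim(mask$data)
  m <- mask$data
  if (mode == "volumetric") {
    if (radius > 0 && any(m) && !all(m)) {
      # pad so the world outside the grid acts as background during closing
      p <- as.integer(ceiling(radius) + 1L)
      dp <- d + 2L * p
      mp <- array(FALSE, dim = dp)
      mp[p + seq_len(d[1L]), p + seq_len(d[2L]), p + seq_len(d[3L])] <- m
      one <- c(1, 1, 1)
      dil <- edt_cpp(as.vector(mp), as.integer(dp), one) <= radius + 1e-9
      dim(dil) <- dp
      ero <- edt_cpp(as.vector(!dil), as.integer(dp), one) > radius + 1e-9
      dim(ero) <- dp
      closed <- ero[p + seq_len(d[1L]), p + seq_len(d[2L]),
                    p + seq_len(d[3L])]
      m <- closed | m  # closing is extensive; keep input explicitly
    }
    if (any(m) && !all(m)) m <- fill_holes3d(m)
  } else {
    for (zi in seq_len(d[1L])) {
      sl <- matrix(m[zi, , ], d[2L], d[3L])
      if (any(sl) && !all(sl)) m[zi, , ] <- fill_holes2d(sl)
    }
  }
  with_provenance(vox_mask(m, mask$voxel_size, mask$provenance),
                  sprintf("fill_mask(%s,r=%g)", mode, radius))
}

#' Programmatic mask editing by regions
#'
#' Deterministic replacement for interactive mask brushing: all `set_regions`
#' are applied first, then all `clear_regions` (so overlaps resolve to
#' cleared).
#'
#' @param mask a [vox_mask()].
#' @param set_regions,clear_regions lists of [roi()].
#' @return A [vox_mask()].
#' @export
edit_mask <- function(mask, set_regions = list(), clear_regions = list()) {
  d <- dim(mask$data)
  m <- mask$data
  for (r in set_regions) {
    check_roi(r, d); s <- roi_slices(r)
    m[s$z, s$y, s$x] <- TRUE
  }
  for (r in clear_regions) {
    check_roi(r, d); s <- roi_slices(r)
    m[s$z, s$y, s$x] <- FALSE
  }
  with_provenance(vox_mask(m, mask$voxel_size, mask$provenance), "edit_mask")
}

#' Write a mask as a single-channel 0/255 TIFF for inspection
#' @param mask a [vox_mask()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  d <- dim(mask$data)
  pages <- lapply(seq_len(d[1L]), function(zi)
    matrix(as.numeric(mask$data[zi, , ]), d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
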