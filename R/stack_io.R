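#' Channel description for a confocal stack
#'
#' @param name unique channel label within a stack.
#' @param stain fluorophore name, e.g. `"DAPI"`, `"TRITC"`, `"AF647"`.
#' @param target imaged structure, e.g. `"nuclei"`, `"f-actin"`, `"a-SMA"`.
#' @return A `channel_spec` object.
#' @export
channel_spec <- function(name, stain = name, target = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, stain = stain, target = target),
            class = "channel_spec")
}

#' Multi-channel voxel grid with physical scale
#'
#' The imaging currency of the pipeline: an intensity grid ordered
#' `(channel, z, y, x)` with voxel sizes in micrometres.
#'
#' @param data numeric array with dim `(n_channels, nz, ny, nx)`.
#' @param voxel_size numeric `(dz, dy, dx)` in um, all positive.
#' @param channels list of [channel_spec()] (or character names).
#' @param bit_depth integer bit depth; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return A `voxel_stack` object.
#' @export
voxel_stack <- function(data, voxel_size, channels, bit_depth = 8L) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.character(channels)) channels <- lapply(channels, channel_spec)
  nms <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nms)) stop("channel names must be unique")
  if (length(channels) != dim(data)[1L])
    stop("channel count (", length(channels),
         ") does not match first data dimension (", dim(data)[1L], ")")
  mx <- 2^bit_depth - 1
  rng <- range(data)
  if (rng[1L] < 0 || rng[2L] > mx)
    stop("intensities outside [0, ", mx, "] for bit depth ", bit_depth)
  structure(list(data = data, voxel_size = voxel_size,
                 channels = channels, bit_depth = as.integer(bit_depth)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<voxel_stack> ", d[1L], " channel(s), grid ", d[2L], " x ", d[3L],
      " x ", d[4L], " (z,y,x)\n", sep = "")
  cat("  voxel size (um): dz=", x$voxel_size[1L], " dy=", x$voxel_size[2L],
      " dx=", x$voxel_size[3L], ", ", x$bit_depth, "-bit\n", sep = "")
  cat("  channels:", paste(channel_names(x), collapse = ", "), "\n")
  invisible(x)
}

channel_names <- function(stack) {
  vapply(stack$channels, function(ch) ch$name, character(1))
}

channel_index <- function(stack, channel) {
  i <- match(channel, channel_names(stack))
  if (is.na(i)) stop("unknown channel '", channel, "'; available: ",
                     paste(channel_names(stack), collapse = ", "))
  i
}

#' Extract one channel as a (z, y, x) array
#' @param stack a [voxel_stack()].
#' @param channel channel name.
#' @return numeric array `(nz, ny, nx)`.
#' @export
get_channel <- function(stack, channel) {
  i <- channel_index(stack, channel)
  d <- dim(stack$data)
  array(stack$data[i, , , ], dim = d[2:4])
}

#' Read a multi-page TIFF z-stack
#'
#' Pages are arranged into a `(channel, z, y, x)` grid. The physical voxel
#' size cannot be stored in plain TIFF for the z axis, so voxel sizes come
#' from `voxel_size` (config override) with highest precedence, then from the
#' stack's XResolution/YResolution tags (in-plane only, so a z size is still
#' required); with neither source available reading fails rather than
#' silently defaulting, because every downstream physical measurement depends
#' on it.
#'
#' @param path readable multi-page TIFF file.
#' @param voxel_size optional numeric `(dz, dy, dx)` in um.
#' @param channels channel names (or list of [channel_spec()]); the page
#'   count must be divisible by the channel count.
#' @param layout `"c_fastest"` (channel-interleaved pages: c1z1, c2z1, ...,
#'   the default) or `"z_fastest"` (all z of channel 1, then channel 2, ...).
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL, channels = "ch1",
                       layout = c("c_fastest", "z_fastest")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.character(channels)) channels <- lapply(channels, channel_spec)
  nc <- length(channels)
  np <- length(pages)
  if (np %% nc != 0L)
    stop("page count (", np, ") not divisible by channel count (", nc, ")")
  nz <- np %/% nc
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L

  if (is.null(voxel_size)) {
    info <- attributes(pages[[1L]])
    xr <- info$x.resolution
    unit <- info$resolution.unit
    if (!is.null(xr) && is.numeric(xr) && xr > 0 && !is.null(unit)) {
      per_um <- switch(as.character(unit),
                       "inch" = xr / 25400, "2" = xr / 25400,
                       "cm" = xr / 10000, "3" = xr / 10000, NULL)
      if (!is.null(per_um))
        stop("in-plane pixel size ", signif(1 / per_um, 6),
             " um found in TIFF tags but z spacing is unavailable; ",
             "supply voxel_size = c(dz, dy, dx)")
    }
    stop("no voxel size available: supply voxel_size = c(dz, dy, dx) in um")
  }
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, dim = c(nc, nz, ny, nx))
  for (p in seq_len(np)) {
    if (layout == "c_fastest") {
      ci <- (p - 1L) %% nc + 1L
      zi <- (p - 1L) %/% nc + 1L
    } else {
      ci <- (p - 1L) %/% nz + 1L
      zi <- (p - 1L) %% nz + 1L
    }
    arr[ci, zi, , ] <- pages[[p]]
  }
  voxel_stack(arr, voxel_size, channels, bit_depth = bits)
}

#' Write a voxel stack as a multi-page TIFF
#'
#' Inverse of [read_stack()]; intensities are stored at the stack's bit
#' depth. The voxel size is not representable in plain TIFF, so callers are
#' expected to carry it in a run configuration.
#'
#' @param stack a [voxel_stack()].
#' @param path output file.
#' @param layout page ordering, as in [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, layout = c("c_fastest", "z_fastest")) {
  layout <- match.arg(layout)
  d <- dim(stack$data)
  nc <- d[1L]; nz <- d[2L]
  mx <- 2^stack$bit_depth - 1
  pages <- vector("list", nc * nz)
  p <- 0L
  if (layout == "c_fastest") {
    for (zi in seq_len(nz)) for (ci in seq_len(nc)) {
      p <- p + 1L
      pages[[p]] <- matrix(stack$data[ci, zi, , ], d[3L], d[4L]) / mx
    }
  } else {
    for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
      p <- p + 1L
      pages[[p]] <- matrix(stack$data[ci, zi, , ], d[3L], d[4L]) / mx
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  invisible(path)
}

#' Validate the physical extent of a stack against expected lengths
#'
#' Computes per-axis extent as voxel count times voxel size and compares it
#' with the expected physical length at a relative tolerance. Failures are
#' reported, not raised, so a run log can carry them.
#'
#' @param stack a [voxel_stack()].
#' @param expected_extent named numeric (any of `z`, `y`, `x`) expected
#'   physical lengths in um; all must be positive.
#' @param tol relative tolerance (fraction).
#' @return data frame with columns `axis`, `n`, `voxel_size_um`,
#'   `computed_um`, `expected_um`, `pass`.
#' @export
validate_scale <- function(stack, expected_extent, tol = 0.01) {
  stopifnot(all(expected_extent > 0))
  axes <- names(expected_extent)
  if (is.null(axes)) axes <- c("z", "y", "x")[seq_along(expected_extent)]
  d <- dim(stack$data)[2:4]
  names(d) <- c("z", "y", "x")
  vs <- stack$voxel_size
  names(vs) <- c("z", "y", "x")
  computed <- d[axes] * vs[axes]
  expected <- as.numeric(expected_extent)
  pass <- abs(computed - expected) <= tol * expected
  data.frame(axis = axes, n = as.integer(d[axes]),
             voxel_size_um = as.numeric(vs[axes]),
             computed_um = as.numeric(computed), expected_um = expected,
             pass = as.logical(pass), row.names = NULL)
}

# ---- STL ----

#' Write a triangle mesh as STL
#'
#' STL is unit-less: coordinates are written as-is (files written at model
#' scale are in mm by convention, recorded by the run log).
#'
#' @param mesh a [surface_mesh()] or [solid_part()], at least one face.
#' @param path output file.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  mesh <- as_surface_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) < 1L) stop("cannot write empty mesh (no faces)")
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  ntri <- nrow(f)
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(ntri), con, size = 4L, endian = "little")
    block <- t(cbind(n, a, b, cc))       # 12 floats per triangle, col = tri
    rawf <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
    m <- matrix(rawf, nrow = 48L)
    out <- rbind(m, matrix(as.raw(0L), 2L, ntri))
    writeBin(as.vector(out), con)
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
    lines <- character(7L * ntri + 2L)
    lines[1L] <- "solid cytoprint"
    idx <- seq_len(ntri)
    lines[7L * (idx - 1L) + 2L] <- paste("facet normal", fmt(n))
    lines[7L * (idx - 1L) + 3L] <- "  outer loop"
    lines[7L * (idx - 1L) + 4L] <- paste("    vertex", fmt(a))
    lines[7L * (idx - 1L) + 5L] <- paste("    vertex", fmt(b))
    lines[7L * (idx - 1L) + 6L] <- paste("    vertex", fmt(cc))
    lines[7L * (idx - 1L) + 7L] <- "  endloop"
    lines[7L * (idx - 1L) + 8L] <- "endfacet"
    lines[length(lines)] <- "endsolid cytoprint"
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file into a surface mesh
#'
#' Binary and ascii STL are auto-detected; duplicate vertices are merged
#' exactly so watertightness checks work on the result.
#'
#' @param path STL file.
#' @param unit unit tag to attach (STL itself is unit-less).
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, unit = "mm") {
  sz <- file.info(path)$size
  raw <- readBin(path, raw(), n = sz)
  is_binary <- FALSE
  if (sz >= 84L) {
    ntri <- readBin(raw[81:84], integer(), size = 4L, endian = "little")
    if (!is.na(ntri) && ntri > 0L && sz == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    body <- matrix(raw[-(1:84)], nrow = 50L)
    floats <- readBin(as.vector(body[1:48, ]), numeric(), n = 12L * ntri,
                      size = 4L, endian = "little")
    fm <- matrix(floats, nrow = 12L)        # per-tri: n, a, b, c
    tri <- array(fm[4:12, ], dim = c(3L, 3L, ntri))
    verts <- t(matrix(tri, nrow = 3L))      # 3*ntri x 3, a,b,c per tri
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]))
    verts <- do.call(rbind, nums)
    ntri <- nrow(verts) %/% 3L
  }
  key <- paste(verts[, 1L], verts[, 2L], verts[, 3L])
  uid <- match(key, key[!duplicated(key)])
  vu <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  surface_mesh(vu, faces, unit = unit, provenance = paste0("read_stl:", path))
}
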