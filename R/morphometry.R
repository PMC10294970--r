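#' Maximum projection of a mask along z
#'
#' Collapses a 3D mask onto the imaging plane (logical OR over z), the plane
#' in which adherent cultured cells are measured.
#'
#' @param mask a non-empty [vox_mask()].
#' @return list with `image` (logical `ny x nx`) and `pixel_size` `(dy, dx)`
#'   in um.
#' @export
project_mask <- function(mask) {
  if (!any(mask$data)) stop("cannot project an empty mask")
  d <- dim(mask$data)
  img <- matrix(colSums(matrix(mask$data, d[1L])) > 0, d[2L], d[3L])
  list(image = img, pixel_size = mask$voxel_size[2:3])
}

#' Feret (caliper) diameters of a 2D binary object
#'
#' `D1` is the maximum caliper diameter (longest diameter) and `D2` the
#' minimum caliper diameter (shortest diameter) of the foreground convex
#' hull, both in um. The minimum caliper uses rotating calipers over the
#' hull edges (the minimum width is attained perpendicular to a hull edge);
#' ties resolve to the first (smallest-angle) edge.
#'
#' @param image2d logical matrix (`ny x nx`), at least one `TRUE` pixel.
#' @param pixel_size numeric `(dy, dx)` in um.
#' @return named numeric `c(D1, D2)`.
#' @export
feret_diameters <- function(image2d, pixel_size) {
  idx <- which(image2d, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty image")
  y <- (idx[, 1L] - 1) * pixel_size[1L]
  x <- (idx[, 2L] - 1) * pixel_size[2L]
  if (nrow(idx) == 1L) return(c(D1 = 0, D2 = 0))
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(h)
  dm <- as.matrix(stats::dist(cbind(hx, hy)))
  d1 <- max(dm)
  if (n < 3L) return(c(D1 = d1, D2 = 0))
  d2 <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    el <- sqrt(ex^2 + ey^2)
    if (el == 0) next
    w <- max(abs((hx - hx[i]) * ey - (hy - hy[i]) * ex) / el)
    if (w < d2) d2 <- w
  }
  c(D1 = d1, D2 = d2)
}

#' Morphometry of every object in a mask
#'
#' One record per 26-connected component with at least `min_voxels` voxels:
#' the longest (`D1`) and shortest (`D2`) in-plane caliper diameters of the
#' z-projection, their mean `Davg = (D1 + D2) / 2`, the projected area, and
#' the volume from the voxel count. Highly elongated objects
#' (`D1/D2 > elongation_max`) keep their computed `Davg` but are flagged so
#' reports can suppress the average, which is not meaningful for
#' spindle-shaped cells.
#'
#' @param mask a [vox_mask()].
#' @param min_voxels minimum component size (voxels) to report.
#' @param elongation_max `D1/D2` ratio above which `davg_suppressed` is set.
#' @return data frame with columns `id`, `D1_um`, `D2_um`, `Davg_um`,
#'   `area_um2`, `volume_um3`, `n_voxels`, `davg_suppressed`.
#' @export
measure_objects <- function(mask, min_voxels = 10L, elongation_max = 3) {
  comps <- split_mask(mask)
  rows <- list()
  id <- 0L
  for (cm in comps) {
    nvox <- sum(cm$data)
    if (nvox < min_voxels) next
    id <- id + 1L
    pr <- project_mask(cm)
    fd <- feret_diameters(pr$image, pr$pixel_size)
    area <- sum(pr$image) * prod(pr$pixel_size)
    vol <- nvox * prod(cm$voxel_size)
    rows[[id]] <- data.frame(
      id = id, D1_um = fd[["D1"]], D2_um = fd[["D2"]],
      Davg_um = (fd[["D1"]] + fd[["D2"]]) / 2,
      area_um2 = area, volume_um3 = vol, n_voxels = nvox,
      davg_suppressed = fd[["D2"]] > 0 && fd[["D1"]] / fd[["D2"]] > elongation_max)
  }
  if (!length(rows))
    return(data.frame(id = integer(), D1_um = numeric(), D2_um = numeric(),
                      Davg_um = numeric(), area_um2 = numeric(),
                      volume_um3 = numeric(), n_voxels = integer(),
                      davg_suppressed = logical()))
  do.call(rbind, rows)
}

#' Write a morphometry table as CSV
#' @param records data frame from [measure_objects()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
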