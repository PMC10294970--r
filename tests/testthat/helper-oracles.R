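# Independent brute-force oracles, deliberately implemented with plain R
# array operations (no package internals).

# flood fill oracle: iterative dilation restricted to the band
# (conn = 26 or 6)
flood_oracle <- function(img, seed, low, high, conn = 26) {
  d <- dim(img)
  band <- img >= low & img <= high
  grow <- array(FALSE, d)
  grow[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    dil <- grow
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      if (conn == 6 && abs(dz) + abs(dy) + abs(dx) != 1) next
      zs <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      xs <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
      dil <- dil | grow[zs, ys, xs]
    }
    dil <- dil & band
    if (identical(dil, grow)) return(grow)
    grow <- dil
  }
}

# caliper width oracle: project foreground pixel centres on a dense set of
# directions (0.5 degree grid)
feret_oracle <- function(image2d, pixel_size) {
  idx <- which(image2d, arr.ind = TRUE)
  y <- (idx[, 1] - 1) * pixel_size[1]
  x <- (idx[, 2] - 1) * pixel_size[2]
  th <- seq(0, pi, by = 0.5 * pi / 180)
  w <- vapply(th, function(t) {
    p <- x * cos(t) + y * sin(t)
    max(p) - min(p)
  }, numeric(1))
  c(D1 = max(w), D2 = min(w))
}

# enclosed volume of a triangle soup by signed tetrahedra (plain R)
volume_oracle <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  tot <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    tot <- tot + det(rbind(a, b, cc)) / 6
  }
  abs(tot)
}
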