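# Analytic and digitized geometry fixtures, built in code at test time.

# subdivided octahedron sphere: watertight, outward-oriented
sphere_mesh <- function(r = 10, subdiv = 4, unit = "mm") {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    mid <- new.env()
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(cc, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  surface_mesh(v, f, unit = unit)
}

# axis-aligned cube mesh of side s centred at ctr
cube_mesh <- function(s = 1, ctr = c(0, 0, 0), unit = "mm") {
  v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))) * s / 2
  v <- sweep(v, 2L, ctr, "+")
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  surface_mesh(v, f, unit = unit)
}

tetra_mesh <- function(unit = "mm") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f, unit = unit)
}

# digitized solid ball as a vox_mask; centre chosen off-grid
ball_mask <- function(r = 10, h = 0.5, voxel_size = rep(h, 3)) {
  n <- ceiling((2 * r + 4) / voxel_size)
  ctr <- (n - 1) / 2 * voxel_size + 0.2 * voxel_size
  ax <- lapply(1:3, function(i) (seq_len(n[i]) - 1) * voxel_size[i])
  d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
              (ax[[3]] - ctr[3])^2, "+")
  vox_mask(array(d2 <= r^2, dim = n), voxel_size)
}

# small random blob masks under a fixed seed
random_mask <- function(d = c(8, 10, 9), p = 0.2, seed = 1) {
  set.seed(seed)
  array(runif(prod(d)) < p, dim = d)
}
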