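# Shared fixtures and independent oracles, all generated in code.

# uniform random cloud in a box
uniform_cloud <- function(n, xlim = c(0, 1), ylim = c(0, 1), zlim = c(0, 1),
                          seed = 1) {
  set.seed(seed)
  point_cloud(runif(n, xlim[1], xlim[2]), runif(n, ylim[1], ylim[2]),
              runif(n, zlim[1], zlim[2]))
}

# brute-force occupied-voxel count; anchor "min" matches box counting
# (cloud minimum corner), anchor "lattice" matches decimation (absolute
# multiples of the edge length)
oracle_voxel_count <- function(cloud, edge, anchor = "min") {
  o <- if (anchor == "min") c(min(cloud$x), min(cloud$y), min(cloud$z))
  else c(0, 0, 0)
  key <- paste(floor((cloud$x - o[1]) / edge + 1e-9),
               floor((cloud$y - o[2]) / edge + 1e-9),
               floor((cloud$z - o[3]) / edge + 1e-9))
  length(unique(key))
}

# brute-force per-voxel point counts (for Hill diversities at q > 0)
oracle_voxel_counts <- function(cloud, edge) {
  key <- paste(floor((cloud$x - min(cloud$x)) / edge + 1e-9),
               floor((cloud$y - min(cloud$y)) / edge + 1e-9),
               floor((cloud$z - min(cloud$z)) / edge + 1e-9))
  as.numeric(table(key))
}

# solid-of-revolution quadrature oracle for stem volume: the radius profile
# is linear from D_rc/2 at the root collar to the tip (conoid), with a
# breakpoint at 1.3 m (DBH/2) for tall trees
oracle_stem_volume <- function(height, d_rc, dbh = NA) {
  radius_at <- function(h) {
    if (height <= 1.3) {
      d_rc / 2 * (1 - h / height)
    } else {
      ifelse(h <= 1.3,
             d_rc / 2 + (dbh / 2 - d_rc / 2) * h / 1.3,
             dbh / 2 * (1 - (h - 1.3) / (height - 1.3)))
    }
  }
  f <- function(h) pi * vapply(h, radius_at, numeric(1))^2
  # integrate piecewise: the radius profile has a kink at breast height
  if (height <= 1.3) {
    stats::integrate(f, 0, height, rel.tol = 1e-12)$value
  } else {
    stats::integrate(f, 0, 1.3, rel.tol = 1e-12)$value +
      stats::integrate(f, 1.3, height, rel.tol = 1e-12)$value
  }
}

# brute-force mean distance to k nearest neighbors
oracle_knn_mean_dist <- function(xyz, k) {
  d <- as.matrix(dist(xyz))
  apply(d, 1, function(row) mean(sort(row[-which.min(row)])[seq_len(k)]))
}
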