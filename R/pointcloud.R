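# Point-cloud container, I/O and the conditioning chain:
# normalize -> clip -> SOR filter -> voxel decimation.

#' Construct a point cloud
#'
#' A point cloud is a plain \code{data.frame} with class \code{point_cloud}
#' and columns \code{x}, \code{y}, \code{z} (meters), \code{return_number},
#' \code{number_of_returns} (per-pulse return index and count, 1-based,
#' numbered top-down) and \code{classification} (one of \code{"ground"},
#' \code{"vegetation"}, \code{"noise"}, \code{"unassigned"}). Optional
#' \code{plot_id} and \code{doy} attributes identify the survey.
#'
#' @param x,y,z numeric coordinates in meters.
#' @param return_number,number_of_returns integer return metadata;
#'   \code{1 <= return_number <= number_of_returns}.
#' @param classification character class labels; defaults to
#'   \code{"unassigned"}.
#' @param plot_id,doy optional survey identifiers stored as attributes.
#' @return a \code{point_cloud} data.frame.
#' @export
point_cloud <- function(x, y, z, return_number = rep(1L, length(x)),
                        number_of_returns = rep(1L, length(x)),
                        classification = rep("unassigned", length(x)),
                        plot_id = NULL, doy = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n,
            length(return_number) == n, length(number_of_returns) == n)
  if (n > 0) {
    if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
      stopf("point coordinates must be finite")
    rn <- as.integer(return_number); nr <- as.integer(number_of_returns)
    if (any(rn < 1L) || any(rn > nr))
      stopf("return_number must satisfy 1 <= return_number <= number_of_returns")
  }
  cloud <- data.frame(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    return_number = as.integer(return_number),
    number_of_returns = as.integer(number_of_returns),
    classification = as.character(classification),
    stringsAsFactors = FALSE
  )
  class(cloud) <- c("point_cloud", "data.frame")
  attr(cloud, "plot_id") <- plot_id
  attr(cloud, "doy") <- doy
  cloud
}

as_point_cloud <- function(df, plot_id = NULL, doy = NULL) {
  point_cloud(df$x, df$y, df$z, df$return_number, df$number_of_returns,
              df$classification %||% rep("unassigned", nrow(df)),
              plot_id = plot_id, doy = doy)
}

#' Read a point cloud from CSV
#'
#' Reads a (optionally gzip-compressed) CSV with a header containing at
#' least \code{x}, \code{y}, \code{z}, \code{return_number} and
#' \code{number_of_returns}; \code{classification} is optional. The fractional
#' cover metric needs return numbers, so files missing those columns are
#' rejected rather than silently defaulted.
#'
#' @param path file path (\code{.csv} or \code{.csv.gz}).
#' @return a \code{point_cloud}.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  df <- tryCatch(utils::read.csv(con, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    warnf("empty point cloud file: %s", path)
    return(point_cloud(numeric(0), numeric(0), numeric(0),
                       integer(0), integer(0), character(0)))
  }
  needed <- c("x", "y", "z", "return_number", "number_of_returns")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stopf("point cloud CSV %s lacks required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  as_point_cloud(df)
}

#' Write a point cloud to CSV
#'
#' @param cloud a \code{point_cloud}.
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.csv(as.data.frame(cloud), con, row.names = FALSE)
  invisible(path)
}

#' Classify ground and normalize heights
#'
#' Estimates the ground surface as the lowest point per cell on a horizontal
#' grid (default 1 m), bilinearly interpolates that surface at every point's
#' position, and replaces \code{z} by height above ground. Points at or below
#' \code{veg_threshold} after normalization are classified \code{"ground"},
#' the rest \code{"vegetation"}. Adequate for flat or gently sloping terrain;
#' cells with no points inherit the global minimum.
#'
#' @param cloud a \code{point_cloud}; must be nonempty.
#' @param cell_m ground-grid cell size in meters.
#' @param veg_threshold height (m) separating ground-ish from vegetation
#'   points; the processing chain uses 0.25 m.
#' @return the normalized, classified \code{point_cloud}.
#' @export
classify_and_normalize <- function(cloud, cell_m = 1, veg_threshold = 0.25) {
  if (nrow(cloud) == 0) stopf("cannot normalize an empty cloud")
  x <- cloud$x; y <- cloud$y; z <- cloud$z
  x0 <- min(x); y0 <- min(y)
  nx <- max(1L, ceiling((max(x) - x0) / cell_m))
  ny <- max(1L, ceiling((max(y) - y0) / cell_m))
  ix <- pmin(nx, pmax(1L, as.integer(floor((x - x0) / cell_m)) + 1L))
  iy <- pmin(ny, pmax(1L, as.integer(floor((y - y0) / cell_m)) + 1L))
  if (nx == 1L && ny == 1L) {
    ground <- rep(min(z), length(z))  # all in one cell: global minimum
  } else {
    grid <- matrix(NA_real_, nx, ny)
    dt <- data.table(ix = ix, iy = iy, z = z)
    mins <- dt[, list(zmin = min(z)), by = c("ix", "iy")]
    grid[cbind(mins$ix, mins$iy)] <- mins$zmin
    grid[is.na(grid)] <- min(z)
    # bilinear interpolation between cell centers, clamped at the border
    cxs <- x0 + (seq_len(nx) - 0.5) * cell_m
    cys <- y0 + (seq_len(ny) - 0.5) * cell_m
    fx <- (x - cxs[1]) / cell_m
    fy <- (y - cys[1]) / cell_m
    i1 <- pmin(nx - 1L, pmax(1L, as.integer(floor(fx)) + 1L))
    j1 <- pmin(ny - 1L, pmax(1L, as.integer(floor(fy)) + 1L))
    if (nx == 1L) i1 <- rep(1L, length(x))
    if (ny == 1L) j1 <- rep(1L, length(y))
    i2 <- pmin(nx, i1 + 1L); j2 <- pmin(ny, j1 + 1L)
    tx <- pmin(1, pmax(0, (x - cxs[i1]) / cell_m))
    ty <- pmin(1, pmax(0, (y - cys[j1]) / cell_m))
    ground <- (1 - tx) * (1 - ty) * grid[cbind(i1, j1)] +
      tx * (1 - ty) * grid[cbind(i2, j1)] +
      (1 - tx) * ty * grid[cbind(i1, j2)] +
      tx * ty * grid[cbind(i2, j2)]
  }
  out <- cloud
  out$z <- z - ground
  out$classification <- ifelse(out$z <= veg_threshold, "ground", "vegetation")
  out
}

#' Plot polygon
#'
#' A closed convex ring of vertices (meters) with an optional signed buffer.
#' The conditioning chain uses a -0.5 m buffer on 10 m x 10 m plots, leaving
#' an 81 m^2 analysis region.
#'
#' @param vertices two-column matrix (x, y) of polygon vertices, in order;
#'   the ring is closed implicitly.
#' @param plot_id optional identifier.
#' @return a \code{plot_polygon} object.
#' @export
plot_polygon <- function(vertices, plot_id = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  # drop duplicated closing vertex if present
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  a <- polygon_area(vertices)
  if (a == 0) stopf("degenerate polygon (zero area)")
  if (a < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  if (!is_convex(vertices))
    stopf("plot_polygon supports convex rings only")
  structure(list(vertices = vertices, plot_id = plot_id),
            class = "plot_polygon")
}

polygon_area <- function(v) {
  n <- nrow(v); j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

is_convex <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1); nxt2 <- c(3:n, 1, 2)
  e1x <- v[nxt, 1] - v[, 1]; e1y <- v[nxt, 2] - v[, 2]
  e2x <- v[nxt2, 1] - v[nxt, 1]; e2y <- v[nxt2, 2] - v[nxt, 2]
  cr <- e1x * e2y - e1y * e2x
  all(cr >= -1e-12)
}

# signed inward distance of points to each edge of a CCW convex ring;
# returns the minimum over edges (positive strictly inside)
inward_distance <- function(v, px, py) {
  n <- nrow(v); nxt <- c(2:n, 1)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ex <- v[nxt[i], 1] - v[i, 1]; ey <- v[nxt[i], 2] - v[i, 2]
    len <- sqrt(ex^2 + ey^2)
    # inward normal of a CCW ring is (-ey, ex)/len
    di <- (-(ey) * (px - v[i, 1]) + ex * (py - v[i, 2])) / len
    d <- pmin(d, di)
  }
  d
}

#' Clip a cloud to a (negatively buffered) plot polygon
#'
#' Retains points strictly inside the polygon shrunk inward by
#' \code{|buffer_m|} (a signed buffer; negative or positive magnitude both
#' shrink by the absolute value, matching the "-0.5 m buffer" convention).
#' Points exactly on the buffered boundary are excluded.
#'
#' @param cloud a \code{point_cloud}.
#' @param polygon a \code{plot_polygon}.
#' @param buffer_m signed buffer in meters; 0 keeps all in-polygon points.
#' @return the clipped \code{point_cloud}.
#' @export
clip_plot <- function(cloud, polygon, buffer_m = -0.5) {
  stopifnot(inherits(polygon, "plot_polygon"))
  b <- abs(buffer_m)
  v <- polygon$vertices
  ctr <- colMeans(v)
  if (inward_distance(v, ctr[1], ctr[2]) <= b)
    stopf("buffer of %.2f m collapses the polygon", buffer_m)
  keep <- inward_distance(v, cloud$x, cloud$y) > b
  out <- cloud[keep, , drop = FALSE]
  class(out) <- class(cloud)
  attr(out, "plot_id") <- attr(cloud, "plot_id") %||% polygon$plot_id
  attr(out, "doy") <- attr(cloud, "doy")
  out
}

#' Statistical outlier removal (SOR)
#'
#' For every point higher than \code{z_min} (vegetation), computes the mean
#' Euclidean distance to its \code{k} nearest vegetation neighbors and
#' removes points whose mean distance exceeds the given quantile
#' (type-7/linear interpolation) of the mean-distance distribution. Points at
#' or below \code{z_min} pass through untouched, as the filter targets
#' vegetation returns only.
#'
#' @param cloud a normalized \code{point_cloud}.
#' @param k number of neighbors (default 30).
#' @param quantile quantile of the mean-distance distribution used as the
#'   removal threshold (default 0.975).
#' @param z_min height (m) above which points are treated as vegetation.
#' @return the filtered \code{point_cloud}.
#' @export
sor_filter <- function(cloud, k = 30, quantile = 0.975, z_min = 0.25) {
  if (k <= 0) stopf("k must be positive")
  if (quantile <= 0 || quantile >= 1) stopf("quantile must be in (0, 1)")
  veg <- which(cloud$z > z_min)
  if (length(veg) <= k) {
    warnf("fewer than k+1 points above %.2f m; SOR filter is a pass-through",
          z_min)
    return(cloud)
  }
  xyz <- as.matrix(cloud[veg, c("x", "y", "z")])
  nn <- FNN::get.knn(xyz, k = k)
  mean_d <- rowMeans(nn$nn.dist)
  thr <- stats::quantile(mean_d, probs = quantile, type = 7, names = FALSE)
  drop_idx <- veg[mean_d > thr]
  out <- if (length(drop_idx)) cloud[-drop_idx, , drop = FALSE] else cloud
  class(out) <- class(cloud)
  attr(out, "plot_id") <- attr(cloud, "plot_id")
  attr(out, "doy") <- attr(cloud, "doy")
  out
}

#' Voxel decimation
#'
#' Thins a cloud to at most one point per occupied voxel on a grid of edge
#' \code{edge_m}; the first point in input order wins within a voxel. The
#' grid is anchored at the cloud's minimum corner snapped down to the
#' absolute voxel lattice, so the voxel identity of a point does not depend
#' on which other points are present — decimation is therefore idempotent.
#' The processing chain uses 1 cm voxels to remove redundant, oversampled
#' returns.
#'
#' @param cloud a \code{point_cloud}.
#' @param edge_m voxel edge length in meters (default 0.01).
#' @return the decimated \code{point_cloud}.
#' @export
voxel_decimate <- function(cloud, edge_m = 0.01) {
  if (edge_m <= 0) stopf("edge_m must be positive")
  if (nrow(cloud) <= 1) return(cloud)
  origin <- floor(c(min(cloud$x), min(cloud$y), min(cloud$z)) / edge_m) *
    edge_m
  idx <- voxel_index(cloud$x, cloud$y, cloud$z, edge_m, origin)
  keep <- !duplicated(idx)
  out <- cloud[keep, , drop = FALSE]
  class(out) <- class(cloud)
  attr(out, "plot_id") <- attr(cloud, "plot_id")
  attr(out, "doy") <- attr(cloud, "doy")
  out
}

#' Full conditioning chain
#'
#' Applies, in order: height normalization, plot clipping with a negative
#' buffer, SOR noise filtering, and voxel decimation — the sequence used for
#' every survey before metrics are computed.
#'
#' @param cloud raw \code{point_cloud}.
#' @param polygon \code{plot_polygon} of the plot limits.
#' @param buffer_m signed clip buffer (default -0.5 m).
#' @param cell_m ground-grid cell (default 1 m).
#' @param k,quantile,z_min SOR parameters (defaults 30, 0.975, 0.25 m).
#' @param edge_m decimation voxel edge (default 0.01 m).
#' @return the conditioned \code{point_cloud}.
#' @export
condition_cloud <- function(cloud, polygon, buffer_m = -0.5, cell_m = 1,
                            k = 30, quantile = 0.975, z_min = 0.25,
                            edge_m = 0.01) {
  cloud <- classify_and_normalize(cloud, cell_m = cell_m,
                                  veg_threshold = z_min)
  cloud <- clip_plot(cloud, polygon, buffer_m = buffer_m)
  cloud <- sor_filter(cloud, k = k, quantile = quantile, z_min = z_min)
  voxel_decimate(cloud, edge_m = edge_m)
}
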