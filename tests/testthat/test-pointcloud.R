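test_that("CSV round-trip preserves coordinates and return fields", {
  cl <- uniform_cloud(1000, seed = 3)
  cl$return_number <- sample(1:3, 1000, replace = TRUE)
  cl$number_of_returns <- pmax(cl$return_number, 3L)
  for (ext in c("csv", "csv.gz")) {
    path <- file.path(tempdir(), paste0("cloud.", ext))
    write_point_cloud(cl, path)
    back <- read_point_cloud(path)
    expect_identical(back$return_number, as.integer(cl$return_number))
    expect_equal(back$x, cl$x, tolerance = 1e-12)
    expect_equal(back$z, cl$z, tolerance = 1e-12)
    unlink(path)
  }
})

test_that("missing return columns are rejected; empty files warn", {
  path <- file.path(tempdir(), "bad.csv")
  write.csv(data.frame(x = 1, y = 1, z = 1, return_number = 1), path,
            row.names = FALSE)
  expect_error(read_point_cloud(path), "number_of_returns")
  writeLines("x,y,z,return_number,number_of_returns", path)
  expect_warning(empty <- read_point_cloud(path), "empty")
  expect_equal(nrow(empty), 0)
  unlink(path)
})

test_that("return metadata is validated at construction", {
  expect_error(point_cloud(1, 1, 1, return_number = 2,
                           number_of_returns = 1), "return_number")
  expect_error(point_cloud(1, 1, Inf), "finite")
})

test_that("height normalization recovers ground under offset and slope", {
  set.seed(11)
  n <- 5000
  x <- runif(n, 0, 10); y <- runif(n, 0, 10)
  veg <- runif(n) < 0.3
  z_true <- ifelse(veg, runif(n, 0.5, 4), 0)
  # constant offset
  cl <- point_cloud(x, y, z_true + 37.2)
  norm <- classify_and_normalize(cl)
  expect_lt(max(abs(norm$z[!veg])), 0.05)
  # idempotence on already-normalized flat ground
  again <- classify_and_normalize(norm)
  expect_lt(max(abs(again$z - norm$z)), 0.05)
  # 2 % tilted plane
  cl2 <- point_cloud(x, y, z_true + 0.02 * x + 0.01 * y)
  norm2 <- classify_and_normalize(cl2)
  expect_lt(max(abs(norm2$z[!veg])), 0.1)
  expect_equal(norm2$x, x)  # only z is altered
})

test_that("normalization classifies by the vegetation threshold", {
  # ground points in every cell plus one low and one tall vegetation point
  gx <- rep(seq(0.5, 9.5, 1), each = 10)
  gy <- rep(seq(0.5, 9.5, 1), times = 10)
  cl <- point_cloud(c(gx, 5.2, 7.2), c(gy, 5.2, 7.2),
                    c(rep(0, length(gx)), 0.1, 3))
  norm <- classify_and_normalize(cl)
  n <- nrow(norm)
  expect_identical(norm$classification[c(n - 1, n)],
                   c("ground", "vegetation"))
  expect_true(all(norm$classification[seq_along(gx)] == "ground"))
})

test_that("negative-buffer clip retains the 81 m^2 interior", {
  # deterministic 0.05 m grid: exactly 81 % of cell centers are strictly
  # inside the 9 m x 9 m buffered square
  g <- expand.grid(x = (1:200 - 0.5) * 0.05, y = (1:200 - 0.5) * 0.05)
  cl <- point_cloud(g$x, g$y, rep(1, nrow(g)))
  sq <- plot_polygon(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  clipped <- clip_plot(cl, sq, buffer_m = -0.5)
  expect_equal(nrow(clipped) / nrow(cl), 0.81)
  # boundary points are excluded (strict inequality)
  onb <- point_cloud(c(0.5, 5), c(5, 5), c(0, 0))
  kept <- clip_plot(onb, sq, buffer_m = -0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 5)
  # zero buffer keeps all interior points
  expect_equal(nrow(clip_plot(cl, sq, buffer_m = 0)), nrow(cl))
  # collapsing buffer errors
  expect_error(clip_plot(cl, sq, buffer_m = -5), "collapses")
})

test_that("SOR removes injected sky noise but spares vegetation", {
  set.seed(5)
  n <- 4000
  veg <- point_cloud(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0.3, 4))
  n_noise <- 40
  noise <- point_cloud(runif(n_noise, 0, 10), runif(n_noise, 0, 10),
                       runif(n_noise, 8, 16))
  cl <- rbind(veg, noise)
  class(cl) <- c("point_cloud", "data.frame")
  cl$source <- rep(c("veg", "noise"), c(n, n_noise))
  out <- sor_filter(cl)
  noise_removed <- n_noise - sum(out$source == "noise")
  veg_removed <- n - sum(out$source == "veg")
  expect_gte(noise_removed / n_noise, 0.9)
  expect_lte(veg_removed / n, 0.03)
})

test_that("SOR matches a brute-force kNN oracle on a small cloud", {
  set.seed(7)
  cl <- uniform_cloud(200, zlim = c(0.3, 3), seed = 7)
  k <- 10
  out <- sor_filter(cl, k = k, quantile = 0.9)
  md <- oracle_knn_mean_dist(as.matrix(cl[, c("x", "y", "z")]), k)
  thr <- quantile(md, 0.9, type = 7, names = FALSE)
  expect_equal(nrow(out), sum(md <= thr))
  expect_equal(out$x, cl$x[md <= thr])
})

test_that("SOR passes through sparse or low clouds and validates inputs", {
  low <- point_cloud(1:5, 1:5, rep(0.1, 5))
  expect_warning(out <- sor_filter(low), "pass-through")
  expect_equal(nrow(out), 5)
  cl <- uniform_cloud(100, zlim = c(1, 2))
  expect_error(sor_filter(cl, k = 0), "positive")
  expect_error(sor_filter(cl, quantile = 1.2), "quantile")
})

test_that("voxel decimation keeps the first point per occupied voxel", {
  two <- point_cloud(c(0.001, 0.004), c(0, 0.003), c(0, 0.002))
  expect_equal(nrow(voxel_decimate(two, 0.01)), 1)
  apart <- point_cloud(c(0, 0.05, 0.1), c(0, 0, 0), c(0, 0, 0))
  expect_equal(nrow(voxel_decimate(apart, 0.01)), 3)
  cl <- uniform_cloud(10000, seed = 9)
  dec <- voxel_decimate(cl, 0.05)
  expect_equal(nrow(dec), oracle_voxel_count(cl, 0.05, anchor = "lattice"))
  # idempotent and order-stable: survivors are a prefix-stable subset
  expect_equal(nrow(voxel_decimate(dec, 0.05)), nrow(dec))
})

test_that("conditioning stages never grow the cloud or move x/y", {
  set.seed(13)
  pool <- generate_species_pool(4, 1, seed = 2)
  des <- generate_design(pool, 2, 1, c(1, 2), seed = 2)
  inv <- generate_inventories(des, pool, seed = 2)
  pid <- des$plots$plot_id[1]
  cl <- simulate_point_cloud(inv$inventory[inv$inventory$plot_id == pid, ],
                             pool, 215, density = 40, seed = 4)
  s1 <- classify_and_normalize(cl)
  s2 <- clip_plot(s1, des$polygon)
  s3 <- suppressWarnings(sor_filter(s2))
  s4 <- voxel_decimate(s3)
  expect_lte(nrow(s2), nrow(s1))
  expect_lte(nrow(s3), nrow(s2))
  expect_lte(nrow(s4), nrow(s3))
  expect_true(all(s4$x %in% cl$x))  # x/y never altered, only dropped
})
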