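test_that("box scans tile exactly and conserve mass", {
  sq <- binary_shape_image(matrix(1L, 64, 64), "silhouette")
  sc <- box_scan(sq, sizes = c(2, 3, 4, 5, 8, 16), n_offsets = 1)
  k8 <- which(sc$sizes == 8)
  expect_equal(sc$counts[k8, 1], 64L)
  expect_true(all(sc$masses[[k8]][[1]] == 64L))

  # 1 x 64 line, size 4, anchored grid: 16 boxes (kernel-level check; the
  # scan itself requires a 2-D bounding box)
  m <- cytofractal:::cf_box_masses(rep(0L, 64), 0:63, 4L, 0L, 0L)
  expect_equal(length(m), 16L)
  expect_true(all(m == 4L))

  # conservation on a random blob for every (size, offset)
  blob <- disk_raster(20)
  blob[10:14, 35:48] <- 1L
  sc2 <- box_scan(binary_shape_image(blob, "silhouette", check = FALSE),
                  n_offsets = 6, seed = 3)
  tot <- sum(blob)
  for (k in seq_along(sc2$sizes))
    for (o in seq_len(ncol(sc2$counts)))
      expect_equal(sum(sc2$masses[[k]][[o]]), tot)
})

test_that("dimension estimators recover analytic dimensions", {
  scan_of <- function(name) box_scan(reference_fractal(name, 512), seed = 1)
  expect_equal(box_counting_dimension(scan_of("square"))$mean, 2,
               tolerance = 0.05 / 2)
  expect_equal(box_counting_dimension(scan_of("line"))$mean, 1,
               tolerance = 0.05)
  expect_equal(box_counting_dimension(
    box_scan(reference_fractal("sierpinski", 512, 7), seed = 1))$mean,
    log(3) / log(2), tolerance = 0.05 / 1.585)
})

test_that("mass dimension carries the silhouette/contour sign convention", {
  sq <- box_scan(reference_fractal("square", 512), seed = 1)
  ln <- box_scan(reference_fractal("line", 512), seed = 1)
  expect_equal(mass_dimension(sq)$mean, -2, tolerance = 0.08 / 2)
  expect_equal(mass_dimension(ln)$mean, -1, tolerance = 0.08)

  # per-offset slopes equal an independent lm() refit
  for (o in c(1, 4)) {
    mm <- vapply(sq$masses, function(mk) mean(mk[[o]]), 0)
    ref <- unname(coef(lm(log(mm) ~ log(1 / sq$sizes)))[2])
    expect_equal(mass_dimension(sq)$per_offset[o], ref, tolerance = 1e-9)
  }
})

test_that("lacunarity matches hand-computed and recomputed values", {
  # exact tiling of a uniform square: zero variance at tiling sizes
  sq <- binary_shape_image(matrix(1L, 64, 64), "silhouette")
  sc <- box_scan(sq, sizes = c(2, 4, 8, 16, 32), n_offsets = 1)
  lac <- suppressWarnings(lacunarity(sc))
  expect_true(all(lac$lambda == 0))

  # two blobs, one 10x the mass of the other, one box each:
  # CV^2 over {m, 10m} = (4.5/5.5)^2
  two <- matrix(0L, 42, 42)
  two[2:4, 2:4] <- 1L                      # 9 px, box (0, 0)
  two[22:31, 22:30] <- 1L                  # 90 px, box (1, 1)
  sc2 <- box_scan(binary_shape_image(two, "silhouette", check = FALSE),
                  sizes = c(2, 3, 5, 8, 20), n_offsets = 1)
  k20 <- which(sc2$sizes == 20)
  expect_equal(sort(sc2$masses[[k20]][[1]]), c(9L, 90L))
  lam <- suppressWarnings(lacunarity(sc2))$lambda[k20, 1]
  expect_equal(lam, (4.5 / 5.5)^2, tolerance = 1e-12)

  # LF equals brute-force recomputation from the stored masses
  fld <- reference_fractal("bernoulli_field", 128, seed = 5)
  sc3 <- box_scan(fld, n_offsets = 4, seed = 2)
  lac3 <- lacunarity(sc3)
  brute <- mean(vapply(seq_along(sc3$sizes), function(k)
    mean(vapply(sc3$masses[[k]], function(m) {
      mu <- mean(m); mean((m - mu)^2) / mu^2
    }, 0)), 0))
  expect_equal(lac3$LF, brute, tolerance = 1e-12)
})

test_that("prefactor lacunarity is zero for invariant grids and matches CV^2", {
  # constructed scan: per-offset counts scaled by known factors
  sizes <- c(2L, 4L, 8L, 16L, 32L)
  base <- 4096 / sizes^1.5
  counts <- round(cbind(base, 1.1 * base, 0.9 * base))
  scan <- structure(list(sizes = sizes, counts = counts,
                         offsets = matrix(0, 3, 2),
                         masses = NULL, n_foreground = 0L,
                         variant = "silhouette"), class = "box_scan")
  pre <- prefactor_lacunarity(scan)
  cv2_ref <- {
    A <- pre$prefactors
    mean((A - mean(A))^2) / mean(A)^2
  }
  expect_equal(pre$PreLac, cv2_ref, tolerance = 1e-12)
  expect_equal(pre$PreLac, 0.00667, tolerance = 0.05)

  # identical counts across offsets -> PreLac 0
  scan0 <- scan
  scan0$counts <- cbind(base, base, base)
  expect_equal(prefactor_lacunarity(scan0)$PreLac, 0, tolerance = 1e-9)
  expect_error(prefactor_lacunarity(
    structure(list(sizes = sizes, counts = cbind(base),
                   offsets = matrix(0, 1, 2)), class = "box_scan")),
    "multiple grids")
})

test_that("local dimensions see connectivity and recover line and circle", {
  # long straight 1-px line: local D = 1 for both variants
  ln <- matrix(0L, 9, 200)
  ln[5, ] <- 1L
  img <- binary_shape_image(ln, "outline", check = FALSE)
  loc <- local_fractal_dimensions(img, window_sizes = c(5, 9, 17),
                                  sample_stride = 4)
  interior <- loc$lfd[5:40]
  expect_equal(mean(interior), 1, tolerance = 0.05)
  expect_equal(mean(loc$lcfd[5:40]), 1, tolerance = 0.05)

  # two parallel lines 3 px apart: LFD counts both, LCFD only the
  # connected one
  two <- matrix(0L, 11, 200)
  two[4, ] <- 1L
  two[7, ] <- 1L
  img2 <- binary_shape_image(two, "outline", check = FALSE)
  cnt <- cytofractal:::cf_local_fd_counts(img2$pixels, rep(4L, 5),
                                          as.integer(c(50, 80, 110, 140, 170)),
                                          c(2L, 4L, 8L))
  expect_true(all(cnt$lfd[, 2:3] > cnt$lcfd[, 2:3]))

  # outline of a disk: mean local connected dimension near 1
  d <- binary_shape_image(disk_raster(80), "silhouette")
  out <- extract_outline(d)
  loc2 <- local_fractal_dimensions(out, sample_stride = 3)
  expect_equal(loc2$outMeanLCFD, 1, tolerance = 0.05)

  # variant discipline
  expect_error(local_fractal_dimensions(d), "outline")
})

test_that("scans are deterministic and stable in the number of grids", {
  ga <- reference_fractal("sierpinski", 512, 7)
  s1 <- box_scan(ga, n_offsets = 4, seed = 9)
  s2 <- box_scan(ga, n_offsets = 4, seed = 9)
  expect_identical(s1$counts, s2$counts)
  d4 <- box_counting_dimension(box_scan(ga, n_offsets = 4, seed = 1))$mean
  d12 <- box_counting_dimension(box_scan(ga, n_offsets = 12, seed = 1))$mean
  expect_lt(abs(d4 - d12), 0.02)
})
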