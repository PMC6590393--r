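test_that("loading a one-bit image recovers the silhouette and resolves components", {
  png <- file.path(tempdir(), "cell.png")
  m <- matrix(1, 10, 10)           # white background
  m[4:7, 4:7] <- 0                 # dark 4x4 cell
  EBImage::writeImage(EBImage::Image(m), png)
  img <- load_binary_image(png)
  expect_s3_class(img, "binary_shape_image")
  expect_equal(sum(img$pixels), 16L)
  expect_equal(img$variant, "silhouette")

  # blob + speck: largest component kept, or refused on demand
  m2 <- matrix(1, 40, 40)
  m2[5:16, 5:16] <- 0              # 144-px blob
  m2[30:31, 30] <- 0               # speck
  png2 <- file.path(tempdir(), "two.png")
  EBImage::writeImage(EBImage::Image(m2), png2)
  img2 <- load_binary_image(png2, keep = "largest_component")
  expect_equal(sum(img2$pixels), 144L)
  expect_error(load_binary_image(png2, keep = "error_if_multiple"),
               "ambiguous")

  # all-background raster
  png3 <- file.path(tempdir(), "blank.png")
  EBImage::writeImage(EBImage::Image(matrix(1, 8, 8)), png3)
  expect_error(load_binary_image(png3), "blank")
})

test_that("outline extraction gives the boundary ring and respects variants", {
  blk <- binary_shape_image(block_raster(8, 8, 3:6, 3:6), "silhouette")
  out <- extract_outline(blk)
  expect_equal(out$variant, "outline")
  expect_equal(sum(out$pixels), 12L)        # 16 - 4 interior
  expect_error(extract_outline(out), "already outline")

  # single pixel is its own boundary
  one <- binary_shape_image(block_raster(5, 5, 3, 3), "silhouette")
  expect_equal(sum(extract_outline(one)$pixels), 1L)

  # disk r = 50: outline agrees with an independent morphological
  # erosion (EBImage) of the same boundary definition
  d <- binary_shape_image(disk_raster(50), "silhouette")
  out_d <- extract_outline(d)
  er <- EBImage::erode(EBImage::Image(d$pixels),
                       EBImage::makeBrush(3, "box"))
  ref <- d$pixels - (as.array(er) > 0.5)
  expect_lt(abs(sum(out_d$pixels) - sum(ref)) / sum(ref), 0.05)

  # idempotence on ring-shaped input: the outline of a 1-px ring is itself
  ring <- binary_shape_image(out_d$pixels, "silhouette", check = FALSE)
  expect_equal(extract_outline(ring)$pixels, out_d$pixels)
})

test_that("geometry primitives match closed forms on simple rasters", {
  blk <- binary_shape_image(block_raster(10, 10, 4:7, 4:7), "silhouette")
  g <- compute_geometry(blk)
  expect_equal(g$area_px, 16L)
  expect_equal(nrow(g$hull_vertices), 4L)
  expect_equal(g$bounding_circle$radius, 3 * sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(g$hull_area, 9)              # 3x3 square of pixel centres
  expect_equal(g$perimeter_px, 12)          # traced boundary of a 4x4 block

  # 1 x 100 pixel row: collinear centres
  row <- binary_shape_image(block_raster(3, 110, 2, 6:105), "silhouette",
                            check = FALSE)
  gr <- compute_geometry(row)
  expect_true(gr$degenerate)
  expect_equal(gr$bounding_circle$radius, 49.5, tolerance = 1e-9)
  expect_gte(gr$ellipse$major / max(gr$ellipse$minor, 1e-12), 20)
})

test_that("minimal enclosing circle matches the exhaustive oracle", {
  set.seed(7)
  for (rep in 1:5) {
    pts <- cbind(rnorm(40, sd = 20), rnorm(40, sd = 8))
    ours <- min_enclosing_circle(pts[grDevices::chull(pts), ])
    brute <- brute_min_circle(pts)
    expect_equal(ours$radius, brute$radius, tolerance = 1e-9)
  }
  # and on a pixel blob
  blob <- disk_raster(8)
  blob[3:5, 9:12] <- 1L
  idx <- which(blob == 1L, arr.ind = TRUE)
  pts <- cbind(as.numeric(idx[, 1]), as.numeric(idx[, 2]))
  hull <- pts[grDevices::chull(pts), ]
  expect_equal(min_enclosing_circle(hull)$radius,
               brute_min_circle(hull)$radius, tolerance = 1e-9)
})

test_that("hull area dominates region area within discretisation tolerance", {
  for (img in list(binary_shape_image(disk_raster(30), "silhouette"),
                   binary_shape_image(ellipse_raster(40, 18), "silhouette"))) {
    g <- compute_geometry(img)
    expect_gte(g$hull_area, g$area_px * 0.95)
  }
})
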