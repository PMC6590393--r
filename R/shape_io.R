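#' @useDynLib cytofractal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom MASS ginv
#' @importFrom stats coef cor cov cutree dist hclust lm pf pt ptukey quantile
#'   rbinom rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

#' Construct a binary shape image
#'
#' The unit of measurement of the whole pipeline: a 2-D binary raster holding
#' one cell, either as a filled silhouette or as its one-pixel-wide outline
#' (contour). Foreground pixels are 1, background 0; pixel centers sit at
#' integer coordinates.
#'
#' @param pixels integer or logical matrix; nonzero entries are foreground.
#' @param variant `"silhouette"` (filled mask) or `"outline"` (boundary
#'   curve). Outline-only descriptors refuse silhouette input and vice versa.
#' @param pixel_size physical side length of one pixel (arbitrary units);
#'   areas scale with its square.
#' @param source_id identifier carried through feature tables.
#' @param check if `TRUE` (default) enforce a single nonempty 8-connected
#'   foreground component; reference fractals such as random fields disable
#'   the check.
#' @return an object of class `binary_shape_image`.
#' @export
binary_shape_image <- function(pixels, variant = c("silhouette", "outline"),
                               pixel_size = 1, source_id = "",
                               check = TRUE) {
  variant <- match.arg(variant)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  pixels[pixels != 0L] <- 1L
  n_fg <- sum(pixels)
  if (n_fg == 0L) stop("blank image")
  if (check) {
    lab <- cf_label_components(pixels)
    if (max(lab) > 1L)
      stop("foreground is not a single 8-connected component")
    if (variant == "outline" && any(interior_mask(pixels)))
      stop("outline variant must have no interior foreground pixel")
  }
  structure(
    list(pixels = pixels, variant = variant, pixel_size = pixel_size,
         source_id = source_id),
    class = "binary_shape_image")
}

#' @export
print.binary_shape_image <- function(x, ...) {
  cat(sprintf("<binary_shape_image %s: %d x %d px, %d foreground, pixel_size=%g%s>\n",
              x$variant, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              x$pixel_size,
              if (nzchar(x$source_id)) paste0(", id=", x$source_id) else ""))
  invisible(x)
}

# foreground pixels all of whose 8 neighbours are foreground
interior_mask <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  nb <- matrix(1L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- nb & pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  (px == 1L) & nb
}

# fill interior background holes: background components (8-connected here,
# conservative) not touching the canvas border become foreground
fill_holes <- function(px) {
  bg <- 1L - px
  lab <- cf_label_components(bg)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  hole <- lab != 0L & !(lab %in% border)
  px[hole] <- 1L
  px
}

#' Load a one-bit cell image
#'
#' Reads a raster (PNG/TIFF/BMP/JPEG, anything EBImage decodes), binarizes at
#' mid-intensity and returns the silhouette of the cell. Hand-sketched cell
#' images are solid shapes, so interior holes are filled by default.
#'
#' @param path file path.
#' @param keep `"largest_component"` keeps the largest 8-connected foreground
#'   object; `"error_if_multiple"` refuses images holding more than one.
#' @param foreground `"dark"` if the cell is drawn dark on light background
#'   (the usual sketch convention), `"bright"` for the inverse.
#' @param fill_holes fill interior background holes (default `TRUE`).
#' @param pixel_size physical pixel side length.
#' @return a silhouette-variant [binary_shape_image()].
#' @export
load_binary_image <- function(path,
                              keep = c("largest_component", "error_if_multiple"),
                              foreground = c("dark", "bright"),
                              fill_holes = TRUE, pixel_size = 1) {
  keep <- match.arg(keep)
  foreground <- match.arg(foreground)
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  px <- matrix(0L, nrow(a), ncol(a))
  if (foreground == "dark") px[a < 0.5] <- 1L else px[a >= 0.5] <- 1L
  if (sum(px) == 0L) stop("blank image")
  lab <- cf_label_components(px)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    if (keep == "error_if_multiple")
      stop("ambiguous object: image holds ", ncomp, " foreground components")
    counts <- tabulate(lab[lab != 0L], nbins = ncomp)
    px <- matrix(0L, nrow(px), ncol(px))
    px[lab == which.max(counts)] <- 1L
  }
  if (fill_holes) px <- fill_holes(px)
  binary_shape_image(px, "silhouette", pixel_size = pixel_size,
                     source_id = basename(path))
}

#' Extract the outline (contour) of a silhouette
#'
#' The outline is the set of silhouette pixels that are 8-adjacent to the
#' background (or lie on the canvas border); for a simply connected
#' silhouette this is a single closed 8-connected curve. All `out`-prefixed
#' descriptors are measured on this variant.
#'
#' @param img a silhouette-variant [binary_shape_image()].
#' @return an outline-variant [binary_shape_image()].
#' @export
extract_outline <- function(img) {
  stopifnot(inherits(img, "binary_shape_image"))
  if (img$variant == "outline") stop("already outline")
  px <- img$pixels
  out <- px
  out[interior_mask(px)] <- 0L
  binary_shape_image(out, "outline", pixel_size = img$pixel_size,
                     source_id = img$source_id, check = FALSE)
}

#' Geometric primitives of a cell silhouette
#'
#' Computes the raw geometry consumed by the linear descriptors: pixel count,
#' traced-boundary perimeter (straight steps of length 1, diagonal steps of
#' sqrt(2)), convex hull of the foreground pixel centers, minimal enclosing
#' circle, ellipse with the same second central moments as the region, and
#' the centroid. All geometry is measured on pixel centers at integer
#' coordinates.
#'
#' @param img a [binary_shape_image()] (usually silhouette variant).
#' @return an object of class `shape_geometry` with fields `area_px`,
#'   `perimeter_px`, `hull_vertices`, `hull_area`, `hull_perimeter`,
#'   `bounding_circle` (`$center`, `$radius`), `ellipse` (`$center`,
#'   `$major`, `$minor`, `$theta`; full axis lengths), `centroid`,
#'   `degenerate` flag.
#' @export
compute_geometry <- function(img) {
  stopifnot(inherits(img, "binary_shape_image"))
  px <- img$pixels
  idx <- which(px == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  pts <- cbind(x = as.numeric(idx[, 1]), y = as.numeric(idx[, 2]))

  degenerate <- FALSE
  if (n < 3L) degenerate <- TRUE else {
    # collinearity: rank of centered coordinates
    cc <- sweep(pts, 2, colMeans(pts))
    degenerate <- qr(cc)$rank < 2L
  }

  # convex hull of pixel centers
  if (!degenerate) {
    h <- grDevices::chull(pts)
    hv <- pts[h, , drop = FALSE]         # counter-clockwise per chull docs
    hull_area <- polygon_area(hv)
    hull_perimeter <- polygon_perimeter(hv)
  } else {
    hv <- pts[grDevices::chull(pts), , drop = FALSE]
    hull_area <- 0
    hull_perimeter <- if (nrow(hv) == 2L)
      2 * sqrt(sum((hv[1, ] - hv[2, ])^2)) else 0
  }

  bc <- min_enclosing_circle(unique.matrix(pts[grDevices::chull(pts), ,
                                               drop = FALSE]))

  # moment ellipse (population second central moments of pixel centers)
  cen <- colMeans(pts)
  cc <- sweep(pts, 2, cen)
  S <- crossprod(cc) / n
  e <- eigen(S, symmetric = TRUE)
  major <- 4 * sqrt(max(e$values[1], 0))
  minor <- 4 * sqrt(max(e$values[2], 0))
  theta <- atan2(e$vectors[2, 1], e$vectors[1, 1])

  # perimeter of the traced boundary chain: straight steps length 1,
  # diagonal steps sqrt(2) (the raster morphometry tool-family
  # convention). The chain preserves every pixel of boundary texture but
  # overestimates smooth digital curves by ~5%, so an ideal disk measures
  # circularity ~0.90 rather than 1; see the methods vignette for why this
  # convention is kept over smoothed-polygon alternatives.
  if (n == 1L) {
    perim <- 0
  } else {
    b <- cf_trace_boundary(px)
    steps <- rbind(diff(b), b[1, ] - b[nrow(b), ])
    perim <- sum(ifelse(rowSums(abs(steps)) == 2L, sqrt(2), 1) *
                   (rowSums(abs(steps)) > 0L))
  }

  structure(
    list(area_px = n, perimeter_px = perim,
         hull_vertices = hv, hull_area = hull_area,
         hull_perimeter = hull_perimeter,
         bounding_circle = bc,
         ellipse = list(center = cen, major = major, minor = minor,
                        theta = theta),
         centroid = cen, degenerate = degenerate,
         pixel_size = img$pixel_size),
    class = "shape_geometry")
}

#' @export
print.shape_geometry <- function(x, ...) {
  cat(sprintf(paste0("<shape_geometry: area %d px, perimeter %.1f px, ",
                     "hull area %.1f, R %.2f, axes %.1f/%.1f%s>\n"),
              x$area_px, x$perimeter_px, x$hull_area,
              x$bounding_circle$radius, x$ellipse$major, x$ellipse$minor,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

# shoelace area of an ordered polygon (rows = vertices)
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygon_perimeter <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}

# centroid of a polygon by area weighting (falls back to vertex mean for
# zero-area degenerate polygons)
polygon_centroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

#' Minimal enclosing circle of a point set
#'
#' Welzl's move-to-front algorithm on the convex hull of the input; exact up
#' to floating point for the circle determined by at most three support
#' points.
#'
#' @param pts numeric matrix with two columns.
#' @return list with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique.matrix(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  eps <- 1e-10
  circ2 <- function(a, b) {
    list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      # collinear: widest diametral pair
      cand <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cand[[which.max(vapply(cand, `[[`, 0, "radius"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  inside <- function(circ, p)
    sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
  trivial <- function(R) {
    m <- length(R)
    if (m == 0L) return(list(center = c(0, 0), radius = -1))
    if (m == 1L) return(list(center = R[[1]], radius = 0))
    if (m == 2L) return(circ2(R[[1]], R[[2]]))
    circ3(R[[1]], R[[2]], R[[3]])
  }
  welzl <- function(i, R) {
    if (i > n || length(R) == 3L) return(trivial(R))
    d <- welzl(i + 1L, R)
    p <- pts[i, ]
    if (d$radius >= 0 && inside(d, p)) return(d)
    welzl(i + 1L, c(R, list(p)))
  }
  welzl(1L, list())
}
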