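# Linear (Euclidean) shape descriptors of one cell: size, circularity,
# convex-hull and bounding-circle ratios, roundness, aspect ratio, and two
# mass-partition symmetry ratios, plus the outline-evaluated auxiliaries.

# display names used in CSV output and reports, keyed by internal names
feature_display_names <- c(
  Area = "Area", Per = "Per", Circ = "Circ", HullsCirc = "Hull'sCirc",
  Round = "Round", MM_HullsCM = "M/MHull'sCM", MM_RadCirc = "M/MRadCirc",
  HalfDivision = "1/2half", In50Out50 = "in50/out50", AR = "AR",
  LCFD_PreLac = "LCFD PreLac", outLCFD_PreLac = "outLCFD PreLac",
  MMFD = "MMFD", outMMFD = "outMMFD", outMeanLCFD = "outMeanLCFD",
  outMeanLFD = "outMeanLFD", outMeanD = "outMeanD", LF = "LF",
  VarInCount = "Var in Count", Area_out = "Area out",
  Round_out = "Round out")

#' Linear shape descriptors of one cell
#'
#' Computes the linear parameter set from the silhouette geometry and the
#' outline:
#' \describe{
#'   \item{Area, Per}{foreground area and traced-boundary perimeter, in
#'     `pixel_size` units.}
#'   \item{Circ}{isoperimetric circularity `4*pi*Area/Per^2` (1 for a
#'     disk).}
#'   \item{Hull'sCirc}{the same for the convex hull.}
#'   \item{Round}{`4*Area/(pi*major^2)` with the major axis of the
#'     moment-equivalent ellipse (= minor/major for a true ellipse).}
#'   \item{AR}{aspect ratio major/minor of the moment ellipse.}
#'   \item{M/MHull'sCM}{max/min distance from the hull centroid to the hull
#'     boundary.}
#'   \item{M/MRadCirc}{max/min distance from the minimal-bounding-circle
#'     center to the outline pixels.}
#'   \item{1/2half}{larger/smaller foreground area of the two half-planes
#'     cut through the centroid along a principal axis, maximized over the
#'     major- and minor-axis cuts (1 for a symmetric cell).}
#'   \item{in50/out50}{foreground area inside the concentric circle of half
#'     the bounding radius divided by the area outside it (1/3 for a disk).}
#'   \item{Round out, Area out}{Round and Area evaluated on the outline
#'     pixels (moment ellipse and count of the contour).}
#' }
#'
#' @param geom [compute_geometry()] of the silhouette.
#' @param img the silhouette [binary_shape_image()].
#' @param outline its outline variant.
#' @return named numeric vector of the 12 linear descriptors (internal
#'   names; see `feature_display_names` for table-style names).
#' @export
compute_linear_features <- function(geom, img, outline) {
  stopifnot(inherits(geom, "shape_geometry"),
            inherits(img, "binary_shape_image"),
            inherits(outline, "binary_shape_image"))
  if (geom$degenerate) stop("degenerate shape")
  if (geom$ellipse$minor <= 0) stop("degenerate shape")
  ps <- img$pixel_size

  area <- geom$area_px * ps^2
  per <- geom$perimeter_px * ps
  circ <- 4 * pi * area / per^2
  hulls_circ <- 4 * pi * (geom$hull_area * ps^2) /
    (geom$hull_perimeter * ps)^2
  round_ <- 4 * geom$area_px / (pi * geom$ellipse$major^2)
  ar <- geom$ellipse$major / geom$ellipse$minor

  # hull centroid to hull boundary: exact max over vertices, min over edges
  hv <- geom$hull_vertices
  hc <- polygon_centroid(hv)
  dmax <- max(sqrt((hv[, 1] - hc[1])^2 + (hv[, 2] - hc[2])^2))
  dmin <- min(point_segment_distances(hc, hv))
  mm_hull <- dmax / dmin

  # bounding-circle center to outline pixels
  oidx <- which(outline$pixels == 1L, arr.ind = TRUE)
  ctr <- geom$bounding_circle$center
  d <- sqrt((oidx[, 1] - ctr[1])^2 + (oidx[, 2] - ctr[2])^2)
  mm_rad <- max(d) / max(min(d), .Machine$double.eps)

  # principal-axis half-plane asymmetry
  idx <- which(img$pixels == 1L, arr.ind = TRUE)
  cen <- geom$centroid
  th <- geom$ellipse$theta
  half_ratio <- function(nrm) {
    s <- (idx[, 1] - cen[1]) * nrm[1] + (idx[, 2] - cen[2]) * nrm[2]
    a <- sum(s > 1e-9) + sum(abs(s) <= 1e-9) / 2
    b <- sum(s < -1e-9) + sum(abs(s) <= 1e-9) / 2
    max(a, b) / max(min(a, b), 0.5)
  }
  half_div <- max(half_ratio(c(-sin(th), cos(th))),  # cut along major axis
                  half_ratio(c(cos(th), sin(th))))   # cut along minor axis

  # concentric half-radius mass partition
  dc <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  n_in <- sum(dc <= 0.5 * geom$bounding_circle$radius)
  n_out <- geom$area_px - n_in
  in50out50 <- if (n_out == 0L) {
    warning("no foreground outside the half-radius circle")
    Inf
  } else n_in / n_out

  # outline-evaluated auxiliaries
  n_o <- nrow(oidx)
  oc <- sweep(oidx, 2, colMeans(oidx))
  So <- crossprod(oc) / n_o
  major_o <- 4 * sqrt(max(eigen(So, symmetric = TRUE,
                                only.values = TRUE)$values[1], 0))
  round_out <- 4 * n_o / (pi * major_o^2)
  area_out <- n_o * ps^2

  c(Area = area, Per = per, Circ = circ, HullsCirc = hulls_circ,
    Round = round_, AR = ar, MM_HullsCM = mm_hull, MM_RadCirc = mm_rad,
    HalfDivision = half_div, In50Out50 = in50out50,
    Round_out = round_out, Area_out = area_out)
}

# distances from point p to each edge segment of an ordered polygon
point_segment_distances <- function(p, v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  ax <- v[, 1]; ay <- v[, 2]
  bx <- v[j, 1]; by <- v[j, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ((p[1] - ax) * dx + (p[2] - ay) * dy) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
}

#' All 21 morphometric descriptors of one cell
#'
#' Convenience wrapper running geometry extraction, the linear descriptors
#' and the quasi-fractal descriptors on a single silhouette.
#'
#' @param img silhouette-variant [binary_shape_image()].
#' @param n_sizes,n_offsets,seed box-scan settings, see [box_scan()].
#' @param window_sizes,sample_stride local-dimension settings, see
#'   [local_fractal_dimensions()].
#' @return named numeric vector of 21 descriptors (internal names).
#' @export
compute_cell_features <- function(img, n_sizes = 10, n_offsets = 12,
                                  seed = 1, window_sizes = c(5, 9, 17, 33),
                                  sample_stride = 1) {
  outline <- extract_outline(img)
  geom <- compute_geometry(img)
  lin <- compute_linear_features(geom, img, outline)
  fra <- compute_fractal_features(img, outline, n_sizes = n_sizes,
                                  n_offsets = n_offsets, seed = seed,
                                  window_sizes = window_sizes,
                                  sample_stride = sample_stride)
  c(lin, fra)[names(feature_display_names)]
}

#' Feature table for a set of cells
#'
#' Runs [compute_cell_features()] over a list of silhouettes and assembles
#' the cells x parameters table consumed by the selection, factor-analysis
#' and clustering stages.
#'
#' @param images list of silhouette [binary_shape_image()] objects.
#' @param cell_ids identifiers (defaults to `source_id`s or indices).
#' @param ... passed to [compute_cell_features()].
#' @param progress print a dot per cell.
#' @return a [feature_table()] (not yet normalized).
#' @export
compute_feature_table <- function(images, cell_ids = NULL, ...,
                                  progress = FALSE) {
  stopifnot(length(images) > 0)
  if (is.null(cell_ids)) {
    cell_ids <- vapply(images, `[[`, "", "source_id")
    if (any(!nzchar(cell_ids)) || anyDuplicated(cell_ids))
      cell_ids <- sprintf("cell_%03d", seq_along(images))
  }
  rows <- lapply(images, function(im) {
    if (progress) cat(".")
    compute_cell_features(im, ...)
  })
  if (progress) cat("\n")
  feature_table(do.call(rbind, rows), cell_ids = cell_ids)
}

#' Write a feature table as CSV with table-style column names
#'
#' Columns are written under the short display names used throughout the
#' reports (`Hull'sCirc`, `M/MRadCirc`, `1/2half`, ...).
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @export
write_features_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values)
  nm <- feature_display_names[colnames(df)]
  colnames(df) <- ifelse(is.na(nm), colnames(df), nm)
  df <- cbind(cell_id = table$cell_ids, df)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature CSV written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return a [feature_table()].
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  rev_map <- setNames(names(feature_display_names), feature_display_names)
  nm <- rev_map[colnames(vals)]
  colnames(vals) <- ifelse(is.na(nm), colnames(vals), nm)
  feature_table(vals, cell_ids = ids)
}
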