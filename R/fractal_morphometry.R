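# Multi-grid box-scan engine and the quasi-fractal descriptors.
#
# All descriptors are built on the same substrate: for a geometric series of
# box sizes and a set of pseudo-random grid offsets, the scan records how
# many grid boxes contain foreground (counts) and how many foreground pixels
# each nonempty box holds (masses). Slopes of the log-log relations give the
# dimensions; coefficients of variation of masses and fitted intercepts give
# the lacunarities.

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# default box-size series for a bounding box with smaller side `min_side`:
# geometric from 2 px up to an upper size calibrated against analytic
# references (see vignette): large boxes inflate counts by partial edge
# boxes and bias the log-log slope, so the ceiling is capped at min_side/32
# (but at least 8 px, and never above the 45% hard cap).
default_box_sizes <- function(min_side, n_sizes) {
  smax <- floor(min(0.45 * min_side, max(8, min_side / 32)))
  if (smax < 3) stop("insufficient scale range")
  sizes <- unique(round(exp(seq(log(2), log(smax), length.out = n_sizes))))
  if (length(sizes) < 5) stop("insufficient scale range")
  as.integer(sizes)
}

#' Multi-grid box scan of a binary shape
#'
#' Scans the foreground with square grids of geometrically spaced box sizes
#' and several grid placements: the anchored placement (no shift) plus
#' `n_offsets - 1` pseudo-random origin shifts drawn in `[0, size)^2` from
#' `seed`. Every fractal descriptor of the pipeline is a summary of this
#' scan.
#'
#' @param img a [binary_shape_image()]; the foreground bounding box must be
#'   at least 8 px in each dimension.
#' @param n_sizes number of box sizes in the geometric series (>= 5).
#' @param n_offsets number of grid placements (>= 1); default 12.
#' @param seed integer seed for the pseudo-random grid shifts.
#' @param sizes optional explicit integer vector of box sizes overriding the
#'   calibrated default series.
#' @return an object of class `box_scan`: `sizes`, `offsets` (fractions in
#'   `[0,1)^2`, first row `c(0,0)`), `counts` (sizes x offsets matrix),
#'   `masses` (list over sizes of lists over offsets of per-box foreground
#'   counts), `n_foreground`, `variant`.
#' @export
box_scan <- function(img, n_sizes = 10, n_offsets = 12, seed = 1,
                     sizes = NULL) {
  stopifnot(inherits(img, "binary_shape_image"))
  if (n_sizes < 5) stop("n_sizes must be >= 5")
  if (n_offsets < 1) stop("n_offsets must be >= 1")
  idx <- which(img$pixels == 1L, arr.ind = TRUE)
  x <- idx[, 1] - min(idx[, 1])
  y <- idx[, 2] - min(idx[, 2])
  bb <- c(max(x) + 1L, max(y) + 1L)
  if (min(bb) < 8L) stop("insufficient scale range")
  if (is.null(sizes)) sizes <- default_box_sizes(min(bb), n_sizes)
  sizes <- as.integer(sort(unique(sizes)))
  offs <- rbind(c(0, 0),
                if (n_offsets > 1)
                  with_seed(seed, matrix(runif(2 * (n_offsets - 1)),
                                         ncol = 2)))
  counts <- matrix(NA_integer_, length(sizes), n_offsets)
  masses <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    mk <- vector("list", n_offsets)
    for (o in seq_len(n_offsets)) {
      m <- cf_box_masses(x, y, s, as.integer(floor(offs[o, 1] * s)),
                         as.integer(floor(offs[o, 2] * s)))
      mk[[o]] <- m
      counts[k, o] <- length(m)
    }
    masses[[k]] <- mk
  }
  structure(
    list(sizes = sizes, offsets = offs, counts = counts, masses = masses,
         n_foreground = nrow(idx), variant = img$variant),
    class = "box_scan")
}

#' @export
print.box_scan <- function(x, ...) {
  cat(sprintf("<box_scan %s: %d sizes (%d..%d px), %d offsets, %d fg px>\n",
              x$variant, length(x$sizes), min(x$sizes), max(x$sizes),
              nrow(x$offsets), x$n_foreground))
  invisible(x)
}

# least-squares slope and intercept of y ~ x
ls_fit <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(intercept = ym - b * xm, slope = b)
}

#' Box-counting dimension
#'
#' Per grid placement, D is minus the least-squares slope of
#' `log(count) ~ log(size)`; the summary value is the mean over placements.
#' Applied to outline scans this is the contour mean dimension (`outMeanD`).
#'
#' @param scan a [box_scan()] with at least 5 sizes.
#' @return list with `per_offset` (one D per grid placement) and `mean`.
#' @export
box_counting_dimension <- function(scan) {
  stopifnot(inherits(scan, "box_scan"))
  if (length(scan$sizes) < 5) stop("insufficient scale range")
  ls <- log(scan$sizes)
  per <- apply(scan$counts, 2, function(ct) {
    lc <- log(ct)
    if (var(lc) == 0) stop("flat scan")
    -ls_fit(ls, lc)[["slope"]]
  })
  list(per_offset = per, mean = mean(per))
}

#' Mass fractal dimension
#'
#' Per grid placement, the least-squares slope of
#' `log(mean nonempty-box mass) ~ log(1/size)`; the summary is the mean over
#' placements. The sign convention makes filled planar regions come out near
#' -2 and thin contours near -1 (silhouette `MMFD` vs outline `outMMFD`).
#'
#' @param scan a [box_scan()] with at least 5 sizes.
#' @return list with `per_offset` and `mean` (the MMFD).
#' @export
mass_dimension <- function(scan) {
  stopifnot(inherits(scan, "box_scan"))
  if (length(scan$sizes) < 5) stop("insufficient scale range")
  linv <- log(1 / scan$sizes)
  per <- vapply(seq_len(ncol(scan$counts)), function(o) {
    mm <- vapply(scan$masses, function(mk) mean(mk[[o]]), 0)
    lm_ <- log(mm)
    if (var(lm_) == 0) stop("flat scan")
    ls_fit(linv, lm_)[["slope"]]
  }, 0)
  list(per_offset = per, mean = mean(per))
}

# population coefficient-of-variation squared
cv2 <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  mean((x - m)^2) / m^2
}

#' Lacunarity and across-grid count heterogeneity
#'
#' Per (size, placement) cell the lacunarity is the squared coefficient of
#' variation of the nonempty-box masses; `LF` averages it over all sizes and
#' placements. `VarInCount` is the variance of the box count across
#' placements, averaged over sizes: a size-coupled translational-
#' heterogeneity companion (large cells occupy many boxes, so their counts
#' also vary more under grid translation).
#'
#' @param scan a [box_scan()] with at least 2 nonempty boxes at every size.
#' @return list with `LF`, `VarInCount`, and the per-(size, offset) `lambda`
#'   matrix.
#' @export
lacunarity <- function(scan) {
  stopifnot(inherits(scan, "box_scan"))
  if (any(scan$counts < 2)) stop("needs >= 2 nonempty boxes at every size")
  lam <- matrix(NA_real_, length(scan$sizes), ncol(scan$counts))
  for (k in seq_along(scan$sizes))
    for (o in seq_len(ncol(scan$counts)))
      lam[k, o] <- cv2(scan$masses[[k]][[o]])
  vic <- if (ncol(scan$counts) < 2) {
    warning("single grid placement: VarInCount is 0")
    0
  } else mean(apply(scan$counts, 1, function(x) mean((x - mean(x))^2)))
  list(LF = mean(lam), VarInCount = vic, lambda = lam)
}

#' Prefactor lacunarity of a box scan
#'
#' Per grid placement the scaling law `log(count) = log(A) - D log(size)` is
#' fitted; the prefactor lacunarity is the squared CV of the fitted
#' prefactors A across placements. It measures how much the scaling-law
#' intercept moves when the grid is translated (translational invariance).
#' Applied to outline scans it is `outLCFD PreLac`.
#'
#' @param scan a [box_scan()] with at least 2 grid placements.
#' @return list with `PreLac` and the per-placement `prefactors`.
#' @export
prefactor_lacunarity <- function(scan) {
  stopifnot(inherits(scan, "box_scan"))
  if (ncol(scan$counts) < 2) stop("needs multiple grids")
  ls <- log(scan$sizes)
  A <- apply(scan$counts, 2, function(ct)
    exp(ls_fit(ls, log(ct))[["intercept"]]))
  list(PreLac = cv2(A), prefactors = A)
}

#' Local and local-connected fractal dimensions of a contour
#'
#' Around sampled outline pixels, concentric square windows of increasing
#' side are examined: the local fractal dimension (LFD) regresses the log of
#' all foreground pixels in the window on the log window side; the local
#' connected variant (LCFD) counts only foreground 8-connected to the window
#' center within the window, excluding nearby but disconnected structures.
#' Summaries are the means over sampled pixels (`outMeanLFD`,
#' `outMeanLCFD`); the squared CV of the fitted LCFD intercepts across
#' sampled pixels is the prefactor lacunarity of the local scans
#' (`LCFD PreLac`).
#'
#' @param img an outline-variant [binary_shape_image()] with >= 10 pixels.
#' @param window_sizes odd window sides, at least 3 of them.
#' @param sample_stride sample every `sample_stride`-th outline pixel
#'   (default 1 = all pixels).
#' @return list with `outMeanLFD`, `outMeanLCFD`, `LCFD_PreLac`, and per-
#'   pixel local dimensions `lfd`, `lcfd`.
#' @export
local_fractal_dimensions <- function(img, window_sizes = c(5, 9, 17, 33),
                                     sample_stride = 1) {
  stopifnot(inherits(img, "binary_shape_image"))
  if (img$variant != "outline")
    stop("local contour dimensions require the outline variant")
  if (length(window_sizes) < 3) stop("need >= 3 window sizes")
  if (any(window_sizes %% 2 == 0)) stop("window sizes must be odd")
  idx <- which(img$pixels == 1L, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("curve too short")
  sel <- seq(1, nrow(idx), by = sample_stride)
  radii <- as.integer((sort(window_sizes) - 1) / 2)
  cnt <- cf_local_fd_counts(img$pixels, as.integer(idx[sel, 1]),
                            as.integer(idx[sel, 2]), radii)
  lw <- log(2 * radii + 1)
  fit_rows <- function(m) {
    t(apply(m, 1, function(cc) ls_fit(lw, log(pmax(cc, 1)))))
  }
  f_lfd <- fit_rows(cnt$lfd)
  f_lcfd <- fit_rows(cnt$lcfd)
  list(outMeanLFD = mean(f_lfd[, "slope"]),
       outMeanLCFD = mean(f_lcfd[, "slope"]),
       LCFD_PreLac = cv2(exp(f_lcfd[, "intercept"])),
       lfd = f_lfd[, "slope"], lcfd = f_lcfd[, "slope"])
}

#' All quasi-fractal descriptors of one cell
#'
#' Runs silhouette and outline box scans plus the local contour scans and
#' assembles the nine quasi-fractal parameters: `MMFD`, `outMMFD`,
#' `outMeanD`, `outMeanLFD`, `outMeanLCFD`, `LF`, `Var in Count`,
#' `LCFD PreLac`, `outLCFD PreLac`.
#'
#' @param img silhouette-variant [binary_shape_image()].
#' @param outline its outline variant (computed if missing).
#' @param n_sizes,n_offsets,seed passed to [box_scan()].
#' @param window_sizes,sample_stride passed to
#'   [local_fractal_dimensions()].
#' @return named numeric vector of the nine descriptors.
#' @export
compute_fractal_features <- function(img, outline = NULL, n_sizes = 10,
                                     n_offsets = 12, seed = 1,
                                     window_sizes = c(5, 9, 17, 33),
                                     sample_stride = 1) {
  stopifnot(inherits(img, "binary_shape_image"), img$variant == "silhouette")
  if (is.null(outline)) outline <- extract_outline(img)
  sil <- box_scan(img, n_sizes, n_offsets, seed)
  out <- box_scan(outline, n_sizes, n_offsets, seed)
  lac <- lacunarity(sil)
  loc <- local_fractal_dimensions(outline, window_sizes, sample_stride)
  c(MMFD = mass_dimension(sil)$mean,
    outMMFD = mass_dimension(out)$mean,
    outMeanD = box_counting_dimension(out)$mean,
    outMeanLFD = loc$outMeanLFD,
    outMeanLCFD = loc$outMeanLCFD,
    LF = lac$LF,
    VarInCount = lac$VarInCount,
    LCFD_PreLac = loc$LCFD_PreLac,
    outLCFD_PreLac = prefactor_lacunarity(out)$PreLac)
}
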