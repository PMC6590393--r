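# Seeded generator of binary cell silhouettes with planted morphotypes, and
# analytic reference rasters for validating the fractal estimators. The
# generator stands in for undeposited micrographs: it emulates flattened
# hemocyte silhouettes as an elliptical body with radial, tapered processes
# and a midpoint-displacement-perturbed boundary.

#' Morphotype specification
#'
#' @param elongation body ellipse axis ratio (>= 1).
#' @param n_processes number of radial processes.
#' @param process_length process length as a fraction of the body radius.
#' @param process_width process base width in px.
#' @param boundary_roughness relative amplitude in `[0, 1]` of the
#'   midpoint-displacement perturbation of the body boundary (gross shape).
#' @param fine_roughness relative amplitude of an independent
#'   high-frequency boundary texture (membrane ruffling): drives the
#'   contour-scale descriptors with little effect on gross shape.
#' @param body_radius geometric mean body radius in px.
#' @param size_cv per-cell lognormal coefficient of variation of the body
#'   radius: adherent cells of one type spread to quite different areas, so
#'   realistic populations carry a size axis of variation.
#' @param name optional label.
#' @return object of class `morphotype_spec`.
#' @export
morphotype_spec <- function(elongation = 1, n_processes = 0,
                            process_length = 0.5, process_width = 5,
                            boundary_roughness = 0.2, body_radius = 80,
                            size_cv = 0.18, fine_roughness = 0.04,
                            name = "") {
  stopifnot(elongation >= 1, n_processes >= 0, process_length >= 0,
            process_width > 0, boundary_roughness >= 0,
            boundary_roughness <= 1, body_radius > 0, size_cv >= 0,
            fine_roughness >= 0)
  structure(list(elongation = elongation, n_processes = n_processes,
                 process_length = process_length,
                 process_width = process_width,
                 boundary_roughness = boundary_roughness,
                 body_radius = body_radius, size_cv = size_cv,
                 fine_roughness = fine_roughness, name = name),
            class = "morphotype_spec")
}

#' Default three-morphotype presets
#'
#' Three planted cell classes mirroring the morphotypes recurring in
#' adherent bivalve hemocyte populations: (1) an elongated body with a few
#' long processes, (2) a moderately shaped body with many short processes,
#' (3) a compact, nearly round body with minimal processes.
#'
#' @return named list of three [morphotype_spec()] objects.
#' @export
morphotype_presets <- function() {
  list(
    elongated = morphotype_spec(elongation = 3.6, n_processes = 10,
                                process_length = 0.85, process_width = 6,
                                boundary_roughness = 0.32,
                                body_radius = 84, size_cv = 0.15,
                                fine_roughness = 0.09,
                                name = "elongated"),
    branched = morphotype_spec(elongation = 1.9, n_processes = 4,
                               process_length = 0.40, process_width = 6,
                               boundary_roughness = 0.18,
                               body_radius = 73, size_cv = 0.20,
                               fine_roughness = 0.065,
                               name = "branched"),
    compact = morphotype_spec(elongation = 1.10, n_processes = 2,
                              process_length = 0.30, process_width = 6,
                              boundary_roughness = 0.13,
                              body_radius = 60, size_cv = 0.26,
                              fine_roughness = 0.045,
                              name = "compact"))
}

# periodic midpoint-displacement noise, length 2^levels, scaled to max |.|=1
midpoint_noise <- function(levels = 6) {
  v <- rnorm(4, 0, 1)
  amp <- 0.5
  while (length(v) < 2^levels) {
    n <- length(v)
    nxt <- (v + v[c(2:n, 1)]) / 2 + rnorm(n, 0, amp)
    v <- as.vector(rbind(v, nxt))
    amp <- amp / 2
  }
  v / max(abs(v), 1e-12)
}

# one raster attempt; consumes the caller's RNG stream.
# Every morphotype axis carries per-cell biological scatter: spreading size
# (lognormal, spec$size_cv), elongation, boundary roughness and process
# count (lognormal with fixed CVs), so types overlap the way real adherent
# hemocyte populations do.
draw_cell <- function(spec, canvas) {
  ctr <- (canvas + 1) / 2
  el <- max(1, spec$elongation * exp(rnorm(1, 0, 0.12)))
  rough <- min(0.45, spec$boundary_roughness * exp(rnorm(1, 0, 0.30)))
  fine <- min(0.5 - rough, spec$fine_roughness * exp(rnorm(1, 0, 0.40)))
  n_proc <- if (spec$n_processes > 0)
    max(0L, as.integer(round(spec$n_processes * exp(rnorm(1, 0, 0.35)))))
  else 0L
  rmul <- exp(rnorm(1, 0, spec$size_cv))
  rmax <- canvas / (2.2 * (sqrt(el) + spec$process_length))
  radius <- min(spec$body_radius * rmul, rmax)
  a0 <- radius * sqrt(el)
  b0 <- radius / sqrt(el)
  phi <- runif(1, 0, pi)
  noise <- midpoint_noise(6)
  nn <- length(noise)
  # high-frequency boundary texture: circularly smoothed white noise
  v2 <- rnorm(512)
  noise2 <- stats::filter(c(v2[509:512], v2, v2[1:4]), rep(1 / 5, 5),
                          sides = 2)[5:516]
  noise2 <- as.numeric(noise2) / max(abs(noise2))
  n2 <- length(noise2)

  xs <- seq_len(canvas) - ctr
  X <- matrix(xs, canvas, canvas)
  Y <- matrix(xs, canvas, canvas, byrow = TRUE)
  U <- cos(phi) * X + sin(phi) * Y
  V <- -sin(phi) * X + cos(phi) * Y
  TH <- atan2(V, U)
  RHO <- sqrt(U^2 + V^2)
  rb <- a0 * b0 / sqrt((b0 * cos(TH))^2 + (a0 * sin(TH))^2)
  ni <- 1 + floor((TH + pi) / (2 * pi) * nn) %% nn
  ni2 <- 1 + floor((TH + pi) / (2 * pi) * n2) %% n2
  redge <- rb * (1 + rough * noise[ni] + fine * noise2[ni2])
  px <- (RHO <= redge) * 1L

  if (n_proc > 0) {
    th_p <- runif(n_proc, -pi, pi)
    len_j <- runif(n_proc, 0.8, 1.2)
    for (q in seq_len(n_proc)) {
      th <- th_p[q]
      rb_q <- a0 * b0 / sqrt((b0 * cos(th))^2 + (a0 * sin(th))^2)
      i1 <- 1 + floor((th + pi) / (2 * pi) * nn) %% nn
      redge_q <- rb_q * (1 + rough * noise[i1] + fine * noise2[1 + floor((th + pi) / (2 * pi) * n2) %% n2])
      # root on the noise-free ellipse radius, below any boundary dip
      r0 <- 0.45 * rb_q
      r1 <- redge_q + spec$process_length * radius * len_j[q]
      du <- cos(th); dv <- sin(th)
      # axial/orthogonal coordinates along the process ray
      w0 <- spec$process_width / 2
      sub <- RHO >= r0 - w0 - 1 & RHO <= r1 + 1
      A <- U[sub] * du + V[sub] * dv         # along-ray coordinate
      O <- -U[sub] * dv + V[sub] * du        # across-ray coordinate
      t <- (A - r0) / (r1 - r0)
      wt <- w0 + (0.6 - w0) * pmax(pmin(t, 1), 0)  # taper to ~1 px tip
      hit <- A >= r0 & A <= r1 & abs(O) <= wt
      pv <- px[sub]
      pv[hit] <- 1L
      px[sub] <- pv
    }
  }
  storage.mode(px) <- "integer"
  px
}

#' Generate one synthetic cell silhouette
#'
#' Rasterizes an elliptical body with `n_processes` tapered radial
#' processes rooted on the body and a boundary perturbed by seeded
#' midpoint-displacement noise. Deterministic given `(spec, seed)`;
#' disconnected rasters (possible for extreme specs) are retried with fresh
#' draws from the same stream, then refused.
#'
#' @param spec a [morphotype_spec()].
#' @param seed integer seed.
#' @param canvas canvas side in px (>= 4x body radius).
#' @return a silhouette-variant [binary_shape_image()].
#' @export
generate_cell <- function(spec, seed, canvas = 512) {
  stopifnot(inherits(spec, "morphotype_spec"))
  if (canvas < 4 * spec$body_radius)
    stop("canvas must be at least 4x the body radius")
  with_seed(seed, {
    for (attempt in 1:3) {
      px <- draw_cell(spec, canvas)
      lab <- cf_label_components(px)
      if (max(lab) > 1L) {
        # rasterization of a noisy boundary sheds sub-8-px flecks; they are
        # aliasing debris, not structure, and are removed before the
        # single-component requirement is enforced
        sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
        debris <- which(sizes < 8L & sizes < max(sizes))
        if (length(debris)) px[lab %in% debris] <- 0L
        lab <- cf_label_components(px)
      }
      if (max(lab) == 1L) {
        px <- fill_holes(px)
        return(binary_shape_image(px, "silhouette",
                                  source_id = sprintf("%s_s%d",
                                                      spec$name, seed),
                                  check = FALSE))
      }
    }
    stop("generated raster is disconnected after retries")
  })
}

#' Generate a seeded population of synthetic cells
#'
#' `n_per_type` cells per morphotype with per-cell seeds derived from
#' `seed`, shuffled into a random order with the true labels recorded.
#' Bit-for-bit reproducible from `(specs, n_per_type, seed)`.
#'
#' @param specs list of [morphotype_spec()] objects.
#' @param n_per_type cells per morphotype.
#' @param seed integer seed.
#' @param canvas canvas side in px.
#' @return object of class `synthetic_population`: `images`,
#'   `true_labels`, `specs`, `seed`.
#' @export
generate_population <- function(specs, n_per_type, seed = 1, canvas = 512) {
  stopifnot(length(specs) >= 1)
  n_total <- length(specs) * n_per_type
  labels <- rep(seq_along(specs), each = n_per_type)
  cell_seeds <- seed * 10000L + seq_len(max(n_total, 1L))
  ord <- if (n_total > 0) with_seed(seed, sample.int(n_total)) else integer(0)
  images <- vector("list", n_total)
  for (t in seq_len(n_total)) {
    i <- ord[t]
    images[[t]] <- generate_cell(specs[[labels[i]]], cell_seeds[i], canvas)
    images[[t]]$source_id <- sprintf("cell_%03d_%s", t,
                                     specs[[labels[i]]]$name)
  }
  structure(list(images = images,
                 true_labels = if (n_total > 0) labels[ord] else integer(0),
                 specs = specs, seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population: %d cells, %d morphotypes, seed %d>\n",
              length(x$images), length(x$specs), x$seed))
  invisible(x)
}

#' Analytic reference rasters for estimator validation
#'
#' Deterministic shapes with known dimensions: a filled `disk` (D = 2), a
#' filled `square` (D = 2), an oblique supercover (4-connected) digital
#' `line` (D = 1), the `sierpinski` gasket (D = log 3 / log 2), a triadic
#' `koch` snowflake curve (D = log 4 / log 3), and a seeded
#' `bernoulli_field` (D = 2, nonzero lacunarity). The line and koch curves
#' are returned as outline-variant images; the rest as silhouettes.
#'
#' @param name one of `"disk"`, `"line"`, `"square"`, `"sierpinski"`,
#'   `"koch"`, `"bernoulli_field"`.
#' @param size canvas side in px (a power of 2 for `sierpinski`).
#' @param iterations recursion depth for `sierpinski` (default 7) and
#'   `koch` (default 4).
#' @param seed seed for `bernoulli_field`.
#' @param p fill probability for `bernoulli_field` (default 0.1).
#' @return a [binary_shape_image()] (connectivity check disabled; these are
#'   estimator fixtures, not cells).
#' @export
reference_fractal <- function(name = c("disk", "line", "square",
                                       "sierpinski", "koch",
                                       "bernoulli_field"),
                              size = 512, iterations = NULL, seed = 1,
                              p = 0.1) {
  name <- match.arg(name)
  px <- switch(name,
    disk = {
      r <- size / 2 - 1
      ctr <- (size + 1) / 2
      m <- outer(seq_len(size), seq_len(size),
                 function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
      m * 1L
    },
    square = matrix(1L, size, size),
    line = supercover_line(size, slope = 0.57),
    sierpinski = {
      if (is.null(iterations)) iterations <- 7
      if (bitwAnd(size, size - 1L) != 0L)
        stop("sierpinski needs a power-of-2 size")
      n <- 2^iterations
      if (size %% n != 0L)
        stop("iterations too deep for this size")
      I <- 0:(n - 1)
      blk <- outer(I, I, function(a, b) ifelse(bitwAnd(a, b) == 0, 1L, 0L))
      kronecker(blk, matrix(1L, size %/% n, size %/% n))
    },
    koch = {
      if (is.null(iterations)) iterations <- 4
      koch_raster(size, iterations)
    },
    bernoulli_field = with_seed(seed,
      matrix(rbinom(size * size, 1L, p), size, size)))
  storage.mode(px) <- "integer"
  variant <- if (name %in% c("line", "koch")) "outline" else "silhouette"
  binary_shape_image(px, variant, source_id = name, check = FALSE)
}

# 4-connected (supercover) digital line: no diagonal corner-cutting, so box
# counts scale cleanly as 1/size
supercover_line <- function(L, slope = 0.57) {
  x <- seq_len(L)
  y <- round(1 + slope * (x - 1))
  px <- x; py <- y
  for (i in 2:L) if (y[i] != y[i - 1]) {
    px <- c(px, x[i]); py <- c(py, y[i - 1])
  }
  m <- matrix(0L, L, max(y))
  m[cbind(px, py)] <- 1L
  m
}

# triadic Koch snowflake boundary rasterized by dense sampling of segments
koch_raster <- function(size, iterations) {
  # equilateral triangle, then the standard one-third bump substitution
  pts <- rbind(c(0.5, 0.95), c(0.11, 0.275), c(0.89, 0.275), c(0.5, 0.95))
  for (it in seq_len(iterations)) {
    new <- matrix(NA_real_, 0, 2)
    for (s in seq_len(nrow(pts) - 1)) {
      a <- pts[s, ]; b <- pts[s + 1, ]
      d <- (b - a) / 3
      p1 <- a + d
      p2 <- a + 2 * d
      # outward bump: rotate d by -60 degrees
      bump <- p1 + c(d[1] * 0.5 + d[2] * sqrt(3) / 2,
                     -d[1] * sqrt(3) / 2 + d[2] * 0.5)
      new <- rbind(new, a, p1, bump, p2)
    }
    pts <- rbind(new, pts[nrow(pts), ])
  }
  m <- matrix(0L, size, size)
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ] * (size - 1) + 1
    b <- pts[s + 1, ] * (size - 1) + 1
    nstep <- max(2L, ceiling(max(abs(b - a)) / 0.4))
    t <- seq(0, 1, length.out = nstep)
    m[cbind(pmin(pmax(round(a[1] + t * (b[1] - a[1])), 1), size),
            pmin(pmax(round(a[2] + t * (b[2] - a[2])), 1), size))] <- 1L
  }
  m
}
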