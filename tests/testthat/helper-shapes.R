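# fixture rasters and independent oracles used across the test files

# filled block in an nr x nc canvas
block_raster <- function(nr, nc, rows, cols) {
  m <- matrix(0L, nr, nc)
  m[rows, cols] <- 1L
  m
}

# filled axis-aligned ellipse on pixel centres
ellipse_raster <- function(a, b, pad = 4) {
  nr <- 2 * ceiling(a) + 2 * pad + 1
  nc <- 2 * ceiling(b) + 2 * pad + 1
  cx <- (nr + 1) / 2
  cy <- (nc + 1) / 2
  m <- outer(seq_len(nr), seq_len(nc),
             function(i, j) ((i - cx) / a)^2 + ((j - cy) / b)^2 <= 1)
  storage.mode(m) <- "integer"
  m
}

disk_raster <- function(r, pad = 4) ellipse_raster(r, r, pad)

# asymmetric comma-like blob: large disk with an offset lobe
comma_raster <- function() {
  m <- matrix(0L, 140, 140)
  idx <- which(outer(1:140, 1:140,
                     function(i, j) (i - 60)^2 + (j - 60)^2 <= 35^2 |
                       ((i - 95)^2 + (j - 95)^2 <= 18^2)), arr.ind = TRUE)
  m[idx] <- 1L
  m
}

# exact minimal enclosing circle by exhaustive search over all pairs and
# triples of support points
brute_min_circle <- function(pts) {
  pts <- unique.matrix(pts)
  n <- nrow(pts)
  best <- list(center = pts[1, ], radius = Inf)
  covers <- function(ctr, r) all(sqrt((pts[, 1] - ctr[1])^2 +
                                        (pts[, 2] - ctr[2])^2) <= r + 1e-9)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best$radius && covers(ctr, r)) best <- list(center = ctr, radius = r)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                  c[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
               sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
               sum(c^2) * (b[1] - a[1])) / d
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (r < best$radius && covers(c(ux, uy), r)) best <-
          list(center = c(ux, uy), radius = r)
    }
  }
  best
}

# brute-force Ward merge sequence by direct minimisation of the increase in
# total within-cluster sum of squares
brute_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  ss <- function(rows) {
    if (length(rows) == 1) return(0)
    sum(sweep(X[rows, , drop = FALSE], 2,
              colMeans(X[rows, , drop = FALSE]))^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- ss(c(clusters[[i]], clusters[[j]])) - ss(clusters[[i]]) -
        ss(clusters[[j]])
      if (is.null(best) || d < best$d - 1e-12) best <- list(i = i, j = j, d = d)
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best$i]], clusters[[best$j]])), dss = best$d)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  merges
}

# population of the 21 features from a small seeded synthetic cohort,
# shared by the selection / cluster tests (computed once per test run)
shared_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- generate_population(morphotype_presets(), 15, seed = 101)
      ft <- compute_feature_table(pop$images, sample_stride = 4)
      cache <<- list(pop = pop, features = ft)
    }
    cache
  }
})
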