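# Planar geometry primitives on polygons stored as lists of rings,
# each ring a list(x = numeric, y = numeric), vertices unclosed.
# All coordinates are metres in a planar CRS.

.ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Classify rings of one polygon as outer/hole by containment parity:
# a ring is a hole iff it lies inside an odd number of the other rings.
.ring_holes <- function(rings) {
  k <- length(rings)
  if (k == 1L) return(FALSE)
  vapply(seq_len(k), function(i) {
    inside <- 0L
    for (j in seq_len(k)) {
      if (j == i) next
      # majority vote over strictly-inside vs strictly-outside vertices:
      # touching rings share (numerically perturbed) boundary vertices,
      # so no single vertex is a reliable probe
      s <- sp::point.in.polygon(rings[[i]]$x, rings[[i]]$y,
                                rings[[j]]$x, rings[[j]]$y)
      if (sum(s == 1L) > sum(s == 0L)) inside <- inside + 1L
    }
    inside %% 2L == 1L
  }, logical(1))
}

.poly_area <- function(rings) {
  holes <- .ring_holes(rings)
  a <- vapply(rings, function(r) abs(.ring_signed_area(r)), numeric(1))
  sum(a[!holes]) - sum(a[holes])
}

.ring_centroid <- function(r) {
  x <- r$x; y <- r$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

.poly_centroid <- function(rings) {
  holes <- .ring_holes(rings)
  a <- vapply(rings, function(r) abs(.ring_signed_area(r)), numeric(1))
  a[holes] <- -a[holes]
  cs <- vapply(rings, .ring_centroid, numeric(2))
  c(sum(cs[1, ] * a), sum(cs[2, ] * a)) / sum(a)
}

# Even-odd point-in-polygon over all rings; boundary counts as inside.
.point_in_poly <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  parity <- integer(length(px))
  for (r in rings) {
    s <- sp::point.in.polygon(px, py, r$x, r$y)
    inside <- inside | s >= 2          # on an edge or vertex
    parity <- parity + as.integer(s == 1)
  }
  inside | (parity %% 2L == 1L)
}

.poly_bbox <- function(rings) {
  xs <- unlist(lapply(rings, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(rings, `[[`, "y"), use.names = FALSE)
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Lower bound on the distance between two polygons from their bboxes.
.bbox_dist <- function(a, b) {
  dx <- max(0, max(a["xmin"], b["xmin"]) - min(a["xmax"], b["xmax"]))
  dy <- max(0, max(a["ymin"], b["ymin"]) - min(a["ymax"], b["ymax"]))
  sqrt(dx^2 + dy^2)
}

# Min distance from each of a set of points to a set of segments,
# returned as a single scalar minimum. Segments given by endpoints.
.min_pts_segs <- function(px, py, x1, y1, x2, y2) {
  best <- Inf
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- .Machine$double.eps
  for (i in seq_along(px)) {
    t <- ((px[i] - x1) * ex + (py[i] - y1) * ey) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (x1 + t * ex - px[i])^2 + (y1 + t * ey - py[i])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(best)
}

.poly_segments <- function(rings) {
  xs <- ys <- xe <- ye <- numeric(0)
  for (r in rings) {
    n <- length(r$x)
    j <- c(seq.int(2L, n), 1L)
    xs <- c(xs, r$x); ys <- c(ys, r$y)
    xe <- c(xe, r$x[j]); ye <- c(ye, r$y[j])
  }
  list(x1 = xs, y1 = ys, x2 = xe, y2 = ye)
}

# Edge-to-edge distance between two disjoint polygons. For polygons
# with disjoint interiors the minimum is attained at a vertex of one
# against an edge of the other, so both vertex-vs-segment sweeps suffice.
.poly_min_dist <- function(ringsA, ringsB) {
  sa <- .poly_segments(ringsA)
  sb <- .poly_segments(ringsB)
  min(
    .min_pts_segs(sa$x1, sa$y1, sb$x1, sb$y1, sb$x2, sb$y2),
    .min_pts_segs(sb$x1, sb$y1, sa$x1, sa$y1, sa$x2, sa$y2)
  )
}

# Regular n-gon approximating a disc, scaled so its area is exactly
# `area` (m^2). Used as the circular foraging-area boundary.
.disc_polygon <- function(cx, cy, area, n = 256L) {
  r <- sqrt(area / (0.5 * n * sin(2 * pi / n)))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}
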