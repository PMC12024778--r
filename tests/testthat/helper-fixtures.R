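# Shared fixtures (generated once per test run) and independent
# oracles used to cross-check the package's geometry and statistics.

.fixture_env <- new.env(parent = emptyenv())

# full-size default mosaic and survey, cached across test files
default_fixture <- function() {
  if (is.null(.fixture_env$default)) {
    cfg <- generator_config()
    ls <- generate_landscape(cfg)
    sv <- generate_survey(ls, cfg)
    .fixture_env$default <- list(cfg = cfg, landscape = ls, survey = sv)
  }
  .fixture_env$default
}

# small two-class mosaic for fast end-to-end tests
small_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- generator_config(
      total_area = 40,
      lus_shares = c(forest = 0.45, grassland = 0.35, orchard = 0.1,
                     habitation = 0.1),
      lus_patch_counts = c(forest = 3, grassland = 5, orchard = 4,
                           habitation = 2),
      richness_by_lus = c(forest = 5, grassland = 12, orchard = 4,
                          maize = 3, wasteland = 5, riparian = 10),
      n_cells = 500, plot_spacing = 60, plot_retention = 1,
      rng_seed = 11)
    ls <- generate_landscape(cfg)
    sv <- generate_survey(ls, cfg)
    .fixture_env$small <- list(cfg = cfg, landscape = ls, survey = sv)
  }
  .fixture_env$small
}

# axis-aligned square patch, lower-left corner (x, y), side s
square_poly <- function(x, y, s) {
  cbind(c(x, x + s, x + s, x), c(y, y, y + s, y + s))
}

# random non-overlapping landscape: n unit-ish squares on a jittered
# grid, random LUS labels from `classes`
random_square_landscape <- function(n, classes = c("forest", "grassland"),
                                    cell = 30, side = 10) {
  k <- ceiling(sqrt(n))
  slots <- sample(k * k, n)
  gx <- ((slots - 1) %% k) * cell + runif(n, 0, cell - side - 1)
  gy <- ((slots - 1) %/% k) * cell + runif(n, 0, cell - side - 1)
  polys <- lapply(seq_len(n), function(i)
    square_poly(gx[i], gy[i], runif(1, side / 2, side)))
  landscape(polys, sample(classes, n, replace = TRUE),
            apiary = c(k * cell / 2, k * cell / 2))
}

# ---- independent oracles ---------------------------------------------

# exact distance between two segments p1-p2 and q1-q2 (closed form:
# zero if they intersect, else min endpoint-to-segment distance)
oracle_seg_dist <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 * o2 < 0 && o3 * o4 < 0) return(0)
  pt_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * ab - p)^2))
  }
  min(pt_seg(q1, p1, p2), pt_seg(q2, p1, p2),
      pt_seg(p1, q1, q2), pt_seg(p2, q1, q2))
}

# brute-force edge-to-edge distance between two LUU polygons: all
# segment pairs, no pruning
oracle_poly_dist <- function(ringsA, ringsB) {
  segs <- function(rings) {
    out <- list()
    for (r in rings) {
      n <- length(r$x)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        out[[length(out) + 1L]] <- list(a = c(r$x[i], r$y[i]),
                                        b = c(r$x[j], r$y[j]))
      }
    }
    out
  }
  sa <- segs(ringsA); sb <- segs(ringsB)
  best <- Inf
  for (s1 in sa) for (s2 in sb)
    best <- min(best, oracle_seg_dist(s1$a, s1$b, s2$a, s2$b))
  best
}

# brute-force mean nearest-neighbour distance for one LUS: exhaustive
# O(n^2) pair scan
oracle_enn <- function(ls, lus) {
  idx <- which(luu_lus(ls) == lus)
  if (length(idx) < 2) return(NA_real_)
  rings <- lapply(ls$luus[idx], `[[`, "rings")
  d <- vapply(seq_along(idx), function(i) {
    min(vapply(setdiff(seq_along(idx), i), function(j)
      oracle_poly_dist(rings[[i]], rings[[j]]), numeric(1)))
  }, numeric(1))
  mean(d)
}

# Kruskal-Wallis H from the textbook rank formula with tie correction
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# random one-window phenology calendar for conservation tests
random_calendar <- function() {
  onset <- sample(10:30, 1)
  dur <- sample(1:8, 1)
  end <- min(onset + dur - 1L, 34L)
  wk <- onset:end
  ph <- if (length(wk) == 1) "full"
        else if (length(wk) == 2) c("early", "late")
        else c("early", rep("full", length(wk) - 2), "late")
  data.frame(taxon = "t1", week = wk, phase = ph,
             stringsAsFactors = FALSE)
}
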