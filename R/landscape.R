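#' Land-use classes of the foraging area
#'
#' The eight land-use stations (LUS) recognised by the pipeline. A LUS is
#' the whole (possibly discontinuous) surface under one land use; a Land
#' Use Unit (LUU) is one contiguous patch of a LUS and is the unit at
#' which honey production potential is scored.
#'
#' @return Character vector of the eight LUS labels.
#' @export
lus_levels <- function() {
  c("forest", "grassland", "wasteland", "riparian",
    "cropfield", "maize", "orchard", "habitation")
}

#' Build a landscape of labelled land-use patches
#'
#' A `landscape` is a set of non-overlapping LUU polygons in a planar
#' metric coordinate system (metres), plus the apiary location. Inputs
#' in geographic coordinates must be projected before entry; all
#' downstream distances and areas assume metres.
#'
#' @param polygons list with one element per LUU: either a two-column
#'   matrix of ring vertices (x, y in metres, unclosed) or a list of
#'   such matrices (first and any non-nested rings are outer boundaries,
#'   nested rings are holes; classification is automatic).
#' @param lus character vector of LUS labels, one per polygon; must be
#'   drawn from [lus_levels()].
#' @param apiary numeric length-2, apiary coordinates (m).
#' @param luu_id optional character ids; defaults to `"luu_001"`, ...
#' @param crs_note free-text note asserting the planar metric CRS.
#' @return An object of class `landscape`: a list with `luus` (each a
#'   list with `luu_id`, `lus`, `rings`, `area` in m2, `centroid`),
#'   `apiary`, and `crs_note`.
#' @examples
#' sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' ls <- landscape(list(sq, sq + 200), c("forest", "grassland"),
#'                 apiary = c(150, 50))
#' composition(ls)
#' @export
landscape <- function(polygons, lus, apiary, luu_id = NULL,
                      crs_note = "planar metric coordinates (m)") {
  if (length(polygons) == 0L) stop("landscape must contain at least one LUU")
  if (length(lus) != length(polygons))
    stop("`lus` must have one label per polygon")
  bad <- setdiff(unique(lus), lus_levels())
  if (length(bad))
    stop("unknown LUS label(s): ", paste(bad, collapse = ", "))
  if (is.null(luu_id))
    luu_id <- sprintf("luu_%03d", seq_along(polygons))
  if (anyDuplicated(luu_id)) stop("luu_id values must be unique")
  stopifnot(is.numeric(apiary), length(apiary) == 2L, all(is.finite(apiary)))

  luus <- vector("list", length(polygons))
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    rings <- if (is.matrix(p)) list(list(x = p[, 1], y = p[, 2]))
             else lapply(p, function(m) {
               if (is.matrix(m)) list(x = m[, 1], y = m[, 2]) else m
             })
    for (r in rings) {
      if (length(r$x) < 3L || !all(is.finite(r$x)) || !all(is.finite(r$y)))
        stop("invalid ring in polygon ", luu_id[i])
    }
    area <- .poly_area(rings)
    if (area <= 0) stop("LUU ", luu_id[i], " has non-positive area")
    luus[[i]] <- list(luu_id = luu_id[i], lus = lus[i], rings = rings,
                      area = area, centroid = .poly_centroid(rings))
  }
  structure(list(luus = luus, apiary = as.numeric(apiary),
                 crs_note = crs_note),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  tab <- table(factor(luu_lus(x), levels = lus_levels()))
  cat("landscape:", length(x$luus), "LUUs,",
      format(round(total_area(x), 1)), "ha total\n")
  cat("  apiary at (", paste(round(x$apiary, 1), collapse = ", "), ") m\n",
      sep = "")
  comp <- composition(x)
  for (l in names(tab)[tab > 0])
    cat(sprintf("  %-10s %4d patches  %5.1f%%\n", l, tab[[l]],
                comp[[l]]))
  invisible(x)
}

#' @export
plot.landscape <- function(x, col = NULL, border = "grey30", ...) {
  if (is.null(col)) {
    pal <- c(forest = "#33691e", grassland = "#9ccc65",
             wasteland = "#bcaaa4", riparian = "#00838f",
             cropfield = "#ffe082", maize = "#f9a825",
             orchard = "#ec407a", habitation = "grey75")
    col <- pal[luu_lus(x)]
  }
  bb <- Reduce(function(a, b) c(xmin = min(a["xmin"], b["xmin"]),
                                xmax = max(a["xmax"], b["xmax"]),
                                ymin = min(a["ymin"], b["ymin"]),
                                ymax = max(a["ymax"], b["ymax"])),
               lapply(x$luus, function(u) .poly_bbox(u$rings)))
  graphics::plot(NA, xlim = bb[c("xmin", "xmax")],
                 ylim = bb[c("ymin", "ymax")], asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  for (i in seq_along(x$luus)) {
    for (r in x$luus[[i]]$rings)
      graphics::polygon(r$x, r$y, col = col[i], border = border)
  }
  graphics::points(x$apiary[1], x$apiary[2], pch = 8, cex = 1.5, lwd = 2)
  invisible(x)
}

#' Total landscape area in hectares
#' @param ls a [landscape()].
#' @return Numeric scalar, hectares.
#' @export
total_area <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  sum(luu_areas(ls)) / 1e4
}

#' @rdname total_area
#' @return `luu_areas`: named numeric vector of LUU areas in m2.
#' @export
luu_areas <- function(ls) {
  stats::setNames(vapply(ls$luus, `[[`, numeric(1), "area"),
                  vapply(ls$luus, `[[`, character(1), "luu_id"))
}

#' @rdname total_area
#' @return `luu_lus`: named character vector of LUS labels per LUU.
#' @export
luu_lus <- function(ls) {
  stats::setNames(vapply(ls$luus, `[[`, character(1), "lus"),
                  vapply(ls$luus, `[[`, character(1), "luu_id"))
}

#' Check structural invariants of a landscape
#'
#' Verifies that every LUU has positive area and a known LUS label, that
#' stored areas agree with their polygons, and (optionally) that LUU
#' interiors do not overlap beyond a small tolerance.
#'
#' @param ls a [landscape()].
#' @param check_overlap logical; pairwise polygon intersection test
#'   (bounding-box pre-filtered). Quadratic in patch count, so off by
#'   default for large mosaics.
#' @param overlap_tol maximum tolerated pairwise intersection area, m2.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_landscape <- function(ls, check_overlap = FALSE,
                               overlap_tol = 1e-6) {
  stopifnot(inherits(ls, "landscape"))
  for (u in ls$luus) {
    if (u$area <= 0) stop("LUU ", u$luu_id, ": non-positive area")
    if (!u$lus %in% lus_levels()) stop("LUU ", u$luu_id, ": unknown LUS")
    pa <- .poly_area(u$rings)
    if (abs(pa - u$area) > 1e-6 * max(1, u$area))
      stop("LUU ", u$luu_id, ": stored area disagrees with polygon")
  }
  if (check_overlap && length(ls$luus) > 1L) {
    bb <- lapply(ls$luus, function(u) .poly_bbox(u$rings))
    n <- length(ls$luus)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (.bbox_dist(bb[[i]], bb[[j]]) > 0) next
      ov <- polyclip::polyclip(ls$luus[[i]]$rings, ls$luus[[j]]$rings,
                               op = "intersection")
      a <- if (length(ov)) sum(vapply(ov, function(r)
             abs(.ring_signed_area(r)), numeric(1))) else 0
      if (a > overlap_tol)
        stop("LUUs ", ls$luus[[i]]$luu_id, " and ", ls$luus[[j]]$luu_id,
             " overlap by ", signif(a, 3), " m2")
    }
  }
  invisible(TRUE)
}

#' Write and read a landscape as GeoJSON
#'
#' Polygons carry `luu_id` and `lus` properties; the apiary is stored as
#' a Point feature with property `kind = "apiary"`. Coordinates are
#' written verbatim (planar metres).
#'
#' @param ls a [landscape()].
#' @param path file path of the GeoJSON document.
#' @return `write_landscape_geojson` returns `path` invisibly;
#'   `read_landscape_geojson` returns a [landscape()].
#' @export
write_landscape_geojson <- function(ls, path) {
  stopifnot(inherits(ls, "landscape"))
  feat <- lapply(ls$luus, function(u) {
    coords <- lapply(u$rings, function(r) {
      m <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))   # closed rings
      lapply(seq_len(nrow(m)), function(i) m[i, ])
    })
    list(type = "Feature",
         properties = list(luu_id = u$luu_id, lus = u$lus,
                           area_m2 = u$area),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  feat[[length(feat) + 1L]] <- list(
    type = "Feature",
    properties = list(kind = "apiary"),
    geometry = list(type = "Point", coordinates = ls$apiary))
  doc <- list(type = "FeatureCollection", crs_note = ls$crs_note,
              features = feat)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape_geojson
#' @export
read_landscape_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  polys <- list(); lus <- character(0); ids <- character(0)
  apiary <- NULL
  for (f in doc$features) {
    g <- f$geometry
    if (identical(g$type, "Point")) {
      apiary <- as.numeric(unlist(g$coordinates))
    } else if (identical(g$type, "Polygon")) {
      rings <- lapply(g$coordinates, function(ring) {
        m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
        m[-nrow(m), , drop = FALSE]                # drop closing vertex
      })
      polys[[length(polys) + 1L]] <- rings
      lus <- c(lus, f$properties$lus)
      ids <- c(ids, f$properties$luu_id)
    }
  }
  if (is.null(apiary)) stop("GeoJSON has no apiary Point feature")
  landscape(polys, lus, apiary, luu_id = ids,
            crs_note = if (!is.null(doc$crs_note)) doc$crs_note
                       else "planar metric coordinates (m)")
}
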