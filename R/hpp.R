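# The honey production potential (HPP) engine. Per LUU and week,
#   HPP = max(0, 1 - D/10000) * S * sum_t (Rt/100 * pnht(t, week))
# with D the LUU centroid-to-apiary distance (m), S the LUU area (ha),
# Rt the percent cover of taxon t on the LUU and pnht its weekly
# nectariferous potential (kg/ha/week). The distance factor is clamped
# at zero beyond 10 km so HPP is never negative; within a 1.5 km
# foraging radius the clamp is inert.

.distance_factor <- function(D) pmax(0, 1 - D / 1e4)

# taxon-by-week pnht matrix (kg/ha/week); excluded taxa give zero rows
.pnht_matrix <- function(traits, calendar) {
  taxa <- rownames(calendar)
  pnt <- traits$pnt_kg_ha[match(taxa, traits$taxon)]
  pnt[is.na(pnt)] <- 0
  sf <- flowering_duration(calendar)
  intens <- matrix(flowering_intensity(as.vector(calendar)),
                   nrow = nrow(calendar),
                   dimnames = dimnames(calendar))
  out <- (pnt / pmax(sf, 1L)) * intens
  out[sf == 0L, ] <- 0
  out
}

#' Weekly honey production potential of one LUU
#'
#' Evaluates the HPP score for a single LUU and week from its assigned
#' taxon cover, the taxon traits and the phenology calendars. Taxa
#' without a nectariferous potential are skipped.
#'
#' @param luu one element of `landscape$luus` (list with `area`,
#'   `centroid`).
#' @param apiary numeric length-2 apiary coordinates (m).
#' @param cover data frame `taxon`, `Rt_pct` for this LUU (percent
#'   cover in `[0, 100]`).
#' @param traits data frame `taxon`, `pnt_kg_ha` (NA = excluded).
#' @param calendar phase matrix from [phenology_calendar()].
#' @param week week number(s) in 10-34.
#' @return HPP in kg/week, one value per requested week.
#' @export
luu_weekly_hpp <- function(luu, apiary, cover, traits, calendar, week) {
  stopifnot(all(week %in% hpp_weeks()))
  if (nrow(cover) && (any(cover$Rt_pct < 0) || any(cover$Rt_pct > 100)))
    stop("cover percentages must lie in [0, 100]")
  D <- sqrt(sum((luu$centroid - apiary)^2))
  S <- luu$area / 1e4
  if (nrow(cover) == 0L) return(rep(0, length(week)))
  pnht <- .pnht_matrix(traits, calendar)
  idx <- match(cover$taxon, rownames(pnht))
  ok <- !is.na(idx)
  if (!any(ok)) return(rep(0, length(week)))
  terms <- (cover$Rt_pct[ok] / 100) *
    pnht[idx[ok], as.character(week), drop = FALSE]
  unname(.distance_factor(D) * S * colSums(terms))
}

#' Compute the full weekly HPP surface
#'
#' Scores every LUU for every week 10-34 and closes the bookkeeping in
#' three directions: per land-use class (`per_lus`, kg/week, and
#' `per_area`, kg/ha/week dividing by the class's total area), per
#' taxon (`per_taxon`, cumulative kg over the season; `per_taxon_week`
#' and `per_taxon_lus` for finer slices), and per LUU (`values`).
#' Landscape totals, per-LUS sums and per-taxon sums agree exactly.
#'
#' @param landscape a [landscape()].
#' @param assignments plot assignment from [assign_observations()].
#' @param cover per-LUU cover table from [luu_cover()].
#' @param traits data frame `taxon`, `pnt_kg_ha`.
#' @param phenology long phenology table (see [phenology_calendar()]).
#' @return An object of class `hpp_surface`.
#' @seealso [hpp()] for the one-call interface.
#' @export
compute_surface <- function(landscape, assignments, cover, traits,
                            phenology) {
  stopifnot(inherits(landscape, "landscape"))
  ids <- vapply(landscape$luus, `[[`, character(1), "luu_id")
  if (!all(ids %in% names(assignments)))
    stop("assignments must cover every LUU")
  wk <- hpp_weeks()
  taxa <- sort(unique(traits$taxon))
  calendar <- phenology_calendar(phenology, taxa = taxa)
  pnht <- .pnht_matrix(traits, calendar)

  lus <- luu_lus(landscape)
  lus_present <- intersect(lus_levels(), unique(lus))
  values <- matrix(0, length(ids), length(wk),
                   dimnames = list(ids, wk))
  per_taxon_week <- matrix(0, length(taxa), length(wk),
                           dimnames = list(taxa, wk))
  per_taxon_lus <- matrix(0, length(taxa), length(lus_present),
                          dimnames = list(taxa, lus_present))
  D <- numeric(length(ids))
  for (i in seq_along(ids)) {
    u <- landscape$luus[[i]]
    D[i] <- sqrt(sum((u$centroid - landscape$apiary)^2))
    cv <- cover[cover$luu_id == ids[i], ]
    if (nrow(cv) == 0L) next
    idx <- match(cv$taxon, taxa)
    ok <- !is.na(idx)
    if (!any(ok)) next
    f <- .distance_factor(D[i]) * (u$area / 1e4)
    terms <- f * (cv$Rt_pct[ok] / 100) * pnht[idx[ok], , drop = FALSE]
    values[i, ] <- colSums(terms)
    per_taxon_week[idx[ok], ] <- per_taxon_week[idx[ok], , drop = FALSE] +
      terms
    per_taxon_lus[idx[ok], u$lus] <- per_taxon_lus[idx[ok], u$lus] +
      rowSums(terms)
  }
  per_lus <- rowsum(values, lus[ids])[lus_present, , drop = FALSE]
  lus_area_ha <- tapply(luu_areas(landscape), lus, sum)[lus_present] / 1e4
  per_area <- per_lus / as.numeric(lus_area_ha)
  structure(list(
    values = values, per_lus = per_lus, per_area = per_area,
    per_taxon = rowSums(per_taxon_week),
    per_taxon_week = per_taxon_week, per_taxon_lus = per_taxon_lus,
    weeks = wk,
    luu_info = data.frame(luu_id = ids, lus = unname(lus[ids]),
                          area_ha = unname(luu_areas(landscape)) / 1e4,
                          D_m = D, stringsAsFactors = FALSE)),
    class = "hpp_surface")
}

#' One-call HPP analysis of a landscape and survey
#'
#' Chains [assign_observations()], [luu_cover()] and
#' [compute_surface()].
#'
#' @param landscape a [landscape()].
#' @param survey a `melliflow_survey` (from [generate_survey()] or
#'   [read_survey_csv()]).
#' @param same_lus_only passed to [assign_observations()].
#' @return An `hpp_surface`.
#' @examples
#' cfg <- generator_config(total_area = 30,
#'   lus_shares = c(forest = 0.5, grassland = 0.5),
#'   lus_patch_counts = c(forest = 3, grassland = 4),
#'   n_cells = 400, plot_spacing = 60, rng_seed = 7)
#' ls <- generate_landscape(cfg)
#' surf <- hpp(ls, generate_survey(ls, cfg))
#' summary(surf)
#' @export
hpp <- function(landscape, survey, same_lus_only = TRUE) {
  stopifnot(inherits(survey, "melliflow_survey"))
  asg <- assign_observations(landscape, survey$plots,
                             same_lus_only = same_lus_only)
  cov <- luu_cover(asg, survey$records)
  compute_surface(landscape, asg, cov, survey$traits, survey$phenology)
}

#' @export
print.hpp_surface <- function(x, ...) {
  tot <- colSums(x$values)
  cat("hpp_surface:", nrow(x$values), "LUUs x", length(x$weeks),
      "weeks\n")
  cat("  season total ", format(round(sum(tot), 1)), " kg; peak week ",
      x$weeks[which.max(tot)], " (", format(round(max(tot), 1)),
      " kg)\n", sep = "")
  invisible(x)
}

#' @export
summary.hpp_surface <- function(object, ...) {
  per <- hpp_periods(object)
  cat("Weekly HPP by land-use class (kg), summed per period:\n")
  print(round(per, 1))
  top <- rank_taxa(object, 5)
  cat("\nTop taxa (cumulative kg):\n")
  print(round(top, 1))
  invisible(list(periods = per, top_taxa = top))
}

#' @export
plot.hpp_surface <- function(x, ...) {
  tot <- t(x$per_lus)
  graphics::matplot(x$weeks, tot, type = "l", lty = 1, lwd = 2,
                    xlab = "week", ylab = "HPP (kg/week)", ...)
  graphics::legend("topright", legend = colnames(tot), lty = 1, lwd = 2,
                   col = seq_len(ncol(tot)), cex = 0.8, bty = "n")
  invisible(x)
}

#' Seasonal period totals of an HPP surface
#'
#' Sums the per-LUS weekly HPP over configurable week-range bins. The
#' defaults follow the four phases of the season: early spring (10-15),
#' mid spring (16-19), early summer peak (20-27) and late summer
#' (28-34).
#'
#' @param surface an `hpp_surface`.
#' @param bins named list of integer week vectors.
#' @return Matrix lus x period, kg.
#' @export
hpp_periods <- function(surface,
                        bins = list(p1_w10_15 = 10:15, p2_w16_19 = 16:19,
                                    p3_w20_27 = 20:27,
                                    p4_w28_34 = 28:34)) {
  stopifnot(inherits(surface, "hpp_surface"))
  vapply(bins, function(w)
    rowSums(surface$per_lus[, as.character(w), drop = FALSE]),
    numeric(nrow(surface$per_lus)))
}

#' Rank taxa by cumulative HPP contribution
#'
#' @param surface an `hpp_surface`.
#' @param k number of taxa to return (full list if larger than the
#'   taxon count). Ties are broken alphabetically.
#' @return Named numeric vector, descending cumulative kg.
#' @export
rank_taxa <- function(surface, k) {
  stopifnot(inherits(surface, "hpp_surface"), k >= 1)
  v <- surface$per_taxon
  ord <- order(-v, names(v))
  v[ord][seq_len(min(k, length(v)))]
}

#' Land-use share of a taxon's cumulative HPP
#'
#' How a taxon's seasonal HPP contribution splits across land-use
#' classes (shares sum to 100).
#'
#' @param surface an `hpp_surface`.
#' @param taxon taxon name with nonzero cumulative contribution.
#' @return Named numeric vector, percent per LUS.
#' @export
lus_share_of_taxon <- function(surface, taxon) {
  stopifnot(inherits(surface, "hpp_surface"))
  if (!taxon %in% rownames(surface$per_taxon_lus))
    stop("unknown taxon: ", taxon)
  v <- surface$per_taxon_lus[taxon, ]
  if (sum(v) <= 0)
    stop("taxon '", taxon, "' has zero cumulative HPP; shares undefined")
  100 * v / sum(v)
}

#' Rasterize one week of the HPP surface
#'
#' Regular grid over the landscape bounding box; each cell takes the
#' HPP of the LUU containing its centre, `NA` outside every LUU.
#'
#' @param surface an `hpp_surface`.
#' @param landscape the [landscape()] the surface was computed on.
#' @param week one week in 10-34.
#' @param cell_size cell edge, metres.
#' @return Object of class `hpp_raster`: list with `values` (matrix,
#'   rows north to south), `xllcorner`, `yllcorner`, `cell_size`,
#'   `week`.
#' @export
rasterize_hpp <- function(surface, landscape, week, cell_size) {
  stopifnot(inherits(surface, "hpp_surface"), cell_size > 0,
            length(week) == 1L, week %in% surface$weeks)
  bb <- Reduce(function(a, b) c(xmin = min(a["xmin"], b["xmin"]),
                                xmax = max(a["xmax"], b["xmax"]),
                                ymin = min(a["ymin"], b["ymin"]),
                                ymax = max(a["ymax"], b["ymax"])),
               lapply(landscape$luus, function(u) .poly_bbox(u$rings)))
  nx <- max(1L, ceiling((bb[["xmax"]] - bb[["xmin"]]) / cell_size))
  ny <- max(1L, ceiling((bb[["ymax"]] - bb[["ymin"]]) / cell_size))
  cx <- bb[["xmin"]] + (seq_len(nx) - 0.5) * cell_size
  cy <- bb[["ymin"]] + (seq_len(ny) - 0.5) * cell_size
  luu_bb <- lapply(landscape$luus, function(u) .poly_bbox(u$rings))
  wv <- surface$values[, as.character(week)]
  vals <- matrix(NA_real_, nrow = ny, ncol = nx)
  for (r in seq_len(ny)) {
    y <- cy[ny - r + 1L]                       # row 1 = north
    for (c in seq_len(nx)) {
      x <- cx[c]
      for (i in seq_along(landscape$luus)) {
        b <- luu_bb[[i]]
        if (x < b["xmin"] || x > b["xmax"] ||
            y < b["ymin"] || y > b["ymax"]) next
        if (.point_in_poly(x, y, landscape$luus[[i]]$rings)) {
          vals[r, c] <- wv[[landscape$luus[[i]]$luu_id]]
          break
        }
      }
    }
  }
  structure(list(values = vals, xllcorner = bb[["xmin"]],
                 yllcorner = bb[["ymin"]], cell_size = cell_size,
                 week = week),
            class = "hpp_raster")
}

#' Write an HPP raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced format readable by QGIS and GDAL.
#'
#' @param raster an `hpp_raster`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  stopifnot(inherits(raster, "hpp_raster"))
  v <- raster$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", raster$xllcorner),
    paste("yllcorner", raster$yllcorner),
    paste("cellsize", raster$cell_size),
    "NODATA_value -9999"), con)
  v[is.na(v)] <- -9999
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write one week of the HPP surface as GeoJSON
#'
#' LUU polygons carrying `luu_id`, `lus` and `hpp_kg` properties.
#'
#' @inheritParams rasterize_hpp
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hpp_geojson <- function(surface, landscape, week, path) {
  stopifnot(inherits(surface, "hpp_surface"), week %in% surface$weeks)
  wv <- surface$values[, as.character(week)]
  feat <- lapply(landscape$luus, function(u) {
    coords <- lapply(u$rings, function(r) {
      m <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
      lapply(seq_len(nrow(m)), function(i) m[i, ])
    })
    list(type = "Feature",
         properties = list(luu_id = u$luu_id, lus = u$lus,
                           week = week, hpp_kg = wv[[u$luu_id]]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
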