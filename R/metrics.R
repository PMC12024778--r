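# Landscape composition and fragmentation indices (Fragstats-style:
# mean patch area, patch density, Euclidean nearest neighbour).

#' Land-use composition of a landscape
#'
#' Percentage of the total landscape area under each LUS.
#'
#' @param ls a [landscape()].
#' @return Named numeric vector (percent), summing to 100.
#' @export
composition <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  a <- luu_areas(ls)
  if (length(a) == 0L) stop("empty landscape")
  by_lus <- tapply(a, luu_lus(ls), sum)
  out <- c(100 * by_lus / sum(a))   # plain named vector
  out[order(-out)]
}

#' Mean patch area of a land-use class
#'
#' Si, the mean LUU surface for a LUS, in hectares, with the sample
#' standard deviation (n - 1; reported as 0 for a single patch).
#'
#' @param ls a [landscape()].
#' @param lus one LUS label.
#' @return Named numeric `c(Si_ha, sd_ha)`.
#' @export
mean_patch_area <- function(ls, lus) {
  a <- luu_areas(ls)[luu_lus(ls) == lus] / 1e4
  if (length(a) == 0L) stop("no LUU with LUS '", lus, "'")
  c(Si_ha = mean(a), sd_ha = if (length(a) > 1L) stats::sd(a) else 0)
}

#' Patch density of a land-use class
#'
#' Dti, the number of LUUs of a LUS per 100 ha of total landscape:
#' `Dti = ni / A * 10000 * 100` with A the total landscape area in m2.
#'
#' @inheritParams mean_patch_area
#' @return Numeric scalar, LUU per 100 ha.
#' @export
patch_density <- function(ls, lus) {
  A <- sum(luu_areas(ls))
  if (A <= 0) stop("landscape has zero area")
  ni <- sum(luu_lus(ls) == lus)
  ni / A * 1e4 * 100
}

#' Mean Euclidean nearest-neighbour distance of a land-use class
#'
#' For each LUU of the class, the edge-to-edge distance to the nearest
#' other LUU of the same class (the Fragstats ENN definition); averaged
#' with its sample standard deviation. With fewer than two patches the
#' index is undefined and `NA` is returned with a warning, matching
#' Fragstats behaviour.
#'
#' @inheritParams mean_patch_area
#' @return Named numeric `c(ENNi_m, sd_m)`, or `NA`s if ni < 2.
#' @export
mean_nearest_neighbor <- function(ls, lus) {
  d <- nearest_neighbor_distances(ls, lus)
  if (all(is.na(d))) return(c(ENNi_m = NA_real_, sd_m = NA_real_))
  c(ENNi_m = mean(d), sd_m = if (length(d) > 1L) stats::sd(d) else 0)
}

#' @rdname mean_nearest_neighbor
#' @return `nearest_neighbor_distances`: numeric vector of per-patch
#'   nearest-neighbour distances (m), named by luu_id.
#' @export
nearest_neighbor_distances <- function(ls, lus) {
  idx <- which(luu_lus(ls) == lus)
  if (length(idx) < 2L) {
    warning("ENN undefined for LUS '", lus, "' (fewer than 2 patches)")
    return(stats::setNames(rep(NA_real_, length(idx)),
                           names(luu_areas(ls))[idx]))
  }
  rings <- lapply(ls$luus[idx], `[[`, "rings")
  bb <- lapply(rings, .poly_bbox)
  n <- length(idx)
  d <- matrix(Inf, n, n)
  # bbox distance is a lower bound on the true edge-to-edge distance;
  # process pairs in increasing bound order and stop once the bound
  # exceeds both patches' current best
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    lb <- .bbox_dist(bb[[i]], bb[[j]])
    if (lb >= min(d[i, ]) && lb >= min(d[j, ])) next
    d[i, j] <- d[j, i] <- .poly_min_dist(rings[[i]], rings[[j]])
  }
  stats::setNames(apply(d, 1L, min),
                  vapply(ls$luus[idx], `[[`, character(1), "luu_id"))
}

#' Landscape structure summary table
#'
#' Per-LUS composition and fragmentation metrics: patch count, mean
#' patch area +/- SD, patch density per 100 ha, mean edge-to-edge
#' nearest-neighbour distance +/- SD, and percent share of total area.
#'
#' @param ls a [landscape()].
#' @return A data frame with one row per LUS present, columns `lus`,
#'   `n_luu`, `Si_ha`, `Si_sd`, `Dti`, `ENNi_m`, `ENNi_sd`,
#'   `share_pct`.
#' @examples
#' cfg <- generator_config(total_area = 20,
#'   lus_shares = c(forest = 0.6, grassland = 0.4),
#'   lus_patch_counts = c(forest = 2, grassland = 3),
#'   n_cells = 300, rng_seed = 1)
#' landscape_metrics(generate_landscape(cfg))
#' @export
landscape_metrics <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  present <- intersect(lus_levels(), unique(luu_lus(ls)))
  comp <- composition(ls)
  rows <- lapply(present, function(l) {
    si <- mean_patch_area(ls, l)
    enn <- suppressWarnings(mean_nearest_neighbor(ls, l))
    data.frame(lus = l, n_luu = sum(luu_lus(ls) == l),
               Si_ha = si[["Si_ha"]], Si_sd = si[["sd_ha"]],
               Dti = patch_density(ls, l),
               ENNi_m = enn[["ENNi_m"]], ENNi_sd = enn[["sd_m"]],
               share_pct = comp[[l]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
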