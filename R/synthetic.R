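#' Configuration for the synthetic foraging-area generator
#'
#' Defaults reproduce the study conditions the pipeline was built
#' around: a 707 ha circular foraging area (1.5 km radius) whose
#' land-use composition, per-class patch counts, survey design (150 m
#' systematic grid, habitation and non-maize cropfields unsurveyed,
#' roughly half of candidate points accessible in the field) and
#' species-richness contrasts match a heterogeneous peripannonian
#' mosaic of forest, grassland, orchards, crops, wasteland and
#' stream-bound riparian corridors.
#'
#' @param total_area total landscape area, hectares.
#' @param lus_shares named fractions of `total_area` per LUS; must sum
#'   to 1 (to 1e-9).
#' @param lus_patch_counts named integer LUU counts per LUS; every LUS
#'   with nonzero share needs at least one patch.
#' @param species_pool_size size of the regional taxon pool.
#' @param richness_by_lus named mean species per observation plot for
#'   the surveyed LUSs.
#' @param community_size named number of pool taxa occurring in each
#'   surveyed LUS (drives total per-LUS richness).
#' @param pnt_range (min, max) annual nectariferous potential, kg/ha;
#'   values are drawn log-uniformly because published potentials span
#'   orders of magnitude.
#' @param pnt_missing_rate fraction of taxa with no published potential
#'   at species or genus level; they are excluded from HPP but kept in
#'   richness.
#' @param flowering_onset_range (week, week) admissible onset weeks.
#' @param flowering_duration_range (weeks, weeks) admissible flowering
#'   durations.
#' @param plot_spacing systematic survey grid spacing, metres.
#' @param plot_retention probability that a candidate grid point is
#'   accessible and studied (emulates field drop-out).
#' @param n_cells number of Voronoi cells the mosaic is built from;
#'   controls patch-boundary granularity.
#' @param rng_seed integer seed; identical config + seed gives
#'   identical landscape, plots, traits and calendars.
#' @return A validated object of class `generator_config`.
#' @seealso [generate_landscape()], [generate_survey()]
#' @export
generator_config <- function(
    total_area = 707,
    lus_shares = c(forest = 0.363, grassland = 0.261, wasteland = 0.0906,
                   riparian = 0.0171, cropfield = 0.0417, maize = 0.0404,
                   orchard = 0.0611, habitation = 0.1251),
    lus_patch_counts = c(forest = 40, grassland = 114, wasteland = 38,
                         riparian = 13, cropfield = 43, maize = 49,
                         orchard = 132, habitation = 70),
    species_pool_size = 160,
    richness_by_lus = c(forest = 5.39, grassland = 14.4, wasteland = 5.78,
                        riparian = 16.7, orchard = 5, maize = 3),
    community_size = c(forest = 66, grassland = 84, wasteland = 50,
                       riparian = 69, orchard = 45, maize = 30),
    pnt_range = c(1, 1000),
    pnt_missing_rate = 0.1,
    flowering_onset_range = c(10, 30),
    flowering_duration_range = c(2, 8),
    plot_spacing = 150,
    plot_retention = 0.54,
    n_cells = 6000,
    rng_seed = 42) {
  cfg <- structure(
    list(total_area = total_area, lus_shares = lus_shares,
         lus_patch_counts = lus_patch_counts,
         species_pool_size = as.integer(species_pool_size),
         richness_by_lus = richness_by_lus,
         community_size = community_size,
         pnt_range = pnt_range, pnt_missing_rate = pnt_missing_rate,
         flowering_onset_range = as.integer(flowering_onset_range),
         flowering_duration_range = as.integer(flowering_duration_range),
         plot_spacing = plot_spacing, plot_retention = plot_retention,
         n_cells = as.integer(n_cells), rng_seed = as.integer(rng_seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param cfg a `generator_config`.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  sh <- cfg$lus_shares
  if (any(sh < 0 | sh > 1)) stop("lus_shares must lie in [0, 1]")
  if (abs(sum(sh) - 1) > 1e-9) stop("lus_shares must sum to 1 (within 1e-9)")
  bad <- setdiff(names(sh), lus_levels())
  if (length(bad)) stop("unknown LUS in lus_shares: ", paste(bad, collapse = ", "))
  cnt <- cfg$lus_patch_counts[names(sh)[sh > 0]]
  if (any(is.na(cnt)) || any(cnt < 1))
    stop("every LUS with nonzero share needs a patch count >= 1")
  if (cfg$total_area <= 0) stop("total_area must be positive")
  on <- cfg$flowering_onset_range
  du <- cfg$flowering_duration_range
  if (on[1] < 10 || on[2] > 34 || on[1] > on[2])
    stop("flowering_onset_range must lie within weeks 10-34")
  if (du[1] < 1 || du[1] > du[2])
    stop("flowering_duration_range must be >= 1 week and ordered")
  if (cfg$pnt_range[1] <= 0 || cfg$pnt_range[1] > cfg$pnt_range[2])
    stop("pnt_range must be positive and ordered")
  invisible(TRUE)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:", x$total_area, "ha,",
      sum(x$lus_patch_counts[names(x$lus_shares)[x$lus_shares > 0]]),
      "patches,", x$species_pool_size, "taxa, seed", x$rng_seed, "\n")
  invisible(x)
}

# ---- mosaic construction ---------------------------------------------

# One shared integer grid (1 micrometre, origin 0) for every polygon
# boolean operation, so edges shared between neighbouring cells round
# identically and patches tile without slivers or overlaps.
.pc_eps <- 1e-6

.pc <- function(A, B, op) {
  polyclip::polyclip(A, B, op = op, eps = .pc_eps, x0 = 0, y0 = 0)
}

# Voronoi tessellation of the circular region into n_cells cells:
# returns cell polygons (clipped to the disc), areas, centers and the
# Delaunay adjacency list.
.voronoi_cells <- function(total_area_m2, n_cells) {
  disc <- .disc_polygon(0, 0, total_area_m2)
  R <- max(disc$x)
  r_in <- min(sqrt(disc$x^2 + disc$y^2))   # apothem of the n-gon
  # uniform points in the disc
  u <- stats::runif(n_cells); th <- stats::runif(n_cells, 0, 2 * pi)
  px <- 0.98 * R * sqrt(u) * cos(th)
  py <- 0.98 * R * sqrt(u) * sin(th)
  dd <- deldir::deldir(px, py, rw = c(-R, R, -R, R) * 1.01)
  tl <- deldir::tile.list(dd)
  cells <- vector("list", n_cells)
  areas <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    cell <- list(x = tl[[i]]$x, y = tl[[i]]$y)
    if (any(cell$x^2 + cell$y^2 > r_in^2)) {
      clip <- .pc(list(cell), list(disc), "intersection")
      if (length(clip) == 0L) { cells[[i]] <- NULL; areas[i] <- 0; next }
      cell <- clip[[which.max(vapply(clip, function(r)
        abs(.ring_signed_area(r)), numeric(1)))]]
    }
    cells[[i]] <- cell
    areas[i] <- abs(.ring_signed_area(cell))
  }
  adj <- vector("list", n_cells)
  e1 <- dd$delsgs$ind1; e2 <- dd$delsgs$ind2
  for (k in seq_along(e1)) {
    adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
    adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
  }
  list(cells = cells, areas = areas, cx = px, cy = py, adj = adj)
}

# Grow one patch from `seed` over free cells. `owner` is the cell ->
# patch map (0 = free). Compact growth adds the frontier cell nearest
# the seed; `stream` (unit vector) switches to corridor growth that
# minimises distance to the stream line through the seed.
.grow_patch <- function(seed, target, patch_id, owner, vor, stream = NULL) {
  cells <- seed
  area <- vor$areas[seed]
  owner[seed] <- patch_id
  sx <- vor$cx[seed]; sy <- vor$cy[seed]
  repeat {
    frontier <- unique(unlist(vor$adj[cells], use.names = FALSE))
    frontier <- frontier[owner[frontier] == 0L]
    if (length(frontier) == 0L) break
    if (is.null(stream)) {
      score <- (vor$cx[frontier] - sx)^2 + (vor$cy[frontier] - sy)^2
    } else {
      # perpendicular distance to the stream line, plus a mild pull
      # along it so the corridor extends instead of thickening
      dx <- vor$cx[frontier] - sx; dy <- vor$cy[frontier] - sy
      perp <- abs(dx * stream[2] - dy * stream[1])
      score <- perp * 4 - abs(dx * stream[1] + dy * stream[2])
    }
    nxt <- frontier[which.min(score)]
    # stop when adding the next cell would overshoot more than staying
    if (abs(area + vor$areas[nxt] - target) >= abs(area - target)) break
    owner[nxt] <- patch_id
    cells <- c(cells, nxt)
    area <- area + vor$areas[nxt]
  }
  list(owner = owner, cells = cells, area = area)
}

#' Generate a synthetic land-use mosaic
#'
#' Tessellates a circular foraging area into Voronoi cells, then grows
#' contiguous patches over the cells so that per-LUS patch counts are
#' hit exactly and per-LUS summed areas match the configured shares to
#' within the tessellation granularity (about 2 percent). Riparian
#' patches are grown as elongated corridors along a random stream
#' direction; all other patches grow compactly. The apiary is placed at
#' the region centroid.
#'
#' @param config a [generator_config()].
#' @return A [landscape()] tiling `config$total_area` hectares.
#' @examples
#' cfg <- generator_config(total_area = 20,
#'   lus_shares = c(forest = 0.6, grassland = 0.4),
#'   lus_patch_counts = c(forest = 2, grassland = 3),
#'   n_cells = 300, rng_seed = 1)
#' ls <- generate_landscape(cfg)
#' composition(ls)
#' @export
generate_landscape <- function(config) {
  validate_generator_config(config)
  set.seed(config$rng_seed)
  A <- config$total_area * 1e4
  sh <- config$lus_shares[config$lus_shares > 0]
  cnt <- config$lus_patch_counts[names(sh)]

  min_cell <- A / config$n_cells
  infeasible <- cnt * min_cell > sh * A + 1e-9
  if (any(infeasible))
    stop("infeasible tessellation: LUS ",
         paste(names(sh)[infeasible], collapse = ", "),
         " cannot host ", paste(cnt[infeasible], collapse = ", "),
         " patches at the current cell granularity")

  vor <- .voronoi_cells(A, config$n_cells)
  owner <- integer(config$n_cells)
  n_patch <- sum(cnt)
  patch_lus <- character(n_patch)
  patch_cells <- vector("list", n_patch)
  patch_area <- numeric(n_patch)

  # large-patch LUSs claim contiguous space first
  ord <- names(sh)[order(-(sh * config$total_area) / cnt)]
  pid <- 0L
  for (l in ord) {
    ni <- cnt[[l]]
    draws <- stats::rlnorm(ni, 0, 0.8)
    targets <- draws / sum(draws) * sh[[l]] * A
    targets <- pmax(targets, min_cell)
    for (j in seq_len(ni)) {
      pid <- pid + 1L
      free <- which(owner == 0L)
      if (length(free) == 0L)
        stop("infeasible tessellation: no free cells left for LUS ", l)
      seed <- if (length(free) == 1L) free else sample(free, 1L)
      stream <- NULL
      if (l == "riparian") {
        a <- stats::runif(1, 0, pi)
        stream <- c(cos(a), sin(a))
      }
      g <- .grow_patch(seed, targets[j], pid, owner, vor, stream)
      owner <- g$owner
      patch_cells[[pid]] <- g$cells
      patch_area[pid] <- g$area
      patch_lus[pid] <- l
    }
  }

  # attach leftover cells to the adjacent patch of the most
  # under-target LUS, keeping shares tight and patches contiguous
  lus_target <- sh * A
  lus_area <- vapply(names(sh), function(l)
    sum(patch_area[patch_lus == l]), numeric(1))
  repeat {
    free <- which(owner == 0L)
    if (length(free) == 0L) break
    progressed <- FALSE
    for (i in free) {
      nb <- vor$adj[[i]]
      nb_patch <- unique(owner[nb][owner[nb] > 0L])
      if (length(nb_patch) == 0L) next
      deficit <- lus_target[patch_lus[nb_patch]] -
                 lus_area[patch_lus[nb_patch]]
      p <- nb_patch[which.max(deficit)]
      owner[i] <- p
      patch_cells[[p]] <- c(patch_cells[[p]], i)
      patch_area[p] <- patch_area[p] + vor$areas[i]
      lus_area[patch_lus[p]] <- lus_area[patch_lus[p]] + vor$areas[i]
      progressed <- TRUE
    }
    if (!progressed) break   # isolated empty cells (zero-area clips)
  }

  polys <- vector("list", n_patch)
  for (p in seq_len(n_patch)) {
    first <- list(vor$cells[[patch_cells[[p]][1L]]])
    acc <- .pc(first, first, "union")    # snap even single-cell patches
    for (i in patch_cells[[p]][-1L])
      acc <- .pc(acc, list(vor$cells[[i]]), "union")
    # drop degenerate sliver rings the union may leave behind
    acc <- acc[vapply(acc, function(r)
      abs(.ring_signed_area(r)) > 1e-6, logical(1))]
    polys[[p]] <- acc
  }
  landscape(polys, patch_lus, apiary = c(0, 0),
            luu_id = sprintf("luu_%03d", seq_len(n_patch)),
            crs_note = "synthetic planar metric coordinates (m)")
}

# ---- survey, traits and phenology ------------------------------------

.stratum_by_lus <- c(forest = "tree", riparian = "tree",
                     wasteland = "shrub", orchard = "shrub",
                     grassland = "herb", maize = "herb",
                     cropfield = "herb", habitation = "herb")

#' Radius of a circular observation plot, by stratum
#'
#' Herb-layer plots use r = 0.56 m, shrub-layer plots 4 m and
#' tree-layer plots 8 m.
#'
#' @param stratum character vector in `c("herb", "shrub", "tree")`.
#' @return Numeric radii in metres.
#' @export
plot_radius <- function(stratum) {
  r <- c(herb = 0.56, shrub = 4, tree = 8)[stratum]
  if (anyNA(r)) stop("unknown stratum; use herb, shrub or tree")
  unname(r)
}

# mean onset week of the flowering window by the taxon's home LUS;
# orchards bloom first (fruit trees), grasslands carry the late season
.onset_mean_by_lus <- c(orchard = 12, forest = 14, riparian = 16,
                        cropfield = 17, habitation = 18, grassland = 19,
                        wasteland = 20, maize = 22)

#' Generate a synthetic botanical survey over a landscape
#'
#' Places observation plots on a systematic grid of spacing
#' `config$plot_spacing`, assigns each to the LUU containing it, drops
#' plots on habitation and non-maize cropfield LUUs (not surveyed) and
#' randomly drops inaccessible points at rate `1 - plot_retention`.
#' Each plot receives a taxon list drawn from its LUS community so that
#' expected per-plot richness matches `richness_by_lus`, with a
#' Braun-Blanquet cover class per record. Each pool taxon receives an
#' annual nectariferous potential (log-uniform over `pnt_range`, a
#' fraction excluded for lack of data) and one contiguous flowering
#' window whose first and last weeks are early/late phase and interior
#' weeks full; a 1-week window is a single full week.
#'
#' @param landscape a [landscape()], typically from
#'   [generate_landscape()].
#' @param config the same [generator_config()].
#' @return An object of class `melliflow_survey`: list with data frames
#'   `plots` (plot_id, x, y, luu_id, lus, stratum, radius_m), `records`
#'   (plot_id, taxon, bb_class), `traits` (taxon, pnt_kg_ha,
#'   provenance) and `phenology` (taxon, week, phase; flowering weeks
#'   only, all other weeks are "none").
#' @export
generate_survey <- function(landscape, config) {
  stopifnot(inherits(landscape, "landscape"))
  validate_generator_config(config)
  set.seed(config$rng_seed + 1L)

  # ---- plots on a systematic grid -------------------------------
  bb <- Reduce(function(a, b) c(xmin = min(a["xmin"], b["xmin"]),
                                xmax = max(a["xmax"], b["xmax"]),
                                ymin = min(a["ymin"], b["ymin"]),
                                ymax = max(a["ymax"], b["ymax"])),
               lapply(landscape$luus, function(u) .poly_bbox(u$rings)))
  s <- config$plot_spacing
  if (s > max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])) {
    warning("plot spacing exceeds landscape extent; no plots generated")
    gx <- numeric(0); gy <- numeric(0)
  } else {
    off <- stats::runif(2, 0, s)
    xs <- seq(bb[["xmin"]] + off[1], bb[["xmax"]], by = s)
    ys <- seq(bb[["ymin"]] + off[2], bb[["ymax"]], by = s)
    g <- expand.grid(x = xs, y = ys)
    gx <- g$x; gy <- g$y
  }

  luu_bb <- lapply(landscape$luus, function(u) .poly_bbox(u$rings))
  locate <- function(x, y) {
    for (i in seq_along(landscape$luus)) {
      b <- luu_bb[[i]]
      if (x < b["xmin"] || x > b["xmax"] || y < b["ymin"] || y > b["ymax"])
        next
      if (.point_in_poly(x, y, landscape$luus[[i]]$rings)) return(i)
    }
    NA_integer_
  }
  hit <- vapply(seq_along(gx), function(k) locate(gx[k], gy[k]), integer(1))
  keep <- !is.na(hit)
  gx <- gx[keep]; gy <- gy[keep]; hit <- hit[keep]
  lus <- vapply(landscape$luus[hit], `[[`, character(1), "lus")
  surveyable <- !(lus %in% c("habitation", "cropfield"))
  gx <- gx[surveyable]; gy <- gy[surveyable]; hit <- hit[surveyable]
  lus <- lus[surveyable]
  accessible <- stats::runif(length(gx)) < config$plot_retention
  gx <- gx[accessible]; gy <- gy[accessible]; hit <- hit[accessible]
  lus <- lus[accessible]

  stratum <- unname(.stratum_by_lus[lus])
  plots <- data.frame(
    plot_id = sprintf("plot_%03d", seq_along(gx)),
    x = gx, y = gy,
    luu_id = vapply(landscape$luus[hit], `[[`, character(1), "luu_id"),
    lus = lus, stratum = stratum,
    radius_m = if (length(gx)) plot_radius(stratum) else numeric(0),
    stringsAsFactors = FALSE)

  # ---- taxon pool, communities, traits --------------------------
  pool <- sprintf("taxon_%03d", seq_len(config$species_pool_size))
  comm <- lapply(config$community_size, function(k)
    sample(pool, min(k, length(pool))))
  home <- stats::setNames(rep(NA_character_, length(pool)), pool)
  for (l in sample(names(comm))) {            # random claim order
    new <- comm[[l]][is.na(home[comm[[l]]])]
    home[new] <- l
  }
  home[is.na(home)] <- sample(names(comm), sum(is.na(home)), replace = TRUE)

  pnt <- exp(stats::runif(length(pool), log(config$pnt_range[1]),
                          log(config$pnt_range[2])))
  provenance <- ifelse(
    stats::runif(length(pool)) < config$pnt_missing_rate, "excluded",
    ifelse(stats::runif(length(pool)) < 0.05, "genus-fallback",
           "species-level"))
  pnt[provenance == "excluded"] <- NA_real_
  traits <- data.frame(taxon = pool, pnt_kg_ha = pnt,
                       provenance = provenance, stringsAsFactors = FALSE)

  # ---- one contiguous flowering window per taxon ----------------
  on_rng <- config$flowering_onset_range
  du_rng <- config$flowering_duration_range
  onset <- round(stats::rnorm(length(pool), .onset_mean_by_lus[home], 2.5))
  onset <- pmin(pmax(onset, on_rng[1]), on_rng[2])
  dur <- sample(seq.int(du_rng[1], du_rng[2]), length(pool), replace = TRUE)
  end <- pmin(onset + dur - 1L, 34L)
  phen <- do.call(rbind, lapply(seq_along(pool), function(i) {
    wk <- seq.int(onset[i], end[i])
    ph <- if (length(wk) == 1L) "full"
          else if (length(wk) == 2L) c("early", "late")
          else c("early", rep("full", length(wk) - 2L), "late")
    data.frame(taxon = pool[i], week = wk, phase = ph,
               stringsAsFactors = FALSE)
  }))

  # ---- plot records: LUS community, Poisson richness ------------
  bb_classes <- c("r", "+", "1", "2", "3", "4", "5")
  bb_probs <- c(0.18, 0.22, 0.25, 0.15, 0.10, 0.06, 0.04)
  recs <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    l <- plots$lus[i]
    pool_l <- comm[[l]]
    if (is.null(pool_l)) next
    mu <- config$richness_by_lus[[l]]
    k <- max(1L, min(stats::rpois(1, mu), length(pool_l)))
    tx <- sample(pool_l, k)
    recs[[i]] <- data.frame(
      plot_id = plots$plot_id[i], taxon = tx,
      bb_class = sample(bb_classes, k, replace = TRUE, prob = bb_probs),
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(plot_id = character(0), taxon = character(0),
               bb_class = character(0), stringsAsFactors = FALSE)
  rownames(records) <- NULL

  structure(list(plots = plots, records = records, traits = traits,
                 phenology = phen),
            class = "melliflow_survey")
}

#' @export
print.melliflow_survey <- function(x, ...) {
  cat("melliflow_survey:", nrow(x$plots), "plots,",
      nrow(x$records), "records,",
      length(unique(x$records$taxon)), "taxa observed of",
      nrow(x$traits), "in pool\n")
  invisible(x)
}

#' Write the survey tables of a synthetic (or real) survey as CSV
#'
#' Writes `plots.csv`, `records.csv`, `traits.csv` and `phenology.csv`
#' with the schemas documented in [generate_survey()].
#'
#' @param survey a `melliflow_survey`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_survey_csv <- function(survey, dir) {
  stopifnot(inherits(survey, "melliflow_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("plots.csv", "records.csv", "traits.csv",
                            "phenology.csv"))
  utils::write.csv(survey$plots, paths[1], row.names = FALSE)
  utils::write.csv(survey$records, paths[2], row.names = FALSE)
  utils::write.csv(survey$traits, paths[3], row.names = FALSE)
  utils::write.csv(survey$phenology, paths[4], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE)
  records <- rd("records.csv")
  records$bb_class <- as.character(records$bb_class)
  structure(list(plots = rd("plots.csv"), records = records,
                 traits = rd("traits.csv"),
                 phenology = rd("phenology.csv")),
            class = "melliflow_survey")
}
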