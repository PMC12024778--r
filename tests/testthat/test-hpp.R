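# shared tiny inputs for direct HPP evaluations
.mk_luu <- function(area_ha, centroid) {
  s <- sqrt(area_ha * 1e4)
  list(luu_id = "u", lus = "forest",
       rings = list(list(x = c(0, s, s, 0) + centroid[1] - s / 2,
                         y = c(0, 0, s, s) + centroid[2] - s / 2)),
       area = area_ha * 1e4, centroid = centroid)
}

.mk_traits <- function(taxa, pnt) {
  data.frame(taxon = taxa, pnt_kg_ha = pnt, stringsAsFactors = FALSE)
}

# calendar: full bloom for `weeks`, one-week Sf if length one
.mk_phen <- function(taxa, weeks) {
  do.call(rbind, lapply(taxa, function(t)
    data.frame(taxon = t, week = weeks, phase = "full",
               stringsAsFactors = FALSE)))
}

test_that("single-LUU HPP matches hand evaluations", {
  traits <- .mk_traits("ta", 10)
  phen <- .mk_phen("ta", 20)
  cal <- phenology_calendar(phen)
  cov <- data.frame(luu_id = "u", taxon = "ta", Rt_pct = 100,
                    stringsAsFactors = FALSE)
  # distance factor vanishes at exactly 10 km
  far <- .mk_luu(1, c(10000, 0))
  expect_equal(luu_weekly_hpp(far, c(0, 0), cov, traits, cal, 20), 0)
  # identity case: D = 0, S = 1 ha, Rt = 100 %, pnht = 10 kg/ha
  near <- .mk_luu(1, c(0, 0))
  expect_equal(luu_weekly_hpp(near, c(0, 0), cov, traits, cal, 20), 10)
  # two-taxon hand evaluation: 0.85 * 2 * (4 + 6) = 17 kg
  traits2 <- .mk_traits(c("ta", "tb"), c(8, 30))
  cov2 <- data.frame(luu_id = "u", taxon = c("ta", "tb"),
                     Rt_pct = c(50, 20), stringsAsFactors = FALSE)
  cal2 <- phenology_calendar(.mk_phen(c("ta", "tb"), 20))
  mid <- .mk_luu(2, c(1500, 0))
  expect_equal(luu_weekly_hpp(mid, c(0, 0), cov2, traits2, cal2, 20), 17)
  expect_error(luu_weekly_hpp(mid, c(0, 0),
    data.frame(luu_id = "u", taxon = "ta", Rt_pct = -5), traits, cal, 20),
    "cover")
})

test_that("HPP is non-increasing in distance and clamped at 10 km", {
  traits <- .mk_traits("ta", 50)
  cal <- phenology_calendar(.mk_phen("ta", 20))
  cov <- data.frame(luu_id = "u", taxon = "ta", Rt_pct = 60,
                    stringsAsFactors = FALSE)
  d <- seq(0, 12000, by = 500)
  v <- vapply(d, function(D)
    luu_weekly_hpp(.mk_luu(1, c(D, 0)), c(0, 0), cov, traits, cal, 20),
    numeric(1))
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v[d >= 10000] == 0))
  expect_true(all(v >= 0))
})

test_that("HPP is linear in patch area and in cover", {
  traits <- .mk_traits("ta", 50)
  cal <- phenology_calendar(.mk_phen("ta", 20))
  base <- function(S, rt)
    luu_weekly_hpp(.mk_luu(S, c(800, 0)), c(0, 0),
                   data.frame(luu_id = "u", taxon = "ta", Rt_pct = rt,
                              stringsAsFactors = FALSE),
                   traits, cal, 20)
  expect_equal(base(2, 30), 2 * base(1, 30))
  expect_equal(base(1.5, 80), 4 * base(1.5, 20))
})

test_that("surface bookkeeping closes across LUS and taxon decompositions", {
  sm <- small_fixture()
  surf <- hpp(sm$landscape, sm$survey)
  # weekly additivity: sum over LUUs equals sum over LUS groups
  expect_equal(colSums(surf$values), colSums(surf$per_lus),
               tolerance = 1e-9)
  # double bookkeeping: taxon totals close on the grand total
  expect_equal(sum(surf$per_taxon), sum(surf$values),
               tolerance = 1e-9)
  expect_equal(rowSums(surf$per_taxon_lus), surf$per_taxon,
               tolerance = 1e-9)
  expect_true(all(surf$values >= 0))
  # per-area series is per_lus divided by the LUS area (ha)
  lus_ha <- tapply(luu_areas(sm$landscape), luu_lus(sm$landscape),
                   sum)[rownames(surf$per_lus)] / 1e4
  expect_equal(surf$per_area, surf$per_lus / as.numeric(lus_ha))
})

test_that("taxa contribute only in weeks where they flower", {
  sm <- small_fixture()
  surf <- hpp(sm$landscape, sm$survey)
  cal <- phenology_calendar(sm$survey$phenology,
                            taxa = rownames(surf$per_taxon_week))
  contributes <- surf$per_taxon_week > 0
  expect_true(all(cal[contributes] != "none"))
})

test_that("all-empty assignments yield an all-zero surface", {
  sm <- small_fixture()
  ids <- vapply(sm$landscape$luus, `[[`, character(1), "luu_id")
  empty <- setNames(rep(list(character(0)), length(ids)), ids)
  surf <- compute_surface(sm$landscape, empty,
                          luu_cover(empty, sm$survey$records),
                          sm$survey$traits, sm$survey$phenology)
  expect_true(all(surf$values == 0))
})

test_that("taxon ranking sorts by contribution with alphabetical ties", {
  sm <- small_fixture()
  surf <- hpp(sm$landscape, sm$survey)
  top <- rank_taxa(surf, 10)
  expect_length(top, 10)
  expect_true(all(diff(top) <= 0))
  # matches an exhaustive sort oracle
  v <- surf$per_taxon
  expect_equal(top, v[order(-v, names(v))][1:10])
  # k beyond the taxon count returns the full list
  expect_length(rank_taxa(surf, 1e6), length(v))
  # forced tie broken alphabetically
  surf2 <- surf
  surf2$per_taxon[c("taxon_002", "taxon_001")] <- max(v) + 1
  expect_equal(names(rank_taxa(surf2, 2)),
               c("taxon_001", "taxon_002"))
})

test_that("land-use shares of a taxon normalise to 100", {
  sm <- small_fixture()
  surf <- hpp(sm$landscape, sm$survey)
  active <- names(surf$per_taxon)[surf$per_taxon > 0]
  for (tx in active[1:10]) {
    sh <- lus_share_of_taxon(surf, tx)
    expect_equal(sum(sh), 100, tolerance = 1e-9)
    expect_true(all(sh >= 0))
  }
  # taxon confined to one LUS gets 100 % there
  one <- active[which.max(apply(surf$per_taxon_lus[active, ] > 0, 1,
                                function(z) sum(z) == 1))]
  zero <- names(surf$per_taxon)[surf$per_taxon == 0][1]
  expect_error(lus_share_of_taxon(surf, zero), "zero cumulative")
  expect_error(lus_share_of_taxon(surf, "nonexistent"), "unknown taxon")
})

test_that("rasterization agrees with a point-in-polygon oracle", {
  sm <- small_fixture()
  surf <- hpp(sm$landscape, sm$survey)
  wk <- surf$weeks[which.max(colSums(surf$values))]
  ras <- rasterize_hpp(surf, sm$landscape, wk, cell_size = 40)
  nx <- ncol(ras$values); ny <- nrow(ras$values)
  set.seed(5)
  ids <- vapply(sm$landscape$luus, `[[`, character(1), "luu_id")
  wv <- surf$values[, as.character(wk)]
  for (k in 1:1000) {
    r <- sample(ny, 1); cc <- sample(nx, 1)
    x <- ras$xllcorner + (cc - 0.5) * ras$cell_size
    y <- ras$yllcorner + (ny - r + 0.5) * ras$cell_size
    hit <- NA_real_
    for (i in seq_along(sm$landscape$luus)) {
      if (melliflow:::.point_in_poly(x, y, sm$landscape$luus[[i]]$rings)) {
        hit <- wv[[ids[i]]]; break
      }
    }
    expect_equal(ras$values[r, cc], hit, label = sprintf("cell %d", k))
  }
  # ASCII grid export has the right header and cell count
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(ras, path)
  hdr <- readLines(path, n = 6)
  expect_equal(hdr[1], paste("ncols", nx))
  expect_equal(hdr[2], paste("nrows", ny))
  body <- utils::read.table(path, skip = 6)
  expect_equal(dim(as.matrix(body)), dim(ras$values))
})
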