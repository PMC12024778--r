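test_that("degenerate config yields a single patch of the full area", {
  cfg <- generator_config(total_area = 10,
                          lus_shares = c(forest = 1),
                          lus_patch_counts = c(forest = 1),
                          n_cells = 50, rng_seed = 3)
  ls <- generate_landscape(cfg)
  expect_length(ls$luus, 1L)
  expect_equal(total_area(ls), 10, tolerance = 1e-6)
  expect_equal(unname(luu_lus(ls)), "forest")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(lus_shares = c(forest = 0.6,
                                               grassland = 0.5)),
               "sum to 1")
  expect_error(generator_config(lus_shares = c(forest = 1),
                                lus_patch_counts = c(grassland = 4)),
               "patch count")
  expect_error(generator_config(flowering_onset_range = c(5, 30)),
               "10-34")
  # infeasible tessellation names the offending LUS
  cfg <- generator_config(total_area = 10,
                          lus_shares = c(forest = 0.99, orchard = 0.01),
                          lus_patch_counts = c(forest = 1, orchard = 30),
                          n_cells = 100, rng_seed = 1)
  expect_error(generate_landscape(cfg), "orchard")
})

test_that("mosaic tiles the region with exact patch counts", {
  sm <- small_fixture()
  ls <- sm$landscape; cfg <- sm$cfg
  # tiling: areas sum to the configured total within 1e-6 relative
  expect_equal(total_area(ls), cfg$total_area,
               tolerance = 1e-6)
  # label conservation: per-LUS patch counts exactly as configured
  cnt <- table(luu_lus(ls))
  for (l in names(cfg$lus_patch_counts))
    expect_identical(as.integer(cnt[l]),
                     as.integer(cfg$lus_patch_counts[l]), label = l)
  # shares within the 2-point tessellation tolerance
  comp <- composition(ls)
  for (l in names(cfg$lus_shares))
    expect_lt(abs(comp[[l]] - 100 * cfg$lus_shares[[l]]), 2)
  expect_true(validate_landscape(ls, check_overlap = TRUE))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(total_area = 15,
                          lus_shares = c(forest = 0.5, grassland = 0.5),
                          lus_patch_counts = c(forest = 2, grassland = 3),
                          n_cells = 200, plot_spacing = 40, rng_seed = 9)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a, b)
  expect_identical(generate_survey(a, cfg), generate_survey(b, cfg))
  cfg2 <- cfg; cfg2$rng_seed <- 10L
  expect_false(identical(generate_landscape(cfg2), a))
})

test_that("every plot lies inside its assigned LUU", {
  sm <- small_fixture()
  pl <- sm$survey$plots
  ids <- vapply(sm$landscape$luus, `[[`, character(1), "luu_id")
  for (i in seq_len(nrow(pl))) {
    u <- sm$landscape$luus[[match(pl$luu_id[i], ids)]]
    expect_true(melliflow:::.point_in_poly(pl$x[i], pl$y[i], u$rings),
                label = pl$plot_id[i])
  }
})

test_that("survey drops unsurveyed land uses and sets strata radii", {
  sm <- small_fixture()
  pl <- sm$survey$plots
  expect_false(any(pl$lus %in% c("habitation", "cropfield")))
  expect_equal(pl$radius_m,
               unname(c(herb = 0.56, shrub = 4, tree = 8)[pl$stratum]))
  expect_true(all(sm$survey$records$bb_class %in%
                  c("r", "+", "1", "2", "3", "4", "5")))
})

test_that("flowering windows are contiguous with early/full/late edges", {
  sm <- small_fixture()
  ph <- sm$survey$phenology
  expect_true(all(ph$week >= 10 & ph$week <= 34))
  for (tx in unique(ph$taxon)[1:25]) {
    wk <- sort(ph$week[ph$taxon == tx])
    expect_equal(wk, seq(min(wk), max(wk)))          # contiguous
    phase <- ph$phase[ph$taxon == tx][order(ph$week[ph$taxon == tx])]
    if (length(wk) == 1) {
      expect_equal(phase, "full")                    # minimal window
    } else if (length(wk) == 2) {
      expect_equal(phase, c("early", "late"))
    } else {
      expect_equal(phase[1], "early")
      expect_equal(phase[length(phase)], "late")
      expect_true(all(phase[-c(1, length(phase))] == "full"))
    }
  }
})

test_that("per-plot richness recovers the configured means", {
  # Monte-Carlo recovery over 10 survey seeds on one landscape
  sm <- small_fixture()
  mean_forest <- mean_grass <- numeric(10)
  for (s in 1:10) {
    cfg <- sm$cfg; cfg$rng_seed <- 100L + s
    sv <- generate_survey(sm$landscape, cfg)
    rich <- richness_summary(sv$plots, sv$records)
    mean_forest[s] <- rich$mean_per_plot[rich$lus == "forest"]
    mean_grass[s] <- rich$mean_per_plot[rich$lus == "grassland"]
  }
  expect_lt(abs(mean(mean_forest) - sm$cfg$richness_by_lus[["forest"]]), 1)
  expect_lt(abs(mean(mean_grass) - sm$cfg$richness_by_lus[["grassland"]]), 1)
})

test_that("oversized plot spacing warns and returns zero plots", {
  sm <- small_fixture()
  cfg <- sm$cfg; cfg$plot_spacing <- 1e6
  expect_warning(sv <- generate_survey(sm$landscape, cfg),
                 "spacing")
  expect_equal(nrow(sv$plots), 0L)
})

test_that("survey CSV round-trip preserves the tables", {
  sm <- small_fixture()
  dir <- withr::local_tempdir()
  write_survey_csv(sm$survey, dir)
  back <- read_survey_csv(dir)
  expect_equal(back$plots, sm$survey$plots, tolerance = 1e-12)
  expect_equal(back$records, sm$survey$records)
  expect_equal(back$traits, sm$survey$traits, tolerance = 1e-12)
  expect_equal(back$phenology, sm$survey$phenology)
})
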