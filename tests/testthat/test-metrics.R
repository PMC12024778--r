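test_that("composition covers trivial and mixed cases", {
  sq <- square_poly(0, 0, 100)
  one <- landscape(list(sq), "forest", c(50, 50))
  expect_equal(composition(one), c(forest = 100))
  two <- landscape(list(sq, square_poly(200, 0, 100)),
                   c("forest", "grassland"), c(150, 50))
  expect_equal(sort(composition(two)),
               sort(c(forest = 50, grassland = 50)))
  expect_equal(sum(composition(small_fixture()$landscape)), 100,
               tolerance = 1e-9)
})

test_that("mean patch area matches the printed study table", {
  # LUS totals from printed shares of a 707 ha area over printed counts
  mk_lus <- function(total_ha, n, lus, row) {
    a <- total_ha * 1e4 / n
    s <- sqrt(a)
    lapply(seq_len(n), function(j)
      square_poly(j * (s + 50), row * 3000, s))
  }
  polys <- c(mk_lus(0.261 * 707, 114, "grassland", 1),
             mk_lus(0.0611 * 707, 132, "orchard", 2),
             mk_lus(0.0404 * 707, 49, "maize", 3))
  ls <- landscape(polys, rep(c("grassland", "orchard", "maize"),
                             c(114, 132, 49)), c(0, 0))
  expect_equal(signif(mean_patch_area(ls, "grassland")[["Si_ha"]], 3), 1.62)
  expect_equal(signif(mean_patch_area(ls, "orchard")[["Si_ha"]], 3), 0.327)
  expect_equal(signif(mean_patch_area(ls, "maize")[["Si_ha"]], 3), 0.583)
  # Si * ni reproduces the summed class area exactly
  for (l in c("grassland", "orchard", "maize")) {
    n <- sum(luu_lus(ls) == l)
    expect_equal(mean_patch_area(ls, l)[["Si_ha"]] * n,
                 sum(luu_areas(ls)[luu_lus(ls) == l]) / 1e4,
                 tolerance = 1e-9)
  }
  # single patch: SD defined as 0
  one <- landscape(list(square_poly(0, 0, sqrt(5e4))), "forest", c(0, 0))
  expect_equal(mean_patch_area(one, "forest"),
               c(Si_ha = 5, sd_ha = 0))
  expect_error(mean_patch_area(one, "maize"), "maize")
})

test_that("patch density follows ni / A * 10^6 and its scaling law", {
  sm <- small_fixture()
  ls <- sm$landscape
  A <- sum(luu_areas(ls))
  for (l in unique(luu_lus(ls)))
    expect_equal(patch_density(ls, l),
                 sum(luu_lus(ls) == l) / A * 1e6)
  expect_equal(patch_density(ls, "riparian"), 0)   # absent class
  # doubling A with ni fixed halves Dti
  big <- ls
  big$luus <- c(ls$luus, list(modifyList(
    ls$luus[[1]], list(luu_id = "pad", lus = "wasteland",
                       area = A))))
  expect_equal(patch_density(big, "forest"),
               patch_density(ls, "forest") / 2)
})

test_that("nearest-neighbour distance is edge-to-edge", {
  # symmetric pair: closest edges 100 m apart
  ls <- landscape(list(square_poly(0, 0, 50), square_poly(150, 0, 50)),
                  c("forest", "forest"), c(0, 0))
  expect_equal(unname(mean_nearest_neighbor(ls, "forest")),
               c(100, 0))
  # three collinear unit squares, gaps 10 m and 30 m
  ls3 <- landscape(list(square_poly(0, 0, 1), square_poly(11, 0, 1),
                        square_poly(42, 0, 1)),
                   rep("forest", 3), c(0, 0))
  expect_equal(mean_nearest_neighbor(ls3, "forest")[["ENNi_m"]],
               (10 + 10 + 30) / 3)
  # fewer than two patches: NA with a warning (Fragstats behaviour)
  one <- landscape(list(square_poly(0, 0, 1)), "forest", c(0, 0))
  expect_warning(enn <- mean_nearest_neighbor(one, "forest"),
                 "fewer than 2")
  expect_true(all(is.na(enn)))
})

test_that("ENN matches the exhaustive segment-pair oracle", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    ls <- random_square_landscape(n)
    for (l in unique(luu_lus(ls))) {
      if (sum(luu_lus(ls) == l) < 2) next
      expect_equal(mean_nearest_neighbor(ls, l)[["ENNi_m"]],
                   oracle_enn(ls, l), tolerance = 1e-12)
    }
  }
})

test_that("ENN is invariant under rigid motion of the landscape", {
  set.seed(7)
  ls <- random_square_landscape(12)
  enn0 <- mean_nearest_neighbor(ls, "forest")
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- ls
  moved$luus <- lapply(ls$luus, function(u) {
    u$rings <- lapply(u$rings, function(r) {
      m <- R %*% rbind(r$x, r$y) + c(1000, -500)
      list(x = m[1, ], y = m[2, ])
    })
    u$centroid <- as.numeric(R %*% u$centroid + c(1000, -500))
    u
  })
  expect_equal(mean_nearest_neighbor(moved, "forest"), enn0,
               tolerance = 1e-6)
})

test_that("landscape_metrics table is schema-stable and consistent", {
  m <- landscape_metrics(small_fixture()$landscape)
  expect_named(m, c("lus", "n_luu", "Si_ha", "Si_sd", "Dti", "ENNi_m",
                    "ENNi_sd", "share_pct"))
  expect_equal(sum(m$share_pct), 100, tolerance = 0.1)
  expect_equal(m$Si_ha * m$n_luu * 1e4 / sum(m$Si_ha * m$n_luu * 1e4),
               m$share_pct / 100, tolerance = 1e-9)
})
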