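uniform_raster <- function(code = 1, n = 200, cell = 25) {
  landuse_raster(matrix(code, n, n), xmin = 0, ymin = 0, cell = cell)
}

test_that("forest cover: uniform, empty and half-plane rasters", {
  centre <- c(2500, 2500)
  for (r in c(100, 500, 1000))
    expect_equal(forest_cover(centre, uniform_raster(1), r), 100)
  expect_equal(forest_cover(centre, uniform_raster(4), 500), 0)
  # half-plane forest, site on the boundary -> 50% +- quantization
  g <- matrix(4L, 200, 200)
  g[1:100, ] <- 1L     # forest where x < 2500
  hp <- landuse_raster(g, cell = 25)
  expect_lt(abs(forest_cover(centre, hp, 500) - 50), 2)
  expect_error(forest_cover(c(100, 100), uniform_raster(1), 500), "exits")
})

test_that("road density follows the chord-length closed forms", {
  # diameter chord: 2r
  road <- list(cbind(c(-2000, 2000), c(0, 0)))
  expect_equal(road_density(c(0, 0), road, 100), 200 / 1000, tolerance = 1e-9)
  # chord at offset d: 2 sqrt(r^2 - d^2)
  off <- list(cbind(c(-2000, 2000), c(60, 60)))
  expect_equal(road_density(c(0, 0), off, 100),
               2 * sqrt(100^2 - 60^2) / 1000, tolerance = 1e-9)
  # fully outside
  expect_equal(road_density(c(0, 0), off, 50), 0)
  expect_error(road_density(c(0, 0), road, 0), "positive")
  # multi-vertex polyline passing through: sum of per-segment clips
  zig <- list(rbind(c(-200, 0), c(0, 0), c(0, 200)))
  expect_equal(road_density(c(0, 0), zig, 100), 200 / 1000, tolerance = 1e-9)
})

test_that("building area: containment, exclusion and exact disc clipping", {
  sq <- function(x0, y0, w, h)
    cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
  # 100 x 100 m building fully inside -> 0.01 km2
  expect_equal(building_area(c(0, 0), list(sq(-50, -50, 100, 100)), 500), 0.01,
               tolerance = 1e-12)
  # outside -> 0
  expect_equal(building_area(c(0, 0), list(sq(1000, 1000, 100, 100)), 500), 0)
  # circle fully inside a huge polygon -> pi r^2
  expect_equal(building_area(c(0, 0), list(sq(-5000, -5000, 10000, 10000)), 300),
               pi * 300^2 / 1e6, tolerance = 1e-9)
  # straddling polygon vs a 1e6-point Monte-Carlo oracle, within 1%
  poly <- sq(-50, 200, 100, 200)
  exact <- building_area(c(0, 0), list(poly), 300)
  set.seed(1)
  pts <- cbind(stats::runif(1e6, -50, 50), stats::runif(1e6, 200, 400))
  mc <- mean(pts[, 1]^2 + pts[, 2]^2 <= 300^2) * (100 * 200) / 1e6
  expect_lt(abs(exact - mc) / mc, 0.01)
  # self-intersecting polygon raises a geometry error
  bow <- cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))
  expect_error(building_area(c(0, 0), list(bow), 500), "self-intersecting")
})

test_that("monotonicity in radius and radius-invariance on uniform forest", {
  set.seed(2)
  roads <- list(cbind(c(-3000, 3000), c(40, 40)),
                rbind(c(100, -500), c(300, 800)))
  polys <- list(cbind(c(100, 300, 300, 100), c(100, 100, 250, 250)))
  radii <- c(100, 200, 500, 1000)
  rd <- vapply(radii, function(r) road_density(c(0, 0), roads, r), numeric(1))
  ba <- vapply(radii, function(r) building_area(c(0, 0), polys, r), numeric(1))
  expect_true(all(diff(rd) >= 0))
  expect_true(all(diff(ba) >= 0))
  fc <- vapply(radii, function(r)
    forest_cover(c(2500, 2500), uniform_raster(2), r), numeric(1))
  expect_true(all(fc == 100))
})

test_that("metrics_table is complete, correctly shaped, and fails loudly", {
  sites <- data.frame(site_id = c("A", "B", "C"),
                      x = c(2000, 2500, 3000), y = c(2500, 2500, 2500))
  layers <- structure(list(raster = uniform_raster(1),
                           primary_roads = list(),
                           secondary_roads = list(cbind(c(0, 5000),
                                                        c(2600, 2600))),
                           buildings = list()),
                      class = "landscape_layers")
  tab <- metrics_table(sites, layers, radii_forest = c(100, 200),
                       radii_roads = c(100, 200))
  cov_cols <- setdiff(names(tab), c("site_id", "x", "y"))
  expect_length(cov_cols, 2 + 2 * 3)   # 2 forest + 2 radii x 3 covariates
  expect_false(anyNA(as.data.frame(tab)[cov_cols]))
  expect_true(all(tab$forest_cover_200 == 100))
  expect_true(all(tab$primary_road_density_200 == 0))
  expect_true(all(tab$building_area_100 == 0))
  # nearby sites with overlapping buffers are computed independently
  expect_equal(tab$secondary_road_density_200[1],
               tab$secondary_road_density_200[3])
  # per-site failure aborts with a site-indexed report
  sites_bad <- rbind(sites, data.frame(site_id = "edge", x = 10, y = 10))
  expect_error(metrics_table(sites_bad, layers, radii_forest = c(100, 200),
                             radii_roads = c(100)), "edge")
  # CSV + JSON sidecar round trip
  path <- tempfile(fileext = ".csv")
  write_metrics_table(tab, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  expect_equal(meta$radii_forest, c(100, 200))
})
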