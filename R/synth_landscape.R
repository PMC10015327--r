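#' Synthetic landscapes, site networks and occurrence truth
#'
#' Generators for a stratified site network with minimum spacing, raster /
#' vector landscape layers (forest mosaic, primary and secondary roads,
#' building clusters) and spatially autocorrelated occurrence with 7-day
#' detection histories, all with known ground truth so downstream statistics
#' can be tested for parameter recovery.
#'
#' @name synth_landscape
NULL

LAND_USE_LEVELS <- c("old_growth", "secondary", "mangrove", "grassland",
                     "palm", "teak")

land_use_code <- function(label) match(label, LAND_USE_LEVELS)

#' Stratified site network with minimum spacing
#'
#' Rejection-samples \code{n} sites uniformly over a rectangular region,
#' enforcing a minimum pairwise distance, and assigns land-use strata with
#' per-stratum counts proportional to the weights (largest-remainder
#' rounding).
#'
#' @param n number of sites.
#' @param region extent as \code{c(xmax, ymax)} metres (origin at 0).
#' @param strata_weights named numeric weights over land-use strata
#'   (names from old_growth, secondary, mangrove, grassland, palm, teak).
#' @param min_dist minimum pairwise distance in metres (default 500).
#' @param seed RNG seed.
#' @param max_tries_per_site rejection budget before declaring the packing
#'   infeasible.
#' @return data frame with site_id, x, y, land_use, elevation.
#' @export
synth_sites <- function(n, region = c(33000, 33000),
                        strata_weights = c(old_growth = 0.35, secondary = 0.25,
                                           mangrove = 0.05, grassland = 0.15,
                                           palm = 0.12, teak = 0.08),
                        min_dist = 500, seed = 1,
                        max_tries_per_site = 500) {
  set.seed(seed)
  stopifnot(all(names(strata_weights) %in% LAND_USE_LEVELS))
  w <- strata_weights / sum(strata_weights)
  counts <- floor(n * w)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * w - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand_x <- stats::runif(1, 0, region[1])
    cand_y <- stats::runif(1, 0, region[2])
    ok <- placed == 0 ||
      min((xs[seq_len(placed)] - cand_x)^2 + (ys[seq_len(placed)] - cand_y)^2) >=
      min_dist^2
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- cand_x; ys[placed] <- cand_y
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries_per_site)
        stop("infeasible packing: cannot place ", n, " sites at min_dist ",
             min_dist, " in the given region")
    }
  }
  land_use <- sample(rep(names(counts), counts))
  data.frame(site_id = sprintf("S%03d", seq_len(n)), x = xs, y = ys,
             land_use = land_use,
             elevation = round(stats::runif(n, 5, 792)))
}

# smooth random surface: bilinear interpolation of a coarse iid grid
smooth_field <- function(xmax, ymax, coarse = 1500, sd = 1) {
  nx <- max(2, ceiling(xmax / coarse) + 1)
  ny <- max(2, ceiling(ymax / coarse) + 1)
  g <- matrix(stats::rnorm(nx * ny, sd = sd), nx, ny)
  function(x, y) {
    fx <- pmin(pmax(x / coarse, 0), nx - 1 - 1e-9)
    fy <- pmin(pmax(y / coarse, 0), ny - 1 - 1e-9)
    i <- floor(fx); j <- floor(fy)
    tx <- fx - i; ty <- fy - j
    g[cbind(i + 1, j + 1)] * (1 - tx) * (1 - ty) +
      g[cbind(i + 2, j + 1)] * tx * (1 - ty) +
      g[cbind(i + 1, j + 2)] * (1 - tx) * ty +
      g[cbind(i + 2, j + 2)] * tx * ty
  }
}

#' Synthetic landscape layers around a site network
#'
#' Builds a land-use raster whose forest pattern is a smooth random mosaic
#' pulled towards forest around forest-stratum sites and away around
#' non-forest sites (so forest cover in site buffers spans from near 0 to
#' 100 percent), plus primary-road polylines crossing the region, scattered
#' secondary roads, and building clusters near the primary roads.
#'
#' @param sites site data frame from \code{\link{synth_sites}}.
#' @param cell raster cell size in metres (default 25; configurable down
#'   to 5).
#' @param margin raster margin beyond the site bounding box, in metres;
#'   must cover the largest buffer radius used downstream.
#' @param n_primary,n_secondary,n_building_clusters feature counts.
#' @param bump_amp,bump_bw strength (logit-ish units) and bandwidth (m) of
#'   the per-site forest/non-forest pull.
#' @param seed RNG seed.
#' @return list of class \code{"landscape_layers"}: \code{raster}
#'   (a \code{"landuse_raster"}), \code{primary_roads},
#'   \code{secondary_roads} (lists of polyline matrices), \code{buildings}
#'   (list of polygon matrices).
#' @export
synth_layers <- function(sites, cell = 25, margin = 1200, n_primary = 2,
                         n_secondary = 8, n_building_clusters = 3,
                         bump_amp = 3, bump_bw = 500, seed = 1) {
  set.seed(seed)
  xmin <- min(sites$x) - margin; xmax <- max(sites$x) + margin
  ymin <- min(sites$y) - margin; ymax <- max(sites$y) + margin
  nx <- ceiling((xmax - xmin) / cell); ny <- ceiling((ymax - ymin) / cell)
  cx <- xmin + (seq_len(nx) - 0.5) * cell
  cy <- ymin + (seq_len(ny) - 0.5) * cell
  fld <- smooth_field(xmax - xmin, ymax - ymin, sd = 1.2)
  xg <- rep(cx, times = ny); yg <- rep(cy, each = nx)
  val <- fld(xg - xmin, yg - ymin)
  forest_site <- sites$land_use %in% c("old_growth", "secondary", "mangrove")
  sgn <- ifelse(forest_site, bump_amp, -bump_amp)
  for (i in seq_len(nrow(sites))) {
    d2 <- (xg - sites$x[i])^2 + (yg - sites$y[i])^2
    val <- val + sgn[i] * exp(-d2 / (2 * bump_bw^2))
  }
  grid <- matrix(ifelse(val > 0, 1L, 4L), nx, ny)
  # paint each site's own land-use class in a small disc so all classes occur
  # (60 m: small enough that even 100 m buffers mix with the mosaic)
  for (i in seq_len(nrow(sites))) {
    near <- (xg - sites$x[i])^2 + (yg - sites$y[i])^2 <= 60^2
    grid[near] <- land_use_code(sites$land_use[i])
  }
  raster <- landuse_raster(grid, xmin = xmin, ymin = ymin, cell = cell)

  jitter_line <- function(x0, y0, x1, y1, n = 6) {
    tt <- seq(0, 1, length.out = n)
    cbind(x0 + tt * (x1 - x0) + c(0, stats::rnorm(n - 2, 0, 400), 0),
          y0 + tt * (y1 - y0) + c(0, stats::rnorm(n - 2, 0, 400), 0))
  }
  primary <- lapply(seq_len(n_primary), function(i) {
    yy <- stats::runif(2, ymin, ymax)
    jitter_line(xmin, yy[1], xmax, yy[2])
  })
  secondary <- lapply(seq_len(n_secondary), function(i) {
    x0 <- stats::runif(1, xmin, xmax); y0 <- stats::runif(1, ymin, ymax)
    ang <- stats::runif(1, 0, 2 * pi); len <- stats::runif(1, 1500, 5000)
    jitter_line(x0, y0, x0 + len * cos(ang), y0 + len * sin(ang), n = 4)
  })
  buildings <- list()
  if (n_building_clusters > 0 && n_primary > 0) {
    for (ci in seq_len(n_building_clusters)) {
      road <- primary[[1 + (ci - 1) %% n_primary]]
      anchor <- road[sample(nrow(road), 1), ]
      n_b <- sample(4:10, 1)
      for (b in seq_len(n_b)) {
        bx <- anchor[1] + stats::rnorm(1, 0, 300)
        by <- anchor[2] + stats::rnorm(1, 0, 300)
        wdt <- stats::runif(1, 10, 40); hgt <- stats::runif(1, 10, 40)
        buildings[[length(buildings) + 1]] <-
          cbind(c(bx, bx + wdt, bx + wdt, bx), c(by, by, by + hgt, by + hgt))
      }
    }
  }
  structure(list(raster = raster, primary_roads = primary,
                 secondary_roads = secondary, buildings = buildings),
            class = "landscape_layers")
}

# Gaussian random field with exponential covariance at site locations
grf_exponential <- function(coords, sd = 1, range = 2000) {
  d <- pair_dist(coords)
  S <- sd^2 * exp(-d / range)
  L <- chol(S + diag(1e-8, nrow(d)))
  drop(crossprod(L, stats::rnorm(nrow(d))))
}

#' Occurrence and detection-history truth
#'
#' Bundles the generating parameters for \code{\link{synth_occurrence}}:
#' a logistic occurrence model on forest cover at the true scale (steep
#' slope at a cover threshold, optionally a hard floor below which presence
#' is impossible), optional linear covariates, a hard exclusion where
#' primary roads enter the buffer, an optional spatial random field on the
#' logit, and the daily detection probability.
#'
#' @param intercept logit intercept (at the cover threshold).
#' @param forest_col,forest_threshold,forest_slope forest-cover column name,
#'   the threshold (percent) where occurrence probability crosses 1/2, and
#'   the logit slope per percent cover.
#' @param forest_hard if TRUE, sites below the threshold are never occupied.
#' @param beta optional named vector of linear coefficients on further
#'   covariate columns.
#' @param road_exclusion_col covariate column; any positive value forces
#'   absence (e.g. primary road density within 1 km). NULL disables.
#' @param spatial_sd,spatial_range Gaussian-field parameters on the logit
#'   scale (sd 0 disables the field).
#' @param p_daily daily detection probability at occupied sites.
#' @param J occasions (days) per site.
#' @return list of class \code{"occurrence_truth"}.
#' @export
occurrence_truth <- function(intercept = 0, forest_col = "forest_cover_200",
                             forest_threshold = 80, forest_slope = 0.4,
                             forest_hard = FALSE, beta = NULL,
                             road_exclusion_col = "primary_road_density_1000",
                             spatial_sd = 0, spatial_range = 2000,
                             p_daily = 0.68, J = 7) {
  structure(list(intercept = intercept, forest_col = forest_col,
                 forest_threshold = forest_threshold,
                 forest_slope = forest_slope, forest_hard = forest_hard,
                 beta = beta, road_exclusion_col = road_exclusion_col,
                 spatial_sd = spatial_sd, spatial_range = spatial_range,
                 p_daily = p_daily, J = J),
            class = "occurrence_truth")
}

#' Simulate site occurrence and 7-day detection histories
#'
#' Occurrence is Bernoulli of the inverse-logit of the truth linear
#' predictor plus the spatial field; occupied sites get independent daily
#' Bernoulli(p_daily) detections, unoccupied sites all-zero histories.
#'
#' @param sites site data frame (needs x, y for the spatial field).
#' @param covariates data frame holding the truth's covariate columns
#'   (typically a \code{\link{metrics_table}} output at the true scale).
#' @param truth an \code{\link{occurrence_truth}}.
#' @param seed RNG seed.
#' @return list with \code{occurrence} (0/1 vector), \code{histories}
#'   (sites x J matrix), \code{psi} (generating probabilities) and
#'   \code{field} (the spatial-field draw, zeros when disabled).
#' @export
synth_occurrence <- function(sites, covariates, truth, seed = 1) {
  set.seed(seed)
  n <- nrow(sites)
  if (!truth$forest_col %in% names(covariates))
    stop("covariate ", truth$forest_col, " missing at the required scale")
  cover <- covariates[[truth$forest_col]]
  eta <- truth$intercept + truth$forest_slope * (cover - truth$forest_threshold)
  if (!is.null(truth$beta)) {
    for (nm in names(truth$beta)) {
      if (!nm %in% names(covariates))
        stop("covariate ", nm, " missing at the required scale")
      eta <- eta + truth$beta[[nm]] * covariates[[nm]]
    }
  }
  field <- rep(0, n)
  if (truth$spatial_sd > 0)
    field <- grf_exponential(cbind(sites$x, sites$y), sd = truth$spatial_sd,
                             range = truth$spatial_range)
  psi <- stats::plogis(eta + field)
  if (truth$forest_hard) psi[cover < truth$forest_threshold] <- 0
  if (!is.null(truth$road_exclusion_col) &&
      truth$road_exclusion_col %in% names(covariates))
    psi[covariates[[truth$road_exclusion_col]] > 0] <- 0
  occ <- stats::rbinom(n, 1, psi)
  H <- matrix(0L, n, truth$J)
  idx <- which(occ == 1)
  if (length(idx) > 0)
    H[idx, ] <- matrix(stats::rbinom(length(idx) * truth$J, 1, truth$p_daily),
                       length(idx), truth$J)
  list(occurrence = occ, histories = H, psi = psi, field = field)
}

#' Write landscape layers to plain-text files
#'
#' Roads and buildings go to GeoJSON; the raster to a plain-text grid with a
#' small JSON georeferencing sidecar.
#'
#' @param layers a \code{"landscape_layers"}.
#' @param dir output directory (created).
#' @export
write_layers <- function(layers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gj_lines <- function(pls) list(
    type = "FeatureCollection",
    features = lapply(pls, function(m) list(
      type = "Feature", properties = list(),
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(m)),
                                           function(i) as.numeric(m[i, ]))))))
  gj_polys <- function(pgs) list(
    type = "FeatureCollection",
    features = lapply(pgs, function(m) {
      ring <- rbind(m, m[1, ])
      list(type = "Feature", properties = list(),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) as.numeric(ring[i, ])))))
    }))
  jsonlite::write_json(gj_lines(layers$primary_roads),
                       file.path(dir, "primary_roads.geojson"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(gj_lines(layers$secondary_roads),
                       file.path(dir, "secondary_roads.geojson"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(gj_polys(layers$buildings),
                       file.path(dir, "buildings.geojson"), auto_unbox = TRUE, digits = NA)
  r <- layers$raster
  jsonlite::write_json(list(xmin = r$xmin, ymin = r$ymin, cell = r$cell,
                            nx = nrow(r$grid), ny = ncol(r$grid),
                            forest_codes = r$forest_codes),
                       file.path(dir, "raster.meta.json"), auto_unbox = TRUE)
  utils::write.table(r$grid, file.path(dir, "raster.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read landscape layers written by \code{\link{write_layers}}
#'
#' @param dir directory holding the layer files.
#' @return a \code{"landscape_layers"} list.
#' @export
read_layers <- function(dir) {
  need <- c("primary_roads.geojson", "secondary_roads.geojson",
            "buildings.geojson", "raster.meta.json", "raster.txt")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    stop("missing layer file(s): ", paste(missing, collapse = ", "))
  lines_of <- function(f) {
    g <- jsonlite::read_json(file.path(dir, f))
    lapply(g$features, function(ft)
      do.call(rbind, lapply(ft$geometry$coordinates, unlist)))
  }
  polys_of <- function(f) {
    g <- jsonlite::read_json(file.path(dir, f))
    lapply(g$features, function(ft) {
      m <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist))
      m[-nrow(m), , drop = FALSE]   # drop the closing vertex
    })
  }
  meta <- jsonlite::read_json(file.path(dir, "raster.meta.json"))
  grid <- as.matrix(utils::read.table(file.path(dir, "raster.txt")))
  dimnames(grid) <- NULL
  structure(list(
    raster = landuse_raster(grid, xmin = meta$xmin, ymin = meta$ymin,
                            cell = meta$cell,
                            forest_codes = unlist(meta$forest_codes)),
    primary_roads = lines_of("primary_roads.geojson"),
    secondary_roads = lines_of("secondary_roads.geojson"),
    buildings = polys_of("buildings.geojson")),
    class = "landscape_layers")
}
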