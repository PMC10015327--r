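#' Buffer-based landscape covariates
#'
#' Percentage forest cover, road density (km of polyline) and building area
#' (km^2 of polygon) inside circular buffers around each site, at a grid of
#' radii. All geometry is planar Euclidean in a metric projection; rasters
#' use the cell-centre inclusion rule, polylines are clipped analytically to
#' the disc, and polygon-disc intersection areas use an exact arc
#' decomposition (Green's theorem with circular-segment terms).
#'
#' @name landscape_metrics
NULL

#' A land-use raster
#'
#' @param grid integer matrix of land-use codes; \code{grid[ix, iy]} is the
#'   cell with centre \code{(xmin + (ix - 0.5) cell, ymin + (iy - 0.5) cell)}.
#' @param xmin,ymin lower-left corner of the raster extent (m).
#' @param cell cell size (m).
#' @param forest_codes codes counted as forest (default old growth,
#'   secondary, mangrove = 1:3).
#' @return list of class \code{"landuse_raster"}.
#' @export
landuse_raster <- function(grid, xmin = 0, ymin = 0, cell = 25,
                           forest_codes = 1:3) {
  structure(list(grid = grid, xmin = xmin, ymin = ymin, cell = cell,
                 forest_codes = forest_codes),
            class = "landuse_raster")
}

#' Percentage forest cover in a buffer
#'
#' Fraction of raster cells whose centre lies inside the disc and whose code
#' is a forest code, times 100. Errors if the buffer leaves the raster
#' extent.
#'
#' @param site numeric \code{c(x, y)} in metres (or a one-row data frame
#'   with x and y columns).
#' @param raster a \code{"landuse_raster"}.
#' @param radius buffer radius (m).
#' @param site_id used in error messages.
#' @return percent in [0, 100].
#' @export
forest_cover <- function(site, raster, radius, site_id = NULL) {
  xy <- site_xy(site)
  g <- raster$grid; cs <- raster$cell
  nx <- nrow(g); ny <- ncol(g)
  if (xy[1] - radius < raster$xmin || xy[2] - radius < raster$ymin ||
      xy[1] + radius > raster$xmin + nx * cs ||
      xy[2] + radius > raster$ymin + ny * cs)
    stop("buffer exits raster extent at site ",
         if (is.null(site_id)) sprintf("(%.0f, %.0f)", xy[1], xy[2]) else site_id)
  ix <- which(abs(raster$xmin + (seq_len(nx) - 0.5) * cs - xy[1]) <= radius)
  iy <- which(abs(raster$ymin + (seq_len(ny) - 0.5) * cs - xy[2]) <= radius)
  cx <- raster$xmin + (ix - 0.5) * cs - xy[1]
  cy <- raster$ymin + (iy - 0.5) * cs - xy[2]
  inside <- outer(cx^2, cy^2, "+") <= radius^2
  if (!any(inside)) stop("no raster cells inside the buffer")
  codes <- g[ix, iy, drop = FALSE]
  100 * sum(codes[inside] %in% raster$forest_codes) / sum(inside)
}

site_xy <- function(site) {
  if (is.data.frame(site)) site <- c(site$x[1], site$y[1])
  as.numeric(site[1:2])
}

# length of segment a-b (2-vectors) inside the circle centred at origin
segment_in_circle <- function(a, b, r) {
  d <- b - a
  A <- sum(d^2)
  if (A == 0) return(0)
  B <- 2 * sum(a * d)
  C <- sum(a^2) - r^2
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(0)
  t1 <- max(0, (-B - sqrt(disc)) / (2 * A))
  t2 <- min(1, (-B + sqrt(disc)) / (2 * A))
  if (t2 <= t1) return(0)
  (t2 - t1) * sqrt(A)
}

#' Road density in a buffer
#'
#' Total polyline length clipped to the disc, in kilometres.
#'
#' @param site numeric \code{c(x, y)} (m).
#' @param polylines list of n x 2 coordinate matrices (consecutive rows are
#'   segments); an empty list gives 0.
#' @param radius buffer radius (m), positive.
#' @return length in km, non-decreasing in \code{radius}.
#' @export
road_density <- function(site, polylines, radius) {
  if (radius <= 0) stop("radius must be positive")
  xy <- site_xy(site)
  total <- 0
  for (pl in polylines) {
    pl <- as.matrix(pl)
    if (nrow(pl) < 2) next
    rel <- sweep(pl, 2, xy)
    for (i in seq_len(nrow(pl) - 1))
      total <- total + segment_in_circle(rel[i, ], rel[i + 1, ], radius)
  }
  total / 1000
}

# exact area of intersection of a simple polygon with the disc |p| <= r,
# polygon given relative to the disc centre; arc-decomposition form of
# Green's theorem: inside sub-edges contribute the triangle term
# cross(P,Q)/2, outside sub-edges the sector term r^2 * angle(P,Q)/2.
circle_polygon_area <- function(poly, r) {
  n <- nrow(poly)
  # orient counter-clockwise
  shoelace <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2]) / 2
  if (shoelace < 0) poly <- poly[n:1, , drop = FALSE]
  area <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    d <- b - a
    A <- sum(d^2)
    if (A == 0) next
    B <- 2 * sum(a * d)
    C <- sum(a^2) - r^2
    disc <- B^2 - 4 * A * C
    ts <- c(0, 1)
    if (disc > 0) {
      t1 <- (-B - sqrt(disc)) / (2 * A)
      t2 <- (-B + sqrt(disc)) / (2 * A)
      ts <- sort(unique(c(0, 1, pmin(1, pmax(0, c(t1, t2))))))
    }
    for (k in seq_len(length(ts) - 1)) {
      p <- a + ts[k] * d
      q <- a + ts[k + 1] * d
      mid <- a + (ts[k] + ts[k + 1]) / 2 * d
      if (sum(mid^2) <= r^2) {
        area <- area + 0.5 * (p[1] * q[2] - q[1] * p[2])
      } else {
        ang <- atan2(p[1] * q[2] - q[1] * p[2], sum(p * q))
        area <- area + 0.5 * r^2 * ang
      }
    }
  }
  abs(area)
}

# simple-polygon check: no two non-adjacent edges intersect
assert_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) stop("polygon needs >= 3 vertices")
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    denom <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(denom) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / denom
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / denom
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      s1 <- seg(i); s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ]))
        stop("self-intersecting polygon")
    }
  }
  invisible(TRUE)
}

#' Building area in a buffer
#'
#' Exact clipped polygon area inside the disc, in km^2. Self-intersecting
#' polygons raise a geometry error.
#'
#' @param site numeric \code{c(x, y)} (m).
#' @param polygons list of n x 2 vertex matrices (unclosed rings, m).
#' @param radius buffer radius (m), positive.
#' @return area in km^2, bounded by \eqn{\pi r^2}.
#' @export
building_area <- function(site, polygons, radius) {
  if (radius <= 0) stop("radius must be positive")
  xy <- site_xy(site)
  total <- 0
  for (pg in polygons) {
    pg <- as.matrix(pg)
    assert_simple_polygon(pg)
    total <- total + circle_polygon_area(sweep(pg, 2, xy), radius)
  }
  total / 1e6
}

#' Full site-by-covariate table across the radius grids
#'
#' @param sites data frame with \code{site_id}, \code{x}, \code{y} and
#'   optionally \code{land_use} and \code{occurrence} columns (carried
#'   through).
#' @param layers a \code{"landscape_layers"} list with \code{raster},
#'   \code{primary_roads}, \code{secondary_roads}, \code{buildings} (see
#'   \code{\link{synth_layers}}).
#' @param radii_forest radii (m) for forest cover
#'   (default 100, 200, 500, 1000, 2000, 3000, 4000, 5000).
#' @param radii_roads radii (m) for roads and buildings
#'   (default 100, 200, 500, 1000).
#' @return data frame of class \code{"site_covariate_table"} with one
#'   \code{<covariate>_<radius>} column per (covariate, radius); the radius
#'   grids are attached as attributes \code{radii_forest}/\code{radii_roads}.
#' @export
metrics_table <- function(sites, layers,
                          radii_forest = c(100, 200, 500, 1000, 2000, 3000,
                                           4000, 5000),
                          radii_roads = c(100, 200, 500, 1000)) {
  out <- sites[, intersect(c("site_id", "x", "y", "land_use", "occurrence"),
                           names(sites)), drop = FALSE]
  for (r in radii_forest)
    out[[paste0("forest_cover_", r)]] <- NA_real_
  for (r in radii_roads) {
    out[[paste0("primary_road_density_", r)]] <- NA_real_
    out[[paste0("secondary_road_density_", r)]] <- NA_real_
    out[[paste0("building_area_", r)]] <- NA_real_
  }
  for (i in seq_len(nrow(sites))) {
    xy <- c(sites$x[i], sites$y[i])
    res <- tryCatch({
      for (r in radii_forest)
        out[i, paste0("forest_cover_", r)] <-
          forest_cover(xy, layers$raster, r, site_id = sites$site_id[i])
      for (r in radii_roads) {
        out[i, paste0("primary_road_density_", r)] <-
          road_density(xy, layers$primary_roads, r)
        out[i, paste0("secondary_road_density_", r)] <-
          road_density(xy, layers$secondary_roads, r)
        out[i, paste0("building_area_", r)] <-
          building_area(xy, layers$buildings, r)
      }
      NULL
    }, error = function(e) e)
    if (!is.null(res))
      stop("covariate computation failed at site ", sites$site_id[i], ": ",
           conditionMessage(res))
  }
  attr(out, "radii_forest") <- radii_forest
  attr(out, "radii_roads") <- radii_roads
  class(out) <- c("site_covariate_table", class(out))
  out
}

#' Write a covariate table with a machine-readable metadata sidecar
#'
#' @param tab a \code{"site_covariate_table"}.
#' @param path CSV path; the JSON sidecar is written next to it as
#'   \code{<path>.meta.json}.
#' @export
write_metrics_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  meta <- list(radii_forest = attr(tab, "radii_forest"),
               radii_roads = attr(tab, "radii_roads"),
               units = list(forest_cover = "percent",
                            road_density = "km", building_area = "km2"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
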