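# Spatial sampling design: home ranges, availability points, patch circles,
# temporal thinning. All coordinates are planar metres (projected); geodetic
# coordinates are rejected, never converted.

#' Minimum convex polygon home range
#'
#' Delineates an individual's home range as the smallest convex polygon
#' containing all of its foraging locations, the classical MCP home-range
#' estimator.
#'
#' @param points A two-column matrix or data frame of planar coordinates in
#'   metres (columns `x`, `y`).
#' @param id Optional individual identifier, used only in error messages.
#' @return An object of class `mcp_polygon`: a closed-ring-implied matrix of
#'   hull vertices (columns `x`, `y`) in counter-clockwise order, each vertex
#'   one of the input points, with attribute `area` (square metres).
#' @details Coordinates that look geodetic (all |x| <= 180 and |y| <= 90 while
#'   spanning less than one unit) are rejected: the design works in projected
#'   metres. Collinear input is an error rather than a zero-area polygon
#'   because availability sampling downstream needs positive area.
#' @examples
#' hr <- minimum_convex_polygon(cbind(x = c(0, 4, 0), y = c(0, 0, 3)))
#' polygon_area(hr)  # 6
#' @export
minimum_convex_polygon <- function(points, id = NULL) {
  pts <- as_point_matrix(points)
  who <- if (is.null(id)) "point set" else paste0("individual '", id, "'")
  if (nrow(pts) < 3L) {
    stop_patchrsf("degenerate geometry for %s: need at least 3 points, got %d",
                  who, nrow(pts), class = "degenerate_geometry")
  }
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(idx) < 3L || abs(ring_area(pts[idx, , drop = FALSE])) < 1e-12) {
    stop_patchrsf("degenerate geometry for %s: points are collinear", who,
                  class = "degenerate_geometry")
  }
  hull <- pts[idx, , drop = FALSE]
  if (ring_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  dimnames(hull) <- list(NULL, c("x", "y"))
  structure(hull, class = "mcp_polygon", area = ring_area(hull))
}

#' Area of a polygon
#'
#' @param polygon An `mcp_polygon` or a vertex matrix (closed ring implied).
#' @return Area in square metres (shoelace formula).
#' @export
polygon_area <- function(polygon) {
  abs(ring_area(unclass_poly(polygon)))
}

# signed shoelace area; positive for counter-clockwise rings
ring_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

unclass_poly <- function(polygon) {
  v <- unclass(polygon)
  attr(v, "area") <- NULL
  v
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  pts <- unique(matrix(as.numeric(points), ncol = 2L,
                       dimnames = list(NULL, c("x", "y"))))
  if (!all(is.finite(pts))) {
    stop_patchrsf("non-finite coordinates in point set", class = "bad_coordinates")
  }
  looks_geodetic <- all(abs(pts[, 1L]) <= 180) && all(abs(pts[, 2L]) <= 90) &&
    nrow(pts) > 1L && max(apply(pts, 2L, function(z) diff(range(z)))) < 1
  if (looks_geodetic) {
    stop_patchrsf(paste0("coordinates look like longitude/latitude; ",
                         "planar metres are required (project first)"),
                  class = "bad_coordinates")
  }
  pts
}

#' Point-in-polygon test for convex polygons
#'
#' Boundary-inclusive (closed polygon): points exactly on an edge or vertex
#' count as inside, so availability samples adjacent to hull vertices are not
#' lost.
#'
#' @param points Two-column matrix of coordinates.
#' @param polygon An `mcp_polygon` (counter-clockwise convex ring).
#' @return Logical vector, one per point.
#' @export
points_in_polygon <- function(points, polygon) {
  v <- unclass_poly(polygon)
  pts <- matrix(as.numeric(points), ncol = 2L)
  scale <- max(abs(v), 1)
  eps <- 1e-9 * scale * scale
  inside <- rep(TRUE, nrow(pts))
  n <- nrow(v)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    cross <- (b[1L] - a[1L]) * (pts[, 2L] - a[2L]) -
             (b[2L] - a[2L]) * (pts[, 1L] - a[1L])
    inside <- inside & (cross >= -eps)
  }
  inside
}

#' Sample availability points inside a home range
#'
#' Draws random points uniformly inside the home-range polygon, excluding a
#' circular buffer around every used (foraging) location: the random points
#' may not fall within `exclusion_radius` metres of any used point. This is
#' the availability half of the use-availability design.
#'
#' @param home_range An `mcp_polygon`.
#' @param used Two-column matrix of used-point coordinates (may have 0 rows).
#' @param n Number of availability points to draw.
#' @param exclusion_radius Buffer radius in metres around used points
#'   (default 10).
#' @param seed Seed controlling the draw; the same seed reproduces the sample
#'   bit-for-bit.
#' @param max_attempts_per_point Rejection-sampling attempt budget, as a
#'   multiple of `n` (default 1000).
#' @param feasible_floor Minimum acceptable feasible fraction of the polygon's
#'   bounding box (default 0.005); designs below it error out.
#' @return An `n` x 2 matrix of coordinates. Every point is inside the
#'   (closed) polygon and at distance strictly greater than
#'   `exclusion_radius` from every used point. The attribute
#'   `feasible_fraction` carries the rejection sampler's estimate of the
#'   feasible share of the polygon's bounding box.
#' @export
sample_availability <- function(home_range, used, n,
                                exclusion_radius = 10, seed = 1L,
                                max_attempts_per_point = 1000L,
                                feasible_floor = 0.005) {
  stopifnot(n >= 0, exclusion_radius > 0)
  out <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y")))
  if (n == 0L) return(out)
  v <- unclass_poly(home_range)
  used <- matrix(as.numeric(used), ncol = 2L)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  r2 <- exclusion_radius^2

  set.seed(as.integer(seed %% 2147483647))
  budget <- max_attempts_per_point * n
  tried <- 0L
  kept <- 0L
  feasible_hits <- 0L
  acc <- matrix(NA_real_, nrow = n, ncol = 2L)
  batch <- max(256L, 4L * n)
  while (kept < n && tried < budget) {
    m <- min(batch, budget - tried)
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]), stats::runif(m, yr[1L], yr[2L]))
    tried <- tried + m
    ok <- points_in_polygon(cand, home_range)
    if (nrow(used) > 0L && any(ok)) {
      ci <- which(ok)
      d2min <- vapply(ci, function(j) {
        min((used[, 1L] - cand[j, 1L])^2 + (used[, 2L] - cand[j, 2L])^2)
      }, numeric(1L))
      ok[ci] <- d2min > r2
    }
    hits <- which(ok)
    feasible_hits <- feasible_hits + length(hits)
    if (length(hits) > 0L) {
      take <- hits[seq_len(min(length(hits), n - kept))]
      acc[kept + seq_along(take), ] <- cand[take, , drop = FALSE]
      kept <- kept + length(take)
    }
  }
  if (kept < n) {
    feas <- feasible_hits / tried
    stop_patchrsf(paste0("infeasible availability design: only %d of %d points ",
                         "placed; estimated feasible fraction %.4f of the ",
                         "bounding box (floor %.4f)"),
                  kept, n, feas, feasible_floor, class = "infeasible_design")
  }
  feas_est <- feasible_hits / tried
  if (feas_est < feasible_floor) {
    stop_patchrsf(paste0("infeasible availability design: feasible fraction ",
                         "%.4f below floor %.4f"), feas_est, feasible_floor,
                  class = "infeasible_design")
  }
  dimnames(acc) <- list(NULL, c("x", "y"))
  attr(acc, "feasible_fraction") <- feas_est
  acc
}

#' Extract patch-scale covariates around a point
#'
#' Measures the two ground-vegetation covariates inside a sampling circle
#' centred on a location: the proportion of bare ground `bare` (area fraction
#' of the circle over bare cells) and the mean vegetation height `height` in
#' cm over the vegetated part of the circle. The circle radius is 1 m for
#' most species presets and 5 m for woodlarks.
#'
#' @param landscape A `habitat_landscape` (see [make_landscape()]).
#' @param center Length-2 numeric (x, y) in metres.
#' @param radius Circle radius in metres (> 0).
#' @return A list with `bare` (in `[0, 1]`) and `height` (cm; 0 when no
#'   vegetated cell intersects the circle, so the covariate is defined
#'   everywhere).
#' @details The circle integral is evaluated on a fixed deterministic subgrid
#'   (spacing `radius / 32`), giving area weighting accurate to well under a
#'   percent at the default grains.
#' @export
sample_patch <- function(landscape, center, radius) {
  out <- sample_patches(landscape,
                        matrix(c(center[[1L]], center[[2L]]), 1L), radius)
  list(bare = unname(out[1L, "bare"]), height = unname(out[1L, "height"]))
}

#' Extract patch covariates for many centres at once
#'
#' Vectorized form of [sample_patch()].
#'
#' @param landscape A `habitat_landscape`.
#' @param centers Two-column coordinate matrix.
#' @param radius Circle radius in metres.
#' @return Matrix with one row per centre, columns `bare` and `height`.
#' @export
sample_patches <- function(landscape, centers, radius) {
  stopifnot(inherits(landscape, "habitat_landscape"), radius > 0)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  ext <- landscape$extent
  bad <- centers[, 1L] - radius < 0 | centers[, 2L] - radius < 0 |
    centers[, 1L] + radius > ext[1L] | centers[, 2L] + radius > ext[2L]
  if (any(bad)) {
    j <- which(bad)[1L]
    stop_patchrsf("patch circle at (%.1f, %.1f) r=%.1f exits the landscape extent",
                  centers[j, 1L], centers[j, 2L], radius, class = "out_of_bounds")
  }
  off <- patch_offsets(radius)
  g <- landscape$grain
  nr <- nrow(landscape$bare)
  m <- nrow(centers)
  n_off <- nrow(off)
  xs <- rep(centers[, 1L], each = n_off) + off[, 1L]
  ys <- rep(centers[, 2L], each = n_off) + off[, 2L]
  ix <- pmin.int(pmax.int(floor(xs / g), 0), ncol(landscape$bare) - 1L)
  iy <- pmin.int(pmax.int(floor(ys / g), 0), nr - 1L)
  idx <- iy + 1L + ix * nr
  bare_cells <- matrix(landscape$bare[idx], n_off, m)
  hh <- matrix(landscape$height[idx], n_off, m)
  bare <- colMeans(bare_cells)
  n_veg <- n_off - colSums(bare_cells)
  hsum <- colSums(hh * !bare_cells)
  height <- ifelse(n_veg > 0L, hsum / pmax(n_veg, 1L), 0)
  cbind(bare = bare, height = height)
}

# Deterministic subgrid of points covering a circle of given radius,
# spacing radius/32; cached per radius within a session.
patch_offsets <- local({
  cache <- new.env(parent = emptyenv())
  function(radius) {
    key <- format(radius, digits = 12)
    if (!is.null(cache[[key]])) return(cache[[key]])
    step <- radius / 32
    s <- seq(-radius + step / 2, radius - step / 2, by = step)
    gr <- expand.grid(dx = s, dy = s)
    keep <- gr$dx^2 + gr$dy^2 <= radius^2
    out <- as.matrix(gr[keep, , drop = FALSE])
    cache[[key]] <- out
    out
  }
})

#' Temporal thinning of a telemetry track
#'
#' Keeps consecutive foraging fixes only when recorded at least
#' `min_interval` seconds apart, unless the bird moved to another foraging
#' site in between (moved more than `site_radius` metres from the last kept
#' fix). Non-foraging fixes are never kept. A greedy forward pass, so the
#' output is a subsequence of the input and re-thinning is a no-op.
#'
#' @param track Data frame with columns `x`, `y`, `t` (seconds since track
#'   start, sorted increasing) and `activity` (`"foraging"` or `"other"`).
#' @param min_interval Minimum separation in seconds (default 300 = 5 min).
#' @param site_radius Distance in metres beyond which a fix counts as a new
#'   foraging site (default 10).
#' @return The thinned track (same columns, subset of rows).
#' @export
thin_track <- function(track, min_interval = 300, site_radius = 10) {
  stopifnot(is.data.frame(track),
            all(c("x", "y", "t", "activity") %in% names(track)))
  if (any(track$t < 0)) {
    stop_patchrsf("track times must be non-negative", class = "bad_track")
  }
  if (is.unsorted(track$t)) {
    stop_patchrsf("track must be sorted by time", class = "unsorted_track")
  }
  keep <- logical(nrow(track))
  last <- NULL
  for (i in seq_len(nrow(track))) {
    if (track$activity[i] != "foraging") next
    if (is.null(last)) {
      keep[i] <- TRUE
      last <- i
      next
    }
    dt <- track$t[i] - track$t[last]
    dd <- sqrt((track$x[i] - track$x[last])^2 + (track$y[i] - track$y[last])^2)
    if (dt >= min_interval || dd > site_radius) {
      keep[i] <- TRUE
      last <- i
    }
  }
  track[keep, , drop = FALSE]
}

#' @export
print.mcp_polygon <- function(x, ...) {
  cat(sprintf("Minimum convex polygon: %d vertices, area %.1f m^2\n",
              nrow(x), polygon_area(x)))
  invisible(x)
}
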