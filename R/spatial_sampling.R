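#' Lambert cylindrical equal-area projection
#'
#' Projects longitude/latitude (degrees) to planar km, centered by default on
#' the center of South America (15 S, 56 W) with the standard parallel at the
#' center latitude.  The projection is exactly equal-area, which is what the
#' gridding and range-overlay steps require.
#'
#' @param lon,lat Coordinates in degrees (or `x`,`y` in km when
#'   `inverse = TRUE`).
#' @param inverse Invert the projection?
#' @param lon0,lat0 Projection center (degrees).
#' @param radius Earth radius in km.
#' @return A tibble with columns `x`, `y` (km), or `lon`, `lat` (degrees)
#'   when `inverse = TRUE`.
#' @export
#' @examples
#' project_lambert(-56, -15)        # the center maps to (0, 0)
project_lambert <- function(lon, lat, inverse = FALSE,
                            lon0 = -56, lat0 = -15, radius = 6371.0088) {
  d2r <- pi / 180
  cs <- cos(lat0 * d2r)
  if (!inverse) {
    if (any(abs(lat) > 90) || any(abs(lon) > 360)) {
      stop("invalid lon/lat coordinates", call. = FALSE)
    }
    tibble::tibble(
      x = radius * cs * (lon - lon0) * d2r,
      y = radius * (sin(lat * d2r) - sin(lat0 * d2r)) / cs
    )
  } else {
    x <- lon
    y <- lat
    s <- y * cs / radius + sin(lat0 * d2r)
    if (any(abs(s) > 1 + 1e-12)) {
      stop("planar coordinates outside the projectable domain", call. = FALSE)
    }
    tibble::tibble(
      lon = x / (radius * cs) / d2r + lon0,
      lat = asin(pmin(1, pmax(-1, s))) / d2r
    )
  }
}

# ---- planar polygon primitives (polygons are n x 2 matrices, open rings) ----

polygon_area <- function(poly) {
  x <- poly[, 1L]
  y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# spherical-equivalent area in square degrees via inverse projection
polygon_area_sq_deg <- function(poly, ...) {
  ll <- project_lambert(poly[, 1L], poly[, 2L], inverse = TRUE, ...)
  polygon_area(cbind(ll$lon, ll$lat))
}

# ray-casting test, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# min distance from points to the polygon boundary (not signed)
dist_to_boundary <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1L]; ay <- poly[j, 2L]
    bx <- poly[i, 1L]; by <- poly[i, 2L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2)) else 0
    ex <- ax + t * dx - px
    ey <- ay + t * dy - py
    d2 <- pmin(d2, ex * ex + ey * ey)
    j <- i
  }
  sqrt(d2)
}

# does the disc (cx, cy, r) intersect the polygon?
disc_intersects_polygon <- function(cx, cy, r, poly) {
  point_in_polygon(cx, cy, poly) | dist_to_boundary(cx, cy, poly) <= r
}

# boundary length of polygon a lying within eps of polygon b's boundary
shared_boundary_length <- function(a, b, eps = 1e-6, n_samples = 400L) {
  per <- cbind(a, a[c(2:nrow(a), 1L), ])
  seg_len <- sqrt((per[, 3L] - per[, 1L])^2 + (per[, 4L] - per[, 2L])^2)
  total <- sum(seg_len)
  if (total == 0) return(0)
  s <- (seq_len(n_samples) - 0.5) / n_samples * total
  cum <- cumsum(seg_len)
  idx <- findInterval(s, c(0, cum), rightmost.closed = TRUE)
  along <- (s - c(0, cum)[idx]) / seg_len[idx]
  px <- per[idx, 1L] + along * (per[idx, 3L] - per[idx, 1L])
  py <- per[idx, 2L] + along * (per[idx, 4L] - per[idx, 2L])
  mean(dist_to_boundary(px, py, b) <= eps) * total
}

#' Construct a landscape of ecoregion polygons
#'
#' Bundles projected ecoregion polygons with their habitat class, regional
#' flags and shared-boundary adjacency.  Adjacency requires a shared boundary
#' of positive length (corner contact does not count).
#'
#' @param ecoregions A tibble with columns `ecoregion` (id), `habitat`
#'   (`"forest"` or `"open"`), `andes`, `atlantic` (logical), and `polygon`
#'   (list of `n x 2` matrices in projected km).
#' @param adjacency Optional logical adjacency matrix; derived from shared
#'   boundaries when omitted.
#' @param eps Distance tolerance (km) for the shared-boundary test.
#' @return An object of class `"landscape"`.
#' @export
new_landscape <- function(ecoregions, adjacency = NULL, eps = 1e-6) {
  need <- c("ecoregion", "habitat", "polygon")
  missing <- setdiff(need, names(ecoregions))
  if (length(missing)) {
    stop("ecoregions table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ecoregions$habitat %in% c("forest", "open"))) {
    stop("habitat must be 'forest' or 'open'", call. = FALSE)
  }
  if (anyDuplicated(ecoregions$ecoregion)) {
    stop("duplicated ecoregion ids", call. = FALSE)
  }
  ecoregions <- tibble::as_tibble(ecoregions)
  if (!"andes" %in% names(ecoregions)) ecoregions$andes <- FALSE
  if (!"atlantic" %in% names(ecoregions)) ecoregions$atlantic <- FALSE
  bad <- vapply(ecoregions$polygon,
                function(p) nrow(p) < 3L || polygon_area(p) <= 0, TRUE)
  if (any(bad)) {
    stop("degenerate polygon(s) for ecoregion(s): ",
         paste(ecoregions$ecoregion[bad], collapse = ", "), call. = FALSE)
  }
  ecoregions$area_km2 <- vapply(ecoregions$polygon, polygon_area, 1)
  ecoregions$area_sq_deg <- vapply(ecoregions$polygon, polygon_area_sq_deg, 1)
  n <- nrow(ecoregions)
  if (is.null(adjacency)) {
    adjacency <- matrix(FALSE, n, n,
                        dimnames = list(ecoregions$ecoregion,
                                        ecoregions$ecoregion))
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          len <- shared_boundary_length(ecoregions$polygon[[i]],
                                        ecoregions$polygon[[j]], eps = eps)
          adjacency[i, j] <- adjacency[j, i] <- len > 10 * eps
        }
      }
    }
  }
  structure(list(ecoregions = ecoregions, adjacency = adjacency),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  e <- x$ecoregions
  cat("Landscape: ", nrow(e), " ecoregions (",
      sum(e$habitat == "forest"), " forest, ", sum(e$habitat == "open"),
      " open), total area ", round(sum(e$area_km2)), " km^2\n", sep = "")
  invisible(x)
}

#' Grid-cell centroids inside each ecoregion
#'
#' Lays a global square grid of width `cell_width_km` over the projected
#' plane (cells aligned to the origin) and keeps the centroids falling inside
#' each ecoregion polygon; these are the candidate sampling points.
#'
#' @param landscape A `landscape`.
#' @param cell_width_km Grid cell width in km (default 26.4, half of which is
#'   the 13.2 km composition buffer).
#' @return A tibble `point_id, ecoregion, x, y`.  Ecoregions too small to
#'   contain any centroid are skipped with a warning.
#' @export
grid_centroids <- function(landscape, cell_width_km = 26.4) {
  stopifnot(inherits(landscape, "landscape"), cell_width_km > 0)
  w <- cell_width_km
  out <- purrr::pmap(
    landscape$ecoregions[c("ecoregion", "polygon")],
    function(ecoregion, polygon) {
      xr <- range(polygon[, 1L])
      yr <- range(polygon[, 2L])
      cx <- (seq(floor(xr[1L] / w), ceiling(xr[2L] / w)) + 0.5) * w
      cy <- (seq(floor(yr[1L] / w), ceiling(yr[2L] / w)) + 0.5) * w
      g <- expand.grid(x = cx, y = cy)
      keep <- point_in_polygon(g$x, g$y, polygon)
      tibble::tibble(ecoregion = ecoregion, x = g$x[keep], y = g$y[keep])
    }
  )
  empty <- vapply(out, nrow, 1L) == 0L
  if (any(empty)) {
    warning(sum(empty), " ecoregion(s) contain no grid centroid and were ",
            "skipped", call. = FALSE)
  }
  pts <- dplyr::bind_rows(out)
  dplyr::mutate(pts, point_id = dplyr::row_number(), .before = 1L)
}

#' Select core and ecotone points per ecoregion
#'
#' For each ecoregion, the `k` candidate points closest to the ecoregion
#' boundary become ecotone points and the `k` farthest become core points
#' (true planar point-to-boundary distances; ties at the k-th rank broken by
#' ascending point id).  An ecoregion with fewer than `2k` candidates
#' contributes `floor(n/2)` points per class, with a warning.
#'
#' @param points Candidate points from [grid_centroids()].
#' @param landscape The `landscape` the points were sampled from.
#' @param k Points per class per ecoregion (default 10).
#' @return A tibble `point_id, ecoregion, x, y, boundary_km, position` with
#'   `position` a factor (`core`, `ecotone`).
#' @export
select_core_ecotone <- function(points, landscape, k = 10L) {
  stopifnot(inherits(landscape, "landscape"), k >= 1L)
  polys <- setNames(landscape$ecoregions$polygon,
                    landscape$ecoregions$ecoregion)
  short <- 0L
  out <- points |>
    dplyr::group_by(.data$ecoregion) |>
    dplyr::group_map(function(g, key) {
      poly <- polys[[as.character(key$ecoregion)]]
      g$boundary_km <- dist_to_boundary(g$x, g$y, poly)
      g$ecoregion <- key$ecoregion
      kk <- k
      if (nrow(g) < 2L * k) {
        kk <- nrow(g) %/% 2L
        short <<- short + 1L
        if (kk == 0L) return(NULL)
      }
      g <- g[order(g$boundary_km, g$point_id), ]
      eco <- g[seq_len(kk), ]
      rest <- g[-seq_len(kk), , drop = FALSE]   # guarantees disjoint classes
      ord <- order(-rest$boundary_km, rest$point_id)
      core <- rest[sort(ord[seq_len(kk)]), ]
      eco$position <- "ecotone"
      core$position <- "core"
      dplyr::bind_rows(core, eco)
    }) |>
    dplyr::bind_rows()
  if (short > 0L) {
    warning(short, " ecoregion(s) had fewer than 2k candidate points; ",
            "floor(n/2) points per class used", call. = FALSE)
  }
  out$position <- factor(out$position, levels = c("core", "ecotone"))
  dplyr::arrange(out, .data$point_id)[
    c("point_id", "ecoregion", "x", "y", "boundary_km", "position")
  ]
}

#' Species composition around points from range polygons
#'
#' A species is present at a point when its range polygon intersects the disc
#' of radius `radius_km` around the point.  Afterwards (by default) the
#' exclusivity filter removes, within each ecoregion, every species found at
#' both core and ecotone points of that ecoregion, so the retained species
#' characterize one class only.
#'
#' @param points A point sample (see [select_core_ecotone()]).
#' @param ranges A tibble with columns `species` and `polygon` (projected
#'   km).
#' @param radius_km Buffer radius (default 13.2 km, half the grid cell).
#' @param exclusivity Apply [exclusivity_filter()]?
#' @return An occurrence tibble: the point metadata columns followed by one
#'   0/1 integer column per species.
#' @export
buffer_composition <- function(points, ranges, radius_km = 13.2,
                               exclusivity = TRUE) {
  stopifnot(radius_km > 0)
  bad <- vapply(ranges$polygon, function(p) nrow(p) < 3L, TRUE)
  if (any(bad)) {
    stop("invalid range polygon(s) for: ",
         paste(ranges$species[bad], collapse = ", "), call. = FALSE)
  }
  if (nrow(points) > 1L && nrow(points) <= 5000L) {
    dmin <- min(stats::dist(cbind(points$x, points$y)))
    if (2 * radius_km > dmin + 1e-9) {
      warning("buffer radius ", radius_km, " km exceeds half the minimum ",
              "inter-point spacing (", signif(dmin / 2, 4), " km); buffers ",
              "overlap", call. = FALSE)
    }
  }
  pres <- vapply(ranges$polygon, function(poly) {
    as.integer(disc_intersects_polygon(points$x, points$y, radius_km, poly))
  }, integer(nrow(points)))
  if (nrow(points) == 1L) pres <- matrix(pres, nrow = 1L)
  colnames(pres) <- ranges$species
  occ <- dplyr::bind_cols(points, tibble::as_tibble(pres))
  if (exclusivity) occ <- exclusivity_filter(occ) else occ
}

occ_species_cols <- function(occ) {
  meta <- c("point_id", "ecoregion", "x", "y", "boundary_km", "position")
  setdiff(names(occ), meta)
}

#' Exclusivity filter on an occurrence table
#'
#' Within each ecoregion, a species present at one or more core points *and*
#' one or more ecotone points of that ecoregion is removed (set absent) from
#' all of that ecoregion's points.  The filter is idempotent.
#'
#' @param occ An occurrence tibble (see [buffer_composition()]).
#' @return The filtered occurrence tibble.
#' @export
exclusivity_filter <- function(occ) {
  sp <- occ_species_cols(occ)
  for (eco in unique(occ$ecoregion)) {
    rows <- occ$ecoregion == eco
    m <- as.matrix(occ[rows, sp, drop = FALSE])
    at_core <- colSums(m[occ$position[rows] == "core", , drop = FALSE]) > 0
    at_eco <- colSums(m[occ$position[rows] == "ecotone", , drop = FALSE]) > 0
    drop <- at_core & at_eco
    if (any(drop)) {
      m[, drop] <- 0L
      occ[rows, sp] <- tibble::as_tibble(m)
    }
  }
  occ
}

#' Keep only small-ranged species
#'
#' Retains species whose range area (square degrees, measured on the
#' unprojected map) is strictly below the threshold; the default is the
#' first quartile of the sigmodontine range-size distribution, 4.16 square
#' degrees.
#'
#' @param ranges A tibble with columns `species` and `area_sq_deg`.
#' @param threshold_sq_deg Strict upper bound (default 4.16).
#' @return The filtered range tibble.
#' @export
small_range_filter <- function(ranges, threshold_sq_deg = 4.16) {
  if (is.null(ranges$area_sq_deg) || anyNA(ranges$area_sq_deg)) {
    stop("ranges must carry a complete 'area_sq_deg' column", call. = FALSE)
  }
  ranges[ranges$area_sq_deg < threshold_sq_deg, , drop = FALSE]
}

#' Model-ready covariate table for sampled points
#'
#' Builds the ecoregion-scale covariates used to model assemblage metrics:
#' position (reference `core`), habitat (reference `open`), their interaction
#' (reference `core-open`), the summed area of adjacent ecoregions (square
#' degrees), counts of forest- and open-habitat neighbor ecoregions whose
#' polygon overlaps the point's buffer, and Andes / Atlantic Rainforest
#' flags.  Quantitative columns are standardized to zero mean and unit
#' variance (when they vary).
#'
#' @inheritParams buffer_composition
#' @param landscape The `landscape`.
#' @param standardize Standardize the quantitative columns?
#' @return A tibble, one row per point.
#' @export
covariate_table <- function(points, landscape, radius_km = 13.2,
                            standardize = TRUE) {
  eco <- landscape$ecoregions
  idx <- match(points$ecoregion, eco$ecoregion)
  if (anyNA(idx)) {
    stop("unknown ecoregion id(s): ",
         paste(unique(points$ecoregion[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  adj <- landscape$adjacency
  nb_area <- numeric(nrow(points))
  n_forest <- integer(nrow(points))
  n_open <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    nbrs <- which(adj[idx[i], ])
    if (!length(nbrs)) next
    nb_area[i] <- sum(eco$area_sq_deg[nbrs])
    for (j in nbrs) {
      hit <- disc_intersects_polygon(points$x[i], points$y[i], radius_km,
                                     eco$polygon[[j]])
      if (hit) {
        if (eco$habitat[j] == "forest") n_forest[i] <- n_forest[i] + 1L
        else n_open[i] <- n_open[i] + 1L
      }
    }
  }
  habitat <- factor(eco$habitat[idx], levels = c("open", "forest"))
  position <- factor(as.character(points$position), levels = c("core", "ecotone"))
  inter <- factor(paste(position, habitat, sep = "-"),
                  levels = c("core-open", "core-forest",
                             "ecotone-open", "ecotone-forest"))
  std <- function(v) {
    if (!standardize) return(v)
    s <- sd(v)
    if (is.na(s) || s == 0) return(v - mean(v))
    (v - mean(v)) / s
  }
  tibble::tibble(
    point_id = points$point_id,
    ecoregion = points$ecoregion,
    position = position,
    habitat = habitat,
    position_habitat = inter,
    neighbor_area_sum = std(nb_area),
    n_overlap_forest = std(as.numeric(n_forest)),
    n_overlap_open = std(as.numeric(n_open)),
    andes = as.integer(eco$andes[idx]),
    atlantic = as.integer(eco$atlantic[idx])
  )
}

#' Moran's I with a permutation test
#'
#' Spatial autocorrelation of point values under inverse-distance,
#' row-standardized weights (or k-nearest-neighbour binary weights), with a
#' permutation p-value obtained by shuffling values over locations.
#'
#' @param values Numeric vector, one value per point.
#' @param coords Two-column matrix or data frame of planar coordinates.
#' @param weighting `"inverse_distance"` (default) or `"knn"`.
#' @param k Neighbours for `"knn"` weighting.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation draw.
#' @param alternative `"greater"` (default; positive autocorrelation),
#'   `"less"` or `"two.sided"`.
#' @return A one-row tibble: `observed_i`, `expected_i` (`-1/(n-1)`),
#'   `p_value`, `n_perm`.
#' @export
morans_i <- function(values, coords, weighting = c("inverse_distance", "knn"),
                     k = 8L, n_perm = 999L, seed = NULL,
                     alternative = c("greater", "less", "two.sided")) {
  weighting <- match.arg(weighting)
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 10L) stop("need at least 10 points", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  if (sd(values) == 0) {
    stop("constant values: Moran's I is undefined", call. = FALSE)
  }
  D <- as.matrix(stats::dist(coords))
  if (weighting == "inverse_distance") {
    W <- 1 / D
    diag(W) <- 0
    W[!is.finite(W)] <- 0
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1L)]
      W[i, nb] <- 1
    }
  }
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W <- W / rs
  s0 <- sum(W)
  stat <- function(v) {
    z <- v - mean(v)
    n / s0 * sum(W * tcrossprod(z)) / sum(z^2)
  }
  obs <- stat(values)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(values)), 1)
  p <- switch(alternative,
    greater = (1 + sum(perm >= obs)) / (n_perm + 1),
    less = (1 + sum(perm <= obs)) / (n_perm + 1),
    two.sided = {
      e <- -1 / (n - 1)
      (1 + sum(abs(perm - e) >= abs(obs - e))) / (n_perm + 1)
    }
  )
  tibble::tibble(observed_i = obs, expected_i = -1 / (n - 1),
                 p_value = p, n_perm = as.integer(n_perm))
}
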