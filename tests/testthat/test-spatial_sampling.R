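# a simple two-rectangle landscape used in several blocks (km coordinates)
two_rect_landscape <- function() {
  e <- tibble::tibble(
    ecoregion = 1:2,
    habitat = c("forest", "open"),
    andes = c(TRUE, FALSE),
    atlantic = c(FALSE, TRUE),
    polygon = list(
      cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
      cbind(c(100, 200, 200, 100), c(0, 0, 100, 100))
    )
  )
  new_landscape(e)
}

test_that("the projection is centered, invertible and equal-area", {
  p0 <- project_lambert(-56, -15)
  expect_equal(c(p0$x, p0$y), c(0, 0), tolerance = 1e-9)
  set.seed(1)
  lon <- runif(50, -80, -35)
  lat <- runif(50, -55, 12)
  xy <- project_lambert(lon, lat)
  ll <- project_lambert(xy$x, xy$y, inverse = TRUE)
  expect_equal(ll$lon, lon, tolerance = 1e-6)
  expect_equal(ll$lat, lat, tolerance = 1e-6)
  expect_error(project_lambert(-56, 95), "invalid")
})

test_that("projected polygon areas match a spherical oracle within 0.5%", {
  skip_if_not_installed("geosphere")
  # a ~1-degree quadrilateral away from the projection center
  lon <- c(-70, -69, -69, -70)
  lat <- c(-30, -30, -29, -29)
  xy <- project_lambert(lon, lat)
  planar_km2 <- tiptempo:::polygon_area(cbind(xy$x, xy$y))
  sph_km2 <- geosphere::areaPolygon(cbind(lon, lat)) / 1e6
  expect_lt(abs(planar_km2 - sph_km2) / sph_km2, 0.005)
})

test_that("grid centroids tile ecoregions and land inside their polygons", {
  ls <- two_rect_landscape()
  pts <- grid_centroids(ls, cell_width_km = 25)
  # each 100x100 rectangle holds a 4x4 grid of 25-km cell centers
  expect_identical(sum(pts$ecoregion == 1), 16L)
  expect_identical(sum(pts$ecoregion == 2), 16L)
  for (e in 1:2) {
    sub <- pts[pts$ecoregion == e, ]
    expect_true(all(tiptempo:::point_in_polygon(sub$x, sub$y,
                                                ls$ecoregions$polygon[[e]])))
  }
  # count agrees with a brute-force point-in-polygon scan on an irregular
  # polygon (an L-shape)
  ell <- tibble::tibble(
    ecoregion = 1L, habitat = "open",
    polygon = list(cbind(c(0, 120, 120, 60, 60, 0),
                         c(0, 0, 60, 60, 120, 120)))
  )
  ls2 <- new_landscape(ell)
  pts2 <- grid_centroids(ls2, cell_width_km = 20)
  centers <- expand.grid(x = seq(10, 110, by = 20), y = seq(10, 110, by = 20))
  brute <- sum(tiptempo:::point_in_polygon(centers$x, centers$y,
                                           ell$polygon[[1L]]))
  expect_identical(nrow(pts2), as.integer(brute))
})

test_that("core and ecotone points are the innermost and outermost ring", {
  ls <- two_rect_landscape()
  pts <- grid_centroids(ls, cell_width_km = 20)   # 5x5 per rectangle
  sel <- select_core_ecotone(pts, ls, k = 5L)
  expect_identical(nrow(sel), 20L)
  for (e in 1:2) {
    sub <- sel[sel$ecoregion == e, ]
    expect_identical(sum(sub$position == "core"), 5L)
    expect_identical(sum(sub$position == "ecotone"), 5L)
    expect_true(max(sub$boundary_km[sub$position == "ecotone"]) <=
                  min(sub$boundary_km[sub$position == "core"]))
    # no point in both classes
    expect_identical(anyDuplicated(sub$point_id), 0L)
  }
  # the center cell of a symmetric 5x5 grid is always a core point
  center <- pts[abs(pts$x - 50) < 1e-9 & abs(pts$y - 50) < 1e-9, ]
  expect_true(center$point_id %in% sel$point_id[sel$position == "core"])
  # deterministic under distance ties: rerunning yields identical selection
  sel2 <- select_core_ecotone(pts, ls, k = 5L)
  expect_identical(sel, sel2)
})

test_that("small ecoregions fall back to floor(n/2) per class with a warning", {
  ls <- two_rect_landscape()
  pts <- grid_centroids(ls, cell_width_km = 40)   # few candidates
  expect_warning(sel <- select_core_ecotone(pts, ls, k = 5L), "floor")
  n1 <- sum(pts$ecoregion == 1)
  expect_identical(sum(sel$ecoregion == 1), 2L * (n1 %/% 2L))
})

test_that("buffer composition matches brute-force disc-polygon intersection", {
  ls <- two_rect_landscape()
  pts <- grid_centroids(ls, cell_width_km = 25)
  sel <- select_core_ecotone(pts, ls, k = 3L)
  set.seed(5)
  ranges <- tibble::tibble(
    species = paste0("sp", 1:12),
    polygon = lapply(1:12, function(i) {
      cx <- runif(1, 0, 200)
      cy <- runif(1, 0, 100)
      r <- runif(1, 8, 45)
      ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
      cbind(cx + r * cos(ang), cy + r * sin(ang))
    })
  )
  occ <- buffer_composition(sel, ranges, radius_km = 12, exclusivity = FALSE)
  # brute force: dense sampling of the disc
  ang <- seq(0, 2 * pi, length.out = 181L)[-181L]
  rad <- seq(0, 1, length.out = 41L)
  for (i in seq_len(nrow(sel))) {
    for (s in seq_len(12L)) {
      px <- sel$x[i] + 12 * as.vector(outer(rad, cos(ang)))
      py <- sel$y[i] + 12 * as.vector(outer(rad, sin(ang)))
      brute <- any(tiptempo:::point_in_polygon(px, py,
                                               ranges$polygon[[s]])) ||
        any(tiptempo:::point_in_polygon(ranges$polygon[[s]][, 1],
                                        ranges$polygon[[s]][, 2],
                                        cbind(sel$x[i] + 12 * cos(ang),
                                              sel$y[i] + 12 * sin(ang))))
      expect_identical(occ[[ranges$species[s]]][i] == 1L, brute)
    }
  }
})

test_that("the exclusivity filter removes cross-class species and is idempotent", {
  ls <- two_rect_landscape()
  pts <- grid_centroids(ls, cell_width_km = 20)
  sel <- select_core_ecotone(pts, ls, k = 5L)
  # one range covering everything, one covering nothing
  everywhere <- cbind(c(-50, 250, 250, -50), c(-50, -50, 150, 150))
  nowhere <- cbind(c(500, 510, 510, 500), c(500, 500, 510, 510))
  ranges <- tibble::tibble(
    species = c("ubiquitous", "absent"),
    polygon = list(everywhere, nowhere)
  )
  raw <- buffer_composition(sel, ranges, radius_km = 9, exclusivity = FALSE)
  expect_true(all(raw$ubiquitous == 1L))   # present everywhere pre-filter
  expect_true(all(raw$absent == 0L))
  filt <- exclusivity_filter(raw)
  expect_true(all(filt$ubiquitous == 0L))  # dropped by exclusivity everywhere
  expect_identical(exclusivity_filter(filt), filt)   # idempotent
})

test_that("the small-range filter uses a strict threshold in square degrees", {
  ranges <- tibble::tibble(
    species = c("a", "b", "c"),
    area_sq_deg = c(0.02, 4.16, 18.30)
  )
  keep <- small_range_filter(ranges, 4.16)
  expect_identical(keep$species, "a")       # the boundary value is excluded
  expect_identical(nrow(small_range_filter(ranges, 0)), 0L)
  # the quartile profile of the real range-size distribution retains ~25%
  set.seed(6)
  meanlog <- log(18.30)
  sdlog <- (log(18.30) - log(4.16)) / stats::qnorm(0.75)
  big <- tibble::tibble(
    species = paste0("s", 1:4000),
    area_sq_deg = stats::rlnorm(4000, meanlog, sdlog)
  )
  frac <- nrow(small_range_filter(big, 4.16)) / 4000
  expect_lt(abs(frac - 0.25), 0.03)
})

test_that("covariates standardize correctly and respect the neighbor graph", {
  # 3-ecoregion strip: 1-2 adjacent, 2-3 adjacent, 1-3 not
  e <- tibble::tibble(
    ecoregion = 1:3,
    habitat = c("forest", "open", "forest"),
    andes = c(TRUE, FALSE, FALSE),
    atlantic = c(FALSE, FALSE, TRUE),
    polygon = list(
      cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
      cbind(c(100, 200, 200, 100), c(0, 0, 100, 100)),
      cbind(c(200, 300, 300, 200), c(0, 0, 100, 100))
    )
  )
  ls <- new_landscape(e)
  expect_true(ls$adjacency[1, 2] && ls$adjacency[2, 3])
  expect_false(ls$adjacency[1, 3])
  pts <- grid_centroids(ls, cell_width_km = 25)
  sel <- select_core_ecotone(pts, ls, k = 3L)
  cov_raw <- covariate_table(sel, ls, standardize = FALSE)
  # neighbor-area sums match a hand computation in square degrees
  a <- ls$ecoregions$area_sq_deg
  expect_equal(unique(cov_raw$neighbor_area_sum[cov_raw$ecoregion == 1]),
               a[2])
  expect_equal(unique(cov_raw$neighbor_area_sum[cov_raw$ecoregion == 2]),
               a[1] + a[3])
  expect_identical(levels(cov_raw$position), c("core", "ecotone"))
  expect_identical(levels(cov_raw$habitat), c("open", "forest"))
  expect_identical(levels(cov_raw$position_habitat)[1L], "core-open")
  expect_identical(unique(cov_raw$andes[cov_raw$ecoregion == 1]), 1L)
  cov_std <- covariate_table(sel, ls)
  for (col in c("neighbor_area_sum", "n_overlap_forest", "n_overlap_open")) {
    if (sd(cov_raw[[col]]) > 0) {
      expect_equal(mean(cov_std[[col]]), 0, tolerance = 1e-12)
      expect_equal(sd(cov_std[[col]]), 1, tolerance = 1e-12)
    }
  }
  expect_error(covariate_table(dplyr::mutate(sel, ecoregion = 99), ls),
               "unknown ecoregion")
})

test_that("Moran's I matches a brute-force double sum and ape", {
  set.seed(7)
  n <- 20
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  vals <- rnorm(n)
  got <- morans_i(vals, coords, n_perm = 99, seed = 1)
  # brute force with the same inverse-distance row-standardized weights
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    W[i, j] <- 1 / sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  W <- W / rowSums(W)
  z <- vals - mean(vals)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  brute <- n / sum(W) * num / sum(z^2)
  expect_equal(got$observed_i, brute, tolerance = 1e-12)
  skip_if_not_installed("ape")
  ref <- ape::Moran.I(vals, W)
  expect_equal(got$observed_i, ref$observed, tolerance = 1e-12)
})

test_that("Moran's I behaves at its limits", {
  set.seed(8)
  n <- 40
  coords <- cbind(seq_len(n) * 10, rep(0, n))
  vals <- coords[, 1] + rnorm(n, 0, 1)   # a smooth transect
  res <- morans_i(vals, coords, n_perm = 199, seed = 2)
  expect_gt(res$observed_i, 0.5)
  expect_lt(res$p_value, 0.02)
  # exchangeable values: I near its null expectation -1/(n-1)
  set.seed(9)
  perm_i <- replicate(200, {
    morans_i(sample(vals), coords, n_perm = 0 + 1, seed = NULL)$observed_i
  })
  expect_lt(abs(mean(perm_i) - (-1 / (n - 1))), 0.02)
  expect_error(morans_i(rep(1, n), coords), "constant")
  expect_error(morans_i(vals[1:5], coords[1:5, ]), "at least 10")
})
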