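#' Simulate a dated birth-death tree conditioned on tip count
#'
#' Forward constant-rate birth-death simulation by sequential waiting times:
#' starting from two lineages at the root, the process waits an
#' `Exp(k (birth + death))` time while `k` lineages are alive, speciating or
#' killing a uniformly chosen lineage at each event; when the extant count
#' first reaches `n_tips` the process runs one final full waiting time and
#' stops, so for a pure-birth process the expected root age is
#' `sum_{k=2..n} 1/(birth k)`.  Extinct lineages are pruned, leaving a dated
#' ultrametric tree with exactly `n_tips` extant tips labelled `t1..tn`.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth,death Speciation and extinction rates (per lineage per Ma);
#'   `birth > death >= 0`.
#' @param seed Optional seed.
#' @param max_tries Retry cap when all lineages go extinct.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth = 0.2, death = 0, seed = NULL,
                          max_tries = 100L) {
  stopifnot(n_tips >= 3L, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    phy <- sim_bd_once(n_tips, birth, death)
    if (!is.null(phy)) return(phy)
  }
  stop("all lineages went extinct in ", max_tries, " attempts", call. = FALSE)
}

sim_bd_once <- function(n_tips, birth, death) {
  rate <- birth + death
  cap <- 6L * n_tips + 64L
  parent <- integer(cap)
  t_start <- numeric(cap)
  t_end <- numeric(cap)
  kid1 <- integer(cap)
  kid2 <- integer(cap)
  extinct <- logical(cap)
  parent[1:2] <- 0L
  nid <- 2L
  alive <- c(1L, 2L)
  tt <- 0
  while (length(alive) < n_tips) {
    k <- length(alive)
    tt <- tt + rexp(1L, k * rate)
    pick <- sample.int(k, 1L)
    j <- alive[pick]
    if (runif(1L) < birth / rate) {
      if (nid + 2L > cap) {                 # grow storage
        grow <- function(v) c(v, vector(typeof(v), cap))
        parent <- grow(parent); t_start <- grow(t_start); t_end <- grow(t_end)
        kid1 <- grow(kid1); kid2 <- grow(kid2); extinct <- grow(extinct)
        cap <- 2L * cap
      }
      c1 <- nid + 1L
      c2 <- nid + 2L
      nid <- nid + 2L
      t_end[j] <- tt
      parent[c(c1, c2)] <- j
      t_start[c(c1, c2)] <- tt
      kid1[j] <- c1
      kid2[j] <- c2
      alive <- c(alive[-pick], c1, c2)
    } else {
      t_end[j] <- tt
      extinct[j] <- TRUE
      alive <- alive[-pick]
      if (length(alive) == 0L) return(NULL)
    }
  }
  tt <- tt + rexp(1L, n_tips * rate)
  t_end[alive] <- tt
  # labels: extant tips t1..tn in id order, extinct x1..xm
  lab <- character(nid)
  lab[alive[order(alive)]] <- paste0("t", seq_len(n_tips))
  ext_ids <- which(extinct[seq_len(nid)])
  lab[ext_ids] <- paste0("x", seq_along(ext_ids))
  nwk <- function(id) {
    len <- t_end[id] - t_start[id]
    if (kid1[id] == 0L) {
      paste0(lab[id], ":", format(len, digits = 17))
    } else {
      paste0("(", nwk(kid1[id]), ",", nwk(kid2[id]), "):",
             format(len, digits = 17))
    }
  }
  txt <- paste0("(", nwk(1L), ",", nwk(2L), ");")
  phy <- ape::read.tree(text = txt)
  if (length(ext_ids)) {
    phy <- ape::drop.tip(phy, lab[ext_ids])
  }
  phy
}

#' Simulate a trait history forward along a tree
#'
#' Forward CTMC simulation of a discrete character under rate matrix `Q`
#' along every branch, recording the full dwell-segment history (the ground
#' truth against which mapping and metrics can be checked).
#'
#' @param phy A `phylo` object.
#' @param Q A rate matrix (see [build_rate_matrix()]).
#' @param root_state Optional 1-based root state; drawn from the stationary
#'   distribution of `Q` when omitted.
#' @param seed Optional seed.
#' @return A list: `map` (a `mapped_history` holding the true history),
#'   `tip_states` (named character vector of state labels), `root_state`.
#' @export
simulate_trait_history <- function(phy, Q, root_state = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q) %||% paste0("s", seq_len(nrow(Q)))
  k <- nrow(Q)
  ntip <- ape::Ntip(phy)
  node_state <- integer(ntip + phy$Nnode)
  root <- ntip + 1L
  node_state[root] <- root_state %||%
    sample.int(k, 1L, prob = stationary_distribution(Q))
  pre <- ape::reorder.phylo(phy, "cladewise")
  ne <- nrow(pre$edge)
  st <- vector("list", ne)
  du <- vector("list", ne)
  nseg <- integer(ne)
  for (i in seq_len(ne)) {
    h <- forward_branch_history(node_state[pre$edge[i, 1L]],
                                pre$edge.length[i], Q)
    node_state[pre$edge[i, 2L]] <- h$state[length(h$state)]
    st[[i]] <- h$state
    du[[i]] <- h$duration
    nseg[i] <- length(h$state)
  }
  seg_idx <- sequence(nseg)
  segments <- tibble::tibble(
    node = rep(pre$edge[, 2L], nseg),
    seg = seg_idx,
    state = as.integer(unlist(st, use.names = FALSE)),
    duration = unlist(du, use.names = FALSE),
    state_change = seg_idx > 1L
  )
  segments <- segments[order(segments$node, segments$seg), ]
  map <- new_mapped_history(phy, node_state, segments, states,
                            tree_id = 1L, sim_id = 0L)
  tip_states <- setNames(states[node_state[seq_len(ntip)]], phy$tip.label)
  list(map = map, tip_states = tip_states,
       root_state = node_state[root])
}

#' Simulate a set of phylogenies sharing one tip set
#'
#' Emulates a posterior sample of dated trees: each member is an independent
#' birth-death draw over the same tip labels, optionally rescaled in depth by
#' a per-tree log-normal factor whose spread (`jitter`) controls the
#' between-phylogeny variance available to the within/between randomization
#' test.  With `fixed_topology = TRUE` a single base tree is drawn and only
#' the depth scaling varies (so `jitter = 0` gives identical trees).
#'
#' @inheritParams simulate_tree
#' @param n_trees Number of trees.
#' @param jitter Standard deviation of the log depth-scaling factor (>= 0).
#' @param fixed_topology Reuse one topology for all trees?
#' @return A validated `multiPhylo` of length `n_trees`.
#' @export
simulate_tree_set <- function(n_tips, n_trees, birth = 0.2, death = 0,
                              jitter = 0, fixed_topology = FALSE,
                              seed = NULL) {
  stopifnot(n_trees >= 1L, jitter >= 0)
  if (!is.null(seed)) set.seed(seed)
  base <- if (fixed_topology) simulate_tree(n_tips, birth, death) else NULL
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    phy <- base %||% simulate_tree(n_tips, birth, death)
    if (jitter > 0) {
      phy$edge.length <- phy$edge.length * exp(rnorm(1L, 0, jitter))
    }
    trees[[i]] <- phy
  }
  class(trees) <- "multiPhylo"
  validate_tree_set(trees, provenance = "simulate_tree_set")
}

# Sutherland-Hodgman clip of a polygon to an axis-aligned rectangle
clip_to_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(p, keep, cross_at) {
    n <- nrow(p)
    if (n == 0L) return(p)
    out <- matrix(0, 0, 2L)
    for (i in seq_len(n)) {
      a <- p[i, ]
      b <- p[if (i == n) 1L else i + 1L, ]
      ka <- keep(a)
      kb <- keep(b)
      if (ka) out <- rbind(out, a)
      if (xor(ka, kb)) out <- rbind(out, cross_at(a, b))
    }
    out
  }
  lerp <- function(a, b, t) a + t * (b - a)
  p <- poly
  p <- clip_edge(p, function(v) v[1L] >= xmin,
                 function(a, b) lerp(a, b, (xmin - a[1L]) / (b[1L] - a[1L])))
  p <- clip_edge(p, function(v) v[1L] <= xmax,
                 function(a, b) lerp(a, b, (xmax - a[1L]) / (b[1L] - a[1L])))
  p <- clip_edge(p, function(v) v[2L] >= ymin,
                 function(a, b) lerp(a, b, (ymin - a[2L]) / (b[2L] - a[2L])))
  p <- clip_edge(p, function(v) v[2L] <= ymax,
                 function(a, b) lerp(a, b, (ymax - a[2L]) / (b[2L] - a[2L])))
  p
}

#' Generate a synthetic landscape of rectangular ecoregions
#'
#' Tiles the projected plane (centered on the projection origin) with
#' `n_rows x n_cols` rectangular ecoregions, assigns forest/open habitat by
#' rule, flags the westernmost column as "Andes" and the easternmost as
#' "Atlantic Rainforest" stand-ins, and derives rook adjacency from shared
#' boundaries.
#'
#' @param n_rows,n_cols Grid dimensions (each >= 2).
#' @param ecoregion_size_km Side length of each rectangle (km).
#' @param habitat_rule `"checkerboard"` (default), `"random"` or `"blocks"`
#'   (west half forest, east half open).
#' @param seed Seed (used by `"random"`).
#' @return A `landscape` object.
#' @export
synthetic_landscape <- function(n_rows, n_cols, ecoregion_size_km = 150,
                                habitat_rule = c("checkerboard", "random",
                                                 "blocks"),
                                seed = NULL) {
  habitat_rule <- match.arg(habitat_rule)
  stopifnot(n_rows >= 2L, n_cols >= 2L, ecoregion_size_km > 0)
  if (!is.null(seed)) set.seed(seed)
  s <- ecoregion_size_km
  x0 <- -n_cols * s / 2
  y0 <- -n_rows * s / 2
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  habitat <- switch(habitat_rule,
    checkerboard = ifelse((grid$row + grid$col) %% 2L == 0L, "forest", "open"),
    random = sample(c("forest", "open"), nrow(grid), replace = TRUE),
    blocks = ifelse(grid$col <= n_cols / 2, "forest", "open")
  )
  polys <- purrr::map2(grid$col, grid$row, function(cc, rr) {
    xa <- x0 + (cc - 1L) * s
    ya <- y0 + (rr - 1L) * s
    cbind(c(xa, xa + s, xa + s, xa), c(ya, ya, ya + s, ya + s))
  })
  eco <- tibble::tibble(
    ecoregion = seq_len(nrow(grid)),
    row = grid$row, col = grid$col,
    habitat = habitat,
    andes = grid$col == 1L,
    atlantic = grid$col == n_cols,
    polygon = polys
  )
  new_landscape(eco, eps = 1e-6)
}

#' Generate synthetic species range polygons
#'
#' One disc-shaped range polygon per species with a right-skewed (log-normal)
#' area distribution, placed inside a randomly chosen ecoregion with a
#' controllable core/ecotone placement bias.  Affinity `+1` places the range
#' center at the candidate position farthest from the ecoregion boundary
#' (fully core-ward), `-1` at the closest (fully ecotone-ward), values in
#' between weight candidates smoothly; `0` is uniform.
#'
#' @param species Character vector of species names.
#' @param landscape A `landscape`.
#' @param meanlog,sdlog Log-normal parameters of range area in square
#'   degrees.
#' @param bias Scalar default affinity applied to all species.
#' @param affinity Optional per-species affinity vector in `[-1, 1]`,
#'   overriding `bias`.
#' @param seed Optional seed.
#' @param n_candidates Candidate centers examined per species.
#' @param n_vertices Vertices of the disc polygon.
#' @return A tibble `species, ecoregion, x, y, radius_km, area_sq_deg,
#'   polygon` (polygons clipped to the landscape extent).
#' @export
synthetic_ranges <- function(species, landscape, meanlog = log(0.15),
                             sdlog = 0.75, bias = 0, affinity = NULL,
                             seed = NULL, n_candidates = 100L,
                             n_vertices = 32L) {
  if (!is.null(seed)) set.seed(seed)
  affinity <- affinity %||% rep(bias, length(species))
  stopifnot(length(affinity) == length(species),
            all(abs(affinity) <= 1 + 1e-12))
  eco <- landscape$ecoregions
  all_xy <- do.call(rbind, eco$polygon)
  xr <- range(all_xy[, 1L])
  yr <- range(all_xy[, 2L])
  # km^2 per square degree near the projection center
  lat0 <- -15
  km2_per_sqdeg <- (pi * 6371.0088 / 180)^2 * cos(lat0 * pi / 180)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  out <- vector("list", length(species))
  for (i in seq_along(species)) {
    e <- sample.int(nrow(eco), 1L)
    poly <- eco$polygon[[e]]
    bx <- range(poly[, 1L])
    by <- range(poly[, 2L])
    cx <- runif(4L * n_candidates, bx[1L], bx[2L])
    cy <- runif(4L * n_candidates, by[1L], by[2L])
    keep <- point_in_polygon(cx, cy, poly)
    cx <- cx[keep][seq_len(min(n_candidates, sum(keep)))]
    cy <- cy[keep][seq_len(min(n_candidates, sum(keep)))]
    d <- dist_to_boundary(cx, cy, poly)
    f <- affinity[i]
    # affinities saturated to within 0.5% of +-1 engage the fully-biased
    # deterministic placement (the tanh coupling never reaches +-1 exactly)
    pick <- if (f >= 0.995) {
      which.max(d)
    } else if (f <= -0.995) {
      which.min(d)
    } else if (f == 0) {
      sample.int(length(d), 1L)
    } else {
      w <- exp(3 * f * d / max(d))
      sample.int(length(d), 1L, prob = w)
    }
    area_deg <- stats::rlnorm(1L, meanlog, sdlog)
    r <- sqrt(area_deg * km2_per_sqdeg / pi)
    disc <- cbind(cx[pick] + r * cos(ang), cy[pick] + r * sin(ang))
    disc <- clip_to_rect(disc, xr[1L], xr[2L], yr[1L], yr[2L])
    out[[i]] <- tibble::tibble(
      species = species[i], ecoregion = eco$ecoregion[e],
      x = cx[pick], y = cy[pick], radius_km = r,
      area_sq_deg = polygon_area_sq_deg(disc),
      polygon = list(disc)
    )
  }
  dplyr::bind_rows(out)
}

#' Assemble a complete synthetic study scenario
#'
#' Generates every input the pipeline needs -- a tree set, a true trait
#' history with tip states, a landscape and species ranges -- under one
#' master seed.  A planted effect couples range placement to the true
#' per-species transition count: with `planted_bias > 0`, species whose true
#' lineage history shows more state transitions receive ecotone-ward ranges
#' (so the assemblage-level transition-rate contrast ecotone minus core is
#' positive by construction); `planted_bias = 0` places ranges independently
#' of the trait history (the null scenario).
#'
#' @param n_species,n_trees,n_sim Design dimensions.
#' @param birth,death Tree simulation rates (per Ma).
#' @param rate True (equal) trait transition rate per Ma.
#' @param k_states Number of trait states (4 uses the diet-state labels).
#' @param n_rows,n_cols,ecoregion_size_km Landscape dimensions.
#' @param jitter Between-tree depth jitter (see [simulate_tree_set()]).
#' @param fixed_topology Share one topology across the tree set (default
#'   `TRUE`: the set emulates dating uncertainty on a common topology, the
#'   regime in which per-species histories stay identifiable; set `FALSE`
#'   to also randomize topology between trees).
#' @param planted_bias Strength of the planted core/ecotone contrast.
#' @param meanlog,sdlog Range-size distribution (square degrees).
#' @param seed Master seed.
#' @return An object of class `"synthetic_scenario"`: a list with `params`,
#'   `trees`, `Q_true`, `truth` (the true history), `tip_states`,
#'   `landscape`, `ranges`, and `affinity`.
#' @export
synthetic_scenario <- function(n_species = 40L, n_trees = 10L, n_sim = 10L,
                               birth = 0.25, death = 0, rate = 0.05,
                               k_states = 4L, n_rows = 4L, n_cols = 4L,
                               ecoregion_size_km = 150, jitter = 0.1,
                               fixed_topology = TRUE,
                               planted_bias = 0, meanlog = log(0.15),
                               sdlog = 0.75, seed = 1L) {
  params <- list(
    n_species = n_species, n_trees = n_trees, n_sim = n_sim, birth = birth,
    death = death, rate = rate, k_states = k_states, n_rows = n_rows,
    n_cols = n_cols, ecoregion_size_km = ecoregion_size_km, jitter = jitter,
    fixed_topology = fixed_topology,
    planted_bias = planted_bias, meanlog = meanlog, sdlog = sdlog, seed = seed
  )
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5L)
  states <- if (k_states == 4L) diet_state_levels else paste0("s", seq_len(k_states))
  Q <- build_rate_matrix(rate, "ER", k_states, states = states)
  trees <- simulate_tree_set(n_species, n_trees, birth, death, jitter,
                             fixed_topology = fixed_topology, seed = sub[1L])
  # reject degenerate (single observed state) histories so the Mk fit exists
  set.seed(sub[2L])
  for (i in 1:50) {
    truth <- simulate_trait_history(trees[[1L]], Q)
    if (length(unique(truth$tip_states)) >= 2L) break
  }
  landscape <- synthetic_landscape(n_rows, n_cols, ecoregion_size_km,
                                   seed = sub[3L])
  species <- sort(trees[[1L]]$tip.label)
  # the planted signal is the species' recent transition activity: the number
  # of state changes fixed at its final node-to-tip comparison.  Terminal
  # changes are nearly independent across species (deep changes are shared by
  # whole clades) and are the part of a lineage's history that tip data
  # identify best, so the planted contrast is recoverable in principle.
  tcounts <- vapply(species, function(sp) {
    p <- extract_lineage(truth$map, sp)
    m <- length(p$node_states)
    as.integer(p$node_states[m - 1L] != p$node_states[m])
  }, 1L)
  affinity <- if (planted_bias == 0 || sd(tcounts) == 0) {
    rep(0, length(species))
  } else {
    -tanh(planted_bias * as.numeric(scale(tcounts)))
  }
  ranges <- synthetic_ranges(species, landscape, meanlog, sdlog,
                             affinity = affinity, seed = sub[4L])
  structure(list(
    params = params, trees = trees, Q_true = Q, truth = truth,
    tip_states = truth$tip_states, landscape = landscape, ranges = ranges,
    affinity = setNames(affinity, species), map_seed = sub[5L]
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  p <- x$params
  cat("Synthetic scenario: ", p$n_species, " species, ", p$n_trees,
      " trees x ", p$n_sim, " sims, ", p$n_rows, "x", p$n_cols,
      " ecoregions, planted bias ", p$planted_bias, ", seed ", p$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a scenario manifest
#'
#' Records all scenario parameters and the master seed as JSON so a run can
#' be reproduced exactly.
#'
#' @param scenario A `synthetic_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_manifest <- function(scenario, path) {
  jsonlite::write_json(scenario$params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Grid sampling, core/ecotone selection, buffer composition with the
#' exclusivity filter, per-tree Mk fitting and stochastic mapping, the
#' estimate cube, assemblage means and the core/ecotone contrast.
#'
#' @param scenario A `synthetic_scenario`.
#' @param model Mk model used for mapping (default `"ER"`, matching the
#'   symmetric generating process).
#' @param k Core/ecotone points per class per ecoregion.
#' @param cell_width_km,radius_km Sampling-design parameters.
#' @return A list: `points`, `occ`, `maps`, `cube`, `assemblage`, `summary`,
#'   `contrast`.
#' @export
run_scenario <- function(scenario, model = "ER", k = 4L,
                         cell_width_km = 26.4, radius_km = 13.2) {
  p <- scenario$params
  pts <- grid_centroids(scenario$landscape, cell_width_km)
  sampled <- select_core_ecotone(pts, scenario$landscape, k = k)
  occ <- suppressWarnings(
    buffer_composition(sampled, scenario$ranges, radius_km)
  )
  maps <- simulate_maps(scenario$trees, scenario$tip_states, model = model,
                        n_sim = p$n_sim, seed = scenario$map_seed)
  cube <- compute_cube(maps)
  am <- suppressWarnings(assemblage_means(cube, occ))
  summ <- uncertainty_summary(am)
  list(points = sampled, occ = occ, maps = maps, cube = cube,
       assemblage = am, summary = summ,
       contrast = core_ecotone_contrast(am, sampled))
}

#' Core/ecotone contrast of assemblage metrics
#'
#' Mean assemblage metric over all ecotone (point, estimate) records minus
#' the mean over all core records, per metric.
#'
#' @param am An `assemblage_metrics` tibble.
#' @param points The point sample carrying the `position` factor.
#' @return A tibble `metric, mean_core, mean_ecotone, difference`.
#' @export
core_ecotone_contrast <- function(am, points) {
  df <- dplyr::inner_join(am, points[c("point_id", "position")],
                          by = "point_id")
  df <- df[stats::complete.cases(df[c("atr", "ast", "alt")]), ]
  long <- tidyr::pivot_longer(df, c("atr", "ast", "alt"),
                              names_to = "metric", values_to = "value")
  wide <- long |>
    dplyr::group_by(.data$metric, .data$position) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "position", values_from = "mean",
                       names_prefix = "mean_")
  if (is.null(wide$mean_core)) wide$mean_core <- NA_real_
  if (is.null(wide$mean_ecotone)) wide$mean_ecotone <- NA_real_
  wide$difference <- wide$mean_ecotone - wide$mean_core
  wide
}
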