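#' Assemblage-level tip-based metrics
#'
#' Averages the species-level metrics over the species present at each point,
#' for every (phylogeny, simulation) estimate, giving aTR, aST and aLT.  The
#' mean is unweighted (no abundance information exists at this scale).
#' Points with no species present get `NA` and a warning; they are excluded
#' by downstream summaries.
#'
#' @param cube An `estimate_cube` (see [compute_cube()]).
#' @param occ An occurrence tibble (see [buffer_composition()]).
#' @return A tibble of class `"assemblage_metrics"`: one row per
#'   (point, tree, simulation) with columns `point_id`, `tree_id`, `sim_id`,
#'   `atr`, `ast`, `alt`, plus per-point `richness`.
#' @export
assemblage_means <- function(cube, occ) {
  sp <- occ_species_cols(occ)
  missing <- setdiff(sp, unique(cube$species))
  if (length(missing)) {
    stop("species in the occurrence table but not in the cube: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  M <- as.matrix(occ[sp])
  storage.mode(M) <- "numeric"
  richness <- rowSums(M)
  if (any(richness == 0)) {
    warning(sum(richness == 0), " point(s) have no species present; their ",
            "assemblage metrics are NA", call. = FALSE)
  }
  est <- dplyr::distinct(cube[c("tree_id", "sim_id")])
  est <- est[order(est$tree_id, est$sim_id), ]
  ne <- nrow(est)
  sp_sorted <- sort(sp)
  sub <- cube[cube$species %in% sp_sorted, ]
  sub <- sub[order(sub$tree_id, sub$sim_id, match(sub$species, sp_sorted)), ]
  if (nrow(sub) != length(sp_sorted) * ne) {
    stop("cube is incomplete for the occurring species (",
         nrow(sub), " records, expected ", length(sp_sorted) * ne, ")",
         call. = FALSE)
  }
  # species x estimate matrices, species in sorted order
  to_mat <- function(v) matrix(v, nrow = length(sp_sorted), ncol = ne)
  TRm <- to_mat(sub$tr)
  STm <- to_mat(sub$st)
  LTm <- to_mat(sub$lt)
  Ms <- M[, sp_sorted, drop = FALSE]
  denom <- ifelse(richness == 0, NA_real_, richness)
  aTR <- (Ms %*% TRm) / denom
  aST <- (Ms %*% STm) / denom
  aLT <- (Ms %*% LTm) / denom
  out <- tibble::tibble(
    point_id = rep(occ$point_id, times = ne),
    tree_id = rep(est$tree_id, each = nrow(occ)),
    sim_id = rep(est$sim_id, each = nrow(occ)),
    atr = as.vector(aTR), ast = as.vector(aST), alt = as.vector(aLT),
    richness = rep(richness, times = ne)
  )
  class(out) <- c("assemblage_metrics", class(out))
  out
}

#' Per-point mean and uncertainty of assemblage metrics
#'
#' Mean and sample standard deviation (n-1 denominator) of each
#' assemblage-level metric across all (phylogeny, simulation) estimates;
#' the SD is the per-point measure of phylogenetic/mapping uncertainty used
#' for mapping.
#'
#' @param am An `assemblage_metrics` tibble (see [assemblage_means()]).
#' @return A tibble, one row per point: `point_id`, `richness`, and
#'   `mean`/`sd` columns for `atr`, `ast`, `alt`.
#' @export
uncertainty_summary <- function(am) {
  n_est <- dplyr::n_distinct(am$tree_id, am$sim_id)
  if (n_est < 2L) {
    stop("need at least 2 estimates to compute an SD", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(am, .data$point_id),
    richness = .data$richness[1L],
    dplyr::across(c("atr", "ast", "alt"), list(mean = mean, sd = sd)),
    .groups = "drop"
  )
}

#' Subsample (phylogeny, simulation) estimates
#'
#' Uniform without-replacement draw of `m` of the cube's estimate indices,
#' used to keep downstream model fitting tractable while preserving the
#' spread across phylogenies.
#'
#' @param cube An `estimate_cube` (or any tibble with `tree_id`, `sim_id`).
#' @param m Number of estimates to keep (study default 2000 of 10,000).
#' @param seed Optional seed.
#' @return A tibble of the sampled `tree_id`, `sim_id` pairs; filter the
#'   cube or the assemblage metrics with a semi-join on it.
#' @export
subsample_estimates <- function(cube, m = 2000L, seed = NULL) {
  est <- dplyr::distinct(cube, .data$tree_id, .data$sim_id)
  if (m > nrow(est)) {
    stop("m = ", m, " exceeds the ", nrow(est), " available estimates",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  est[sort(sample.int(nrow(est), m)), ]
}

#' Within- versus between-phylogeny variation of assemblage metrics
#'
#' Randomization test of where phylogenetic uncertainty comes from.  Each of
#' `n_rand` randomizations draws (a) a "within" set: `group_size` simulation
#' estimates from one randomly chosen phylogeny, and (b) a "between" set:
#' one simulation estimate from each of `group_size` randomly chosen distinct
#' phylogenies (the same simulation index for all of them by default).  For
#' each set the SD across the pooled estimates is computed per point and
#' averaged over points; the reported proportion is the fraction of
#' randomizations in which the within-phylogeny SD is the lower one.
#'
#' @param am An `assemblage_metrics` tibble.
#' @param n_rand Number of randomizations (default 1000).
#' @param group_size Estimates per set (default 10).
#' @param seed Optional seed.
#' @param between_mode `"shared_sim"` (default): the between set reuses one
#'   simulation index across its phylogenies; `"independent_sim"`: an
#'   independent simulation index per phylogeny.
#' @return A tibble with one row per metric: `metric`,
#'   `prop_within_lower`, `n_rand`.
#' @export
within_between_randomization <- function(am, n_rand = 1000L, group_size = 10L,
                                         seed = NULL,
                                         between_mode = c("shared_sim",
                                                          "independent_sim")) {
  between_mode <- match.arg(between_mode)
  trees <- sort(unique(am$tree_id))
  sims <- sort(unique(am$sim_id))
  if (length(trees) < group_size || length(sims) < group_size) {
    stop("need at least ", group_size, " phylogenies and ", group_size,
         " simulations per phylogeny", call. = FALSE)
  }
  pts <- sort(unique(am$point_id))
  keep <- stats::complete.cases(am[c("atr", "ast", "alt")])
  am_ok <- am[keep, ]
  pts <- intersect(pts, unique(am_ok$point_id))
  # 3-d arrays point x tree x sim for fast slicing
  arr <- function(col) {
    a <- array(NA_real_, c(length(pts), length(trees), length(sims)))
    i <- match(am_ok$point_id, pts)
    j <- match(am_ok$tree_id, trees)
    l <- match(am_ok$sim_id, sims)
    a[cbind(i, j, l)] <- am_ok[[col]]
    a
  }
  arrays <- list(atr = arr("atr"), ast = arr("ast"), alt = arr("alt"))
  if (!is.null(seed)) set.seed(seed)
  wins <- c(atr = 0L, ast = 0L, alt = 0L)
  row_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  }
  for (r in seq_len(n_rand)) {
    t0 <- sample(seq_along(trees), 1L)
    s10 <- sample(seq_along(sims), group_size)
    t10 <- sample(seq_along(trees), group_size)
    s0 <- if (between_mode == "shared_sim") {
      rep(sample(seq_along(sims), 1L), group_size)
    } else {
      sample(seq_along(sims), group_size, replace = TRUE)
    }
    for (met in names(arrays)) {
      a <- arrays[[met]]
      within_m <- a[, t0, s10, drop = FALSE]
      dim(within_m) <- c(length(pts), group_size)
      between_m <- matrix(
        vapply(seq_len(group_size), function(g) a[, t10[g], s0[g]],
               numeric(length(pts))),
        nrow = length(pts)
      )
      w <- mean(row_sd(within_m), na.rm = TRUE)
      b <- mean(row_sd(between_m), na.rm = TRUE)
      if (is.finite(w) && is.finite(b) && w < b) {
        wins[met] <- wins[met] + 1L
      }
    }
  }
  tibble::tibble(
    metric = names(wins),
    prop_within_lower = as.numeric(wins) / n_rand,
    n_rand = as.integer(n_rand)
  )
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree spanning the species
#' present, root-inclusive: the spanning subtree always includes the path up
#' to the root, so a single-species assemblage on an ultrametric tree of
#' height H has PD = H.
#'
#' @param phy A `phylo` object.
#' @param species Character vector of present tip labels (at least one).
#' @return PD in Ma (scalar).
#' @export
faith_pd <- function(phy, species) {
  if (!length(species)) stop("need at least one species", call. = FALSE)
  tips <- match(species, phy$tip.label)
  if (anyNA(tips)) {
    stop("species not in tree: ",
         paste(species[is.na(tips)], collapse = ", "), call. = FALSE)
  }
  par <- parent_map(phy)
  on_path <- logical(ape::Ntip(phy) + phy$Nnode)
  for (tp in tips) {
    v <- tp
    while (v != 0L && !on_path[v]) {
      on_path[v] <- TRUE
      v <- par[v]
    }
  }
  sum(phy$edge.length[on_path[phy$edge[, 2L]]])
}

#' Richness and PD per point
#'
#' @param occ An occurrence tibble.
#' @param phy A `phylo` object containing all occurring species.
#' @return A tibble `point_id, richness, pd` (PD is `NA` for empty points).
#' @export
assemblage_pd <- function(occ, phy) {
  sp <- occ_species_cols(occ)
  M <- as.matrix(occ[sp])
  pd <- apply(M, 1L, function(row) {
    present <- sp[row > 0]
    if (!length(present)) return(NA_real_)
    faith_pd(phy, present)
  })
  tibble::tibble(point_id = occ$point_id, richness = rowSums(M), pd = pd)
}
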