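# build a small estimate cube and occurrence table directly
make_cube <- function(n_sp = 4L, n_tree = 3L, n_sim = 2L, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(species = paste0("t", seq_len(n_sp)),
                      tree_id = seq_len(n_tree), sim_id = seq_len(n_sim),
                      stringsAsFactors = FALSE)
  cube <- tibble::tibble(
    species = grid$species, tree_id = grid$tree_id, sim_id = grid$sim_id,
    n_nodes = 5L, n_transitions = 2L,
    tr = runif(nrow(grid)), st = runif(nrow(grid), 0, 5),
    lt = runif(nrow(grid), 0, 8)
  )
  class(cube) <- c("estimate_cube", class(cube))
  cube
}

make_occ <- function(m, position = NULL) {
  n <- nrow(m)
  tibble::tibble(
    point_id = seq_len(n),
    ecoregion = rep(1L, n),
    x = seq_len(n) * 30, y = rep(0, n),
    boundary_km = seq_len(n),
    position = factor(position %||% rep(c("core", "ecotone"), length.out = n),
                      levels = c("core", "ecotone"))
  ) |> dplyr::bind_cols(tibble::as_tibble(m))
}

test_that("assemblage means are unweighted species averages", {
  cube <- make_cube()
  occ1 <- make_occ(matrix(c(1L, 0L, 0L, 0L), 1,
                          dimnames = list(NULL, paste0("t", 1:4))))
  am1 <- assemblage_means(cube, occ1)
  one <- cube[cube$species == "t1", ]
  expect_equal(am1$atr, one$tr[order(one$tree_id, one$sim_id)])
  # two species: plain average
  occ2 <- make_occ(matrix(c(1L, 1L, 0L, 0L), 1,
                          dimnames = list(NULL, paste0("t", 1:4))))
  am2 <- assemblage_means(cube, occ2)
  pair <- cube[cube$species %in% c("t1", "t2"), ]
  manual <- tapply(pair$tr, list(pair$tree_id, pair$sim_id), mean)
  expect_equal(sort(am2$atr), sort(as.vector(manual)))
  expect_true(all(am2$richness == 2))
})

test_that("assemblage means equal a loop-based recomputation", {
  set.seed(12)
  cube <- make_cube(n_sp = 6L, n_tree = 4L, n_sim = 3L, seed = 12)
  M <- matrix(rbinom(5L * 6L, 1L, 0.5), 5L, 6L,
              dimnames = list(NULL, paste0("t", 1:6)))
  M[3L, ] <- 0L                      # an empty point
  occ <- make_occ(M)
  expect_warning(am <- assemblage_means(cube, occ), "no species")
  for (r in sample(nrow(am), 40L)) {
    row <- am[r, ]
    present <- colnames(M)[M[row$point_id, ] > 0]
    if (!length(present)) {
      expect_true(is.na(row$atr) && is.na(row$ast) && is.na(row$alt))
      next
    }
    sub <- cube[cube$species %in% present & cube$tree_id == row$tree_id &
                  cube$sim_id == row$sim_id, ]
    expect_equal(row$atr, mean(sub$tr), tolerance = 1e-12)
    expect_equal(row$ast, mean(sub$st), tolerance = 1e-12)
    expect_equal(row$alt, mean(sub$lt), tolerance = 1e-12)
    # bounded by the species extremes
    expect_gte(row$atr, min(sub$tr) - 1e-12)
    expect_lte(row$atr, max(sub$tr) + 1e-12)
  }
  expect_error(assemblage_means(cube[cube$species != "t2", ], occ), "t2")
})

test_that("uncertainty summaries use the sample SD", {
  cube <- make_cube(n_sp = 2L, n_tree = 5L, n_sim = 4L, seed = 3)
  occ <- make_occ(matrix(c(1L, 1L), 1, dimnames = list(NULL, c("t1", "t2"))))
  am <- assemblage_means(cube, occ)
  s <- uncertainty_summary(am)
  expect_identical(nrow(s), 1L)
  expect_equal(s$atr_mean, mean(am$atr))
  expect_equal(s$atr_sd, sd(am$atr))     # n-1 denominator
  # constant estimates give SD 0; two estimates give |a-b|/sqrt(2)
  am2 <- am[am$sim_id <= 2L & am$tree_id == 1L, ]
  expect_equal(uncertainty_summary(am2)$ast_sd,
               abs(diff(am2$ast)) / sqrt(2))
  expect_error(uncertainty_summary(am[am$tree_id == 1L & am$sim_id == 1L, ]),
               "at least 2")
})

test_that("estimate subsampling is uniform, exact and seed-stable", {
  cube <- make_cube(n_sp = 2L, n_tree = 10L, n_sim = 10L, seed = 4)
  all_pairs <- dplyr::distinct(cube[c("tree_id", "sim_id")])
  full <- subsample_estimates(cube, m = 100L, seed = 5)
  expect_identical(nrow(full), 100L)
  expect_equal(dplyr::arrange(full, tree_id, sim_id),
               dplyr::arrange(all_pairs, tree_id, sim_id),
               ignore_attr = TRUE)
  s1 <- subsample_estimates(cube, m = 20L, seed = 6)
  s2 <- subsample_estimates(cube, m = 20L, seed = 6)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1), 0L)
  expect_error(subsample_estimates(cube, m = 101L), "exceeds")
  # long-run per-phylogeny frequencies are uniform
  set.seed(7)
  counts <- table(unlist(lapply(1:300, function(i) {
    subsample_estimates(cube, m = 20L)$tree_id
  })))
  expect_gt(chisq_pooled_p(as.numeric(counts), rep(0.1, 10)), 0.001)
})

test_that("the randomization separates phylogeny- from mapping-variance", {
  # synthetic assemblage metrics with controllable variance components
  build_am <- function(tree_sd, sim_sd, n_tree = 12L, n_sim = 12L,
                       n_pts = 4L, seed = 1L) {
    set.seed(seed)
    tree_eff <- rnorm(n_tree, 0, tree_sd)
    grid <- expand.grid(point_id = seq_len(n_pts), tree_id = seq_len(n_tree),
                        sim_id = seq_len(n_sim))
    val <- 1 + tree_eff[grid$tree_id] + rnorm(nrow(grid), 0, sim_sd)
    tibble::tibble(point_id = grid$point_id, tree_id = grid$tree_id,
                   sim_id = grid$sim_id, atr = val, ast = val, alt = val,
                   richness = 3)
  }
  # no between-tree signal: within vs between is symmetric -> prop near 0.5
  am_null <- build_am(tree_sd = 0, sim_sd = 1, seed = 21)
  p_null <- within_between_randomization(am_null, n_rand = 400L,
                                         group_size = 10L, seed = 22)
  expect_true(all(abs(p_null$prop_within_lower - 0.5) < 0.15))
  # strong tree effects, almost no mapping noise -> within nearly always lower
  am_tree <- build_am(tree_sd = 1, sim_sd = 0.01, seed = 23)
  p_tree <- within_between_randomization(am_tree, n_rand = 200L,
                                         group_size = 10L, seed = 24)
  expect_true(all(p_tree$prop_within_lower > 0.95))
  expect_true(all(p_tree$prop_within_lower <= 1))
  # reproducible under a fixed seed
  p_again <- within_between_randomization(am_tree, n_rand = 200L,
                                          group_size = 10L, seed = 24)
  expect_identical(p_tree, p_again)
  expect_error(within_between_randomization(am_tree[am_tree$tree_id <= 5, ]),
               "at least")
})

test_that("the randomization proportion matches a brute-force estimator", {
  set.seed(31)
  n_tree <- 10L
  n_sim <- 10L
  tree_eff <- rnorm(n_tree, 0, 0.5)
  grid <- expand.grid(point_id = 1L, tree_id = seq_len(n_tree),
                      sim_id = seq_len(n_sim))
  val <- tree_eff[grid$tree_id] + rnorm(nrow(grid), 0, 0.5)
  am <- tibble::tibble(point_id = grid$point_id, tree_id = grid$tree_id,
                       sim_id = grid$sim_id, atr = val, ast = val, alt = val,
                       richness = 1)
  got <- within_between_randomization(am, n_rand = 2000L, group_size = 10L,
                                      seed = 32)
  # independent brute force on the same value matrix
  V <- matrix(val, n_tree, n_sim)   # grid varies tree fastest? check below
  V <- matrix(NA_real_, n_tree, n_sim)
  V[cbind(grid$tree_id, grid$sim_id)] <- val
  set.seed(33)
  wins <- 0L
  reps <- 20000L
  for (r in seq_len(reps)) {
    wt <- sample(n_tree, 1L)
    within_sd <- sd(V[wt, sample(n_sim, 10L)])
    bs <- sample(n_sim, 1L)
    between_sd <- sd(V[sample(n_tree, 10L), bs])
    if (within_sd < between_sd) wins <- wins + 1L
  }
  brute <- wins / reps
  se <- sqrt(brute * (1 - brute) * (1 / reps + 1 / 2000))
  expect_lt(abs(got$prop_within_lower[1L] - brute), 4 * se + 0.02)
})

test_that("Faith's PD follows the root-inclusive spanning-subtree definition", {
  set.seed(41)
  phy <- simulate_tree(20, 0.3, seed = 411)
  # all tips: the whole tree
  expect_equal(faith_pd(phy, phy$tip.label), sum(phy$edge.length))
  # single tip on an ultrametric tree: the tree height
  h <- max(ape::node.depth.edgelength(phy))
  expect_equal(faith_pd(phy, phy$tip.label[1L]), h, tolerance = 1e-9)
  expect_error(faith_pd(phy, "nope"), "not in tree")
  expect_error(faith_pd(phy, character(0)), "at least one")
  # random subsets match a brute-force union of root-to-tip edge sets
  for (i in 1:20) {
    sp <- sample(phy$tip.label, sample(1:20, 1L))
    edges <- unique(unlist(lapply(sp, function(s) {
      path <- ape::nodepath(phy, from = ape::Ntip(phy) + 1L,
                            to = match(s, phy$tip.label))
      path[-1L]
    })))
    brute <- sum(phy$edge.length[match(edges, phy$edge[, 2L])])
    expect_equal(faith_pd(phy, sp), brute, tolerance = 1e-12)
  }
})

test_that("PD is monotone under species addition and matches picante", {
  set.seed(42)
  phy <- simulate_tree(15, 0.3, seed = 421)
  sp <- sample(phy$tip.label, 6L)
  pds <- vapply(seq_along(sp), function(i) faith_pd(phy, sp[seq_len(i)]), 1)
  expect_true(all(diff(pds) >= -1e-12))
  skip_if_not_installed("picante")
  comm <- matrix(0L, 2, ape::Ntip(phy),
                 dimnames = list(c("p1", "p2"), phy$tip.label))
  comm[1L, sp] <- 1L
  comm[2L, phy$tip.label[1:3]] <- 1L
  ref <- picante::pd(comm, phy, include.root = TRUE)
  expect_equal(faith_pd(phy, sp), ref$PD[1L], tolerance = 1e-9)
  expect_equal(faith_pd(phy, phy$tip.label[1:3]), ref$PD[2L], tolerance = 1e-9)
})

test_that("per-point richness and PD are tabulated together", {
  set.seed(43)
  phy <- simulate_tree(8, 0.3, seed = 431)
  M <- matrix(rbinom(3L * 8L, 1L, 0.6), 3L, 8L,
              dimnames = list(NULL, phy$tip.label))
  M[2L, ] <- 0L
  occ <- make_occ(M)
  res <- assemblage_pd(occ, phy)
  expect_equal(res$richness, rowSums(M), ignore_attr = TRUE)
  expect_true(is.na(res$pd[2L]))
  expect_equal(res$pd[1L], faith_pd(phy, colnames(M)[M[1L, ] > 0]))
})
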