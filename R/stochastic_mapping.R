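#' Jointly sample ancestral node states
#'
#' Draws internal-node states from their joint posterior given observed tip
#' states and a rate matrix: conditional likelihoods are computed by pruning,
#' the root state is drawn from `prior * partial`, and the remaining nodes
#' are drawn in preorder conditionally on their parent's draw (the standard
#' joint sampler used by stochastic character mapping).
#'
#' @inheritParams mk_loglik
#' @param n Number of independent joint draws.
#' @return An `n x (Ntip + Nnode)` integer matrix of 1-based state codes,
#'   with attribute `"states"`; tip columns repeat the observed states.
#' @export
sample_node_states <- function(phy, tip_states, Q, root_prior = "stationary",
                               n = 1L) {
  states <- rownames(Q) %||% paste0("s", seq_len(nrow(Q)))
  k <- nrow(Q)
  code <- align_tip_states(phy, tip_states, states)
  prior <- resolve_root_prior(root_prior, Q)
  pr <- mk_prune(phy, code, Q, prior)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  root <- ntip + 1L
  draws <- matrix(0L, n, ntip + nnode)
  draws[, seq_len(ntip)] <- matrix(code, n, ntip, byrow = TRUE)

  w <- prior * pr$partial[root, ]
  if (sum(w) <= 0) {
    stop("tip configuration has zero likelihood under Q; cannot sample",
         call. = FALSE)
  }
  draws[, root] <- sample.int(k, n, replace = TRUE, prob = w)

  # preorder: parents are drawn before children
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    chi <- pre$edge[i, 2L]
    if (chi <= ntip) next
    par <- pre$edge[i, 1L]
    len <- pre$edge.length[i]
    P <- prob_from_eigen(pr$eig, len)
    if (is.null(P) || anyNA(P)) P <- expm_series(unclass(Q) * len)
    # P(child = s | parent, tips below child) by parent state, vectorized
    for (ps in unique(draws[, par])) {
      sel <- which(draws[, par] == ps)
      w <- P[ps, ] * pr$partial[chi, ]
      if (sum(w) <= 0) {
        stop("zero conditional likelihood at node ", chi, call. = FALSE)
      }
      draws[sel, chi] <- sample.int(k, length(sel), replace = TRUE, prob = w)
    }
  }
  structure(draws, states = states)
}

# one forward CTMC path from state a over duration t; tibble(state, duration)
forward_branch_history <- function(a, t, Q) {
  k <- nrow(Q)
  st <- integer(0)
  dur <- numeric(0)
  cur <- a
  left <- t
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) {
      st <- c(st, cur); dur <- c(dur, left)
      break
    }
    w <- rexp(1L, rate)
    if (w >= left) {
      st <- c(st, cur); dur <- c(dur, left)
      break
    }
    st <- c(st, cur); dur <- c(dur, w)
    left <- left - w
    p <- Q[cur, ]
    p[cur] <- 0
    cur <- sample.int(k, 1L, prob = p)
  }
  list(state = st, duration = dur)
}

# powers of the uniformized transition matrix R, up to nmax
r_powers <- function(R, nmax) {
  out <- vector("list", nmax + 1L)
  out[[1L]] <- diag(nrow(R))
  for (n in seq_len(nmax)) out[[n + 1L]] <- out[[n]] %*% R
  out
}

# exact endpoint-conditioned path via uniformization
uniformization_history <- function(a, b, t, Q) {
  k <- nrow(Q)
  lam <- max(-diag(Q))
  if (lam <= 0) {
    if (a != b) stop("impossible endpoints under zero-rate Q", call. = FALSE)
    return(list(state = a, duration = t))
  }
  R <- diag(k) + unclass(Q) / lam
  p_ab <- transition_probabilities(Q, t)[a, b]
  if (p_ab <= 0) stop("endpoint pair has zero probability", call. = FALSE)
  nmax <- max(10L, ceiling(lam * t + 10 * sqrt(lam * t) + 10))
  Rp <- r_powers(R, nmax)
  wts <- vapply(0:nmax, function(n) dpois(n, lam * t) * Rp[[n + 1L]][a, b], 1)
  wts <- wts / sum(wts)
  nj <- sample.int(nmax + 1L, 1L, prob = wts) - 1L
  if (nj == 0L) return(list(state = a, duration = t))
  # sample the uniformized chain states given endpoints and nj jumps
  xs <- integer(nj + 1L)
  xs[1L] <- a
  xs[nj + 1L] <- b
  if (nj > 1L) {
    for (i in 2:nj) {
      w <- R[xs[i - 1L], ] * Rp[[nj - i + 2L]][, b]
      xs[i] <- sample.int(k, 1L, prob = w)
    }
  }
  times <- c(0, sort(runif(nj)) * t, t)
  # collapse virtual (self) jumps into dwell segments
  st <- integer(0)
  dur <- numeric(0)
  cur <- xs[1L]
  seg_start <- 0
  for (i in seq_len(nj)) {
    if (xs[i + 1L] != cur) {
      st <- c(st, cur); dur <- c(dur, times[i + 1L] - seg_start)
      seg_start <- times[i + 1L]
      cur <- xs[i + 1L]
    }
  }
  st <- c(st, cur); dur <- c(dur, t - seg_start)
  list(state = st, duration = dur)
}

#' Sample an endpoint-conditioned branch history
#'
#' Draws a complete dwell-segment path of the CTMC along one branch,
#' conditioned to start in `a` and end in `b` after time `t`.  Forward
#' rejection sampling is tried first (cheap at low rates, and exact); after
#' `max_reject` failed attempts the sampler falls back to uniformization,
#' which is exact and always terminates.
#'
#' @param a,b 1-based start and end state codes.
#' @param t Branch length (Ma), `>= 0`.
#' @param Q Rate matrix.
#' @param max_reject Rejection-attempt cap before the uniformization fallback.
#' @return A tibble with columns `state` (integer code) and `duration` (Ma);
#'   durations sum to `t`, consecutive states differ, first state is `a` and
#'   last is `b`.
#' @export
sample_branch_history <- function(a, b, t, Q, max_reject = 10000L) {
  path <- branch_path(a, b, t, Q, max_reject)
  tibble::tibble(state = as.integer(path$state), duration = path$duration)
}

# internal list-based path sampler (hot path; no tibble allocation)
branch_path <- function(a, b, t, Q, max_reject = 10000L) {
  if (t < 0) stop("'t' must be non-negative", call. = FALSE)
  if (t == 0) {
    if (a != b) stop("zero-length branch cannot change state", call. = FALSE)
    return(list(state = as.integer(a), duration = 0))
  }
  # rejection of forward paths is only cheap when few events are expected;
  # on long/fast branches uniformization is used directly (still exact)
  if (max(-diag(Q)) * t <= 15) {
    for (i in seq_len(max_reject)) {
      cand <- forward_branch_history(a, t, Q)
      if (cand$state[length(cand$state)] == b) return(cand)
    }
  }
  uniformization_history(a, b, t, Q)
}

new_mapped_history <- function(phy, node_state, segments, states,
                               tree_id = 1L, sim_id = 1L, seed = NA_integer_) {
  structure(list(
    tree = phy,
    node_state = as.integer(node_state),
    segments = segments,
    states = states,
    tree_id = as.integer(tree_id),
    sim_id = as.integer(sim_id),
    seed = seed
  ), class = "mapped_history")
}

#' @export
print.mapped_history <- function(x, ...) {
  cat("Stochastic character map (tree ", x$tree_id, ", simulation ", x$sim_id,
      ")\n", sep = "")
  cat("  ", ape::Ntip(x$tree), " tips, ", length(x$states), " states (",
      paste(x$states, collapse = ", "), ")\n", sep = "")
  cat("  ", nrow(x$segments), " dwell segments, ",
      sum(x$segments$state_change), " state changes\n", sep = "")
  invisible(x)
}

# draw one full map for a fitted Q; node states already sampled (vector)
map_from_node_states <- function(phy, node_state, Q, states,
                                 tree_id = 1L, sim_id = 1L) {
  ne <- nrow(phy$edge)
  st <- vector("list", ne)
  du <- vector("list", ne)
  nseg <- integer(ne)
  for (i in seq_len(ne)) {
    h <- branch_path(node_state[phy$edge[i, 1L]], node_state[phy$edge[i, 2L]],
                     phy$edge.length[i], Q)
    st[[i]] <- h$state
    du[[i]] <- h$duration
    nseg[i] <- length(h$state)
  }
  seg_idx <- sequence(nseg)
  segments <- tibble::tibble(
    node = rep(phy$edge[, 2L], nseg),
    seg = seg_idx,
    state = as.integer(unlist(st, use.names = FALSE)),
    duration = unlist(du, use.names = FALSE),
    state_change = seg_idx > 1L
  )
  segments <- segments[order(segments$node, segments$seg), ]
  new_mapped_history(phy, node_state, segments, states, tree_id, sim_id)
}

#' Draw one stochastic character map
#'
#' Samples joint node states, then an endpoint-conditioned path on every
#' branch.
#'
#' @inheritParams mk_loglik
#' @param tree_id,sim_id Provenance indices stored on the map.
#' @return A `mapped_history` object: the tree, integer node states, and a
#'   per-branch segment table `(node, seg, state, duration)` oriented
#'   parent-to-child.
#' @export
sample_map <- function(phy, tip_states, Q, root_prior = "stationary",
                       tree_id = 1L, sim_id = 1L) {
  states <- rownames(Q) %||% paste0("s", seq_len(nrow(Q)))
  ns <- sample_node_states(phy, tip_states, Q, root_prior, n = 1L)
  map_from_node_states(phy, ns[1L, ], Q, states, tree_id, sim_id)
}

# deterministic substream seeds: one per (tree, sim) cell
spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate stochastic maps across a tree set
#'
#' Refits the Mk model on every phylogeny (topology and branch lengths differ
#' across trees) and draws `n_sim` maps per tree.  One master seed spawns a
#' deterministic per-(tree, simulation) substream, so any subset of the
#' ensemble is reproducible in isolation.
#'
#' @param trees A validated `multiPhylo` (see [read_trees()],
#'   [validate_tree_set()]).
#' @param tip_states Named vector of tip states shared by all trees.
#' @param model Mk model class passed to [fit_mk()].
#' @param n_sim Simulations per tree.
#' @param seed Master seed (integer) for reproducibility.
#' @param root_prior Root prior mode for fitting and node sampling.
#' @param states Optional state labels.
#' @return A list of `mapped_history` objects of length
#'   `n_trees * n_sim` (minus skipped trees), with attributes `fits` (one
#'   `mk_fit` or `NULL` per tree) and `seed`.  Trees whose fit fails are
#'   skipped with a warning.
#' @export
simulate_maps <- function(trees, tip_states, model = "SYM", n_sim = 100L,
                          seed = NULL, root_prior = "stationary",
                          states = NULL) {
  trees <- validate_tree_set(trees)
  n_trees <- length(trees)
  sub <- spawn_seeds(seed, n_trees * n_sim)
  fits <- vector("list", n_trees)
  maps <- vector("list", n_trees * n_sim)
  n_fail <- 0L
  for (ti in seq_len(n_trees)) {
    fit <- tryCatch(
      fit_mk(trees[[ti]], tip_states, model = model, root_prior = root_prior,
             states = states),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      n_fail <- n_fail + 1L
      fits[ti] <- list(NULL)
      next
    }
    fits[[ti]] <- fit
    for (si in seq_len(n_sim)) {
      cell <- (ti - 1L) * n_sim + si
      set.seed(sub[cell])
      maps[[cell]] <- sample_map(trees[[ti]], tip_states, fit$Q,
                                 root_prior = fit$root_prior,
                                 tree_id = ti, sim_id = si)
      maps[[cell]]$seed <- sub[cell]
    }
  }
  if (n_fail > 0L) {
    warning(n_fail, " tree(s) skipped because the Mk fit failed", call. = FALSE)
  }
  maps <- maps[!vapply(maps, is.null, TRUE)]
  structure(maps, fits = fits, seed = seed, class = "mapped_history_list")
}

#' @export
print.mapped_history_list <- function(x, ...) {
  cat("List of ", length(x), " stochastic character maps\n", sep = "")
  invisible(x)
}

#' Serialize maps to a long segment table
#'
#' One row per dwell segment: `(tree_id, sim_id, node, seg, state, duration)`
#' where `node` is the child-node id of the branch.  The representation is
#' lossless: node states are recoverable from the segment endpoints.
#'
#' @param maps A list of `mapped_history` objects.
#' @return A tibble.
#' @seealso [maps_from_tibble()]
#' @export
maps_to_tibble <- function(maps) {
  if (inherits(maps, "mapped_history")) maps <- list(maps)
  dplyr::bind_rows(lapply(maps, function(m) {
    dplyr::mutate(
      m$segments[c("node", "seg", "state", "duration")],
      tree_id = m$tree_id, sim_id = m$sim_id,
      state = m$states[.data$state], .before = 1L
    )
  }))
}

#' Rebuild maps from a serialized segment table
#'
#' @param df A tibble as produced by [maps_to_tibble()].
#' @param trees The tree set the maps were drawn on (`tree_id` indexes it).
#' @param states State labels in canonical order; defaults to the sorted
#'   distinct states in `df`.
#' @return A list of `mapped_history` objects.
#' @export
maps_from_tibble <- function(df, trees, states = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  states <- states %||% sort(unique(df$state))
  keys <- dplyr::distinct(df, .data$tree_id, .data$sim_id)
  purrr::pmap(keys, function(tree_id, sim_id) {
    phy <- trees[[tree_id]]
    sdf <- df[df$tree_id == tree_id & df$sim_id == sim_id, ]
    sdf <- sdf[order(sdf$node, sdf$seg), ]
    code <- match(sdf$state, states)
    segments <- tibble::tibble(
      node = as.integer(sdf$node), seg = as.integer(sdf$seg),
      state = code, duration = sdf$duration,
      state_change = as.integer(sdf$seg) > 1L
    )
    ntip <- ape::Ntip(phy)
    node_state <- integer(ntip + phy$Nnode)
    last <- segments[!duplicated(segments$node, fromLast = TRUE), ]
    node_state[last$node] <- last$state
    root <- ntip + 1L
    first_child <- phy$edge[phy$edge[, 1L] == root, 2L][1L]
    node_state[root] <- segments$state[segments$node == first_child][1L]
    new_mapped_history(phy, node_state, segments, states, tree_id, sim_id)
  })
}
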