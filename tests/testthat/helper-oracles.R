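# Independent oracles used across the suite.  Everything here is deliberately
# naive (enumeration, double loops, quadrature) and shares no code with the
# implementation paths it checks.

`%||%` <- function(x, y) if (is.null(x)) y else x

# truncated-series matrix exponential (scaled and squared so the series
# converges for large-norm arguments)
series_expm <- function(A, n_terms = 60L) {
  s <- max(0L, ceiling(log2(max(abs(A)) + 1e-300)) + 1L)
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(n_terms)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# likelihood of tip states by exhaustive enumeration of internal-node states
enum_likelihood_terms <- function(phy, code, Q, prior) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  k <- nrow(Q)
  Ps <- lapply(seq_len(nrow(phy$edge)), function(i) {
    series_expm(unclass(Q) * phy$edge.length[i])
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  w <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    s <- integer(ntip + nnode)
    s[seq_len(ntip)] <- code
    s[ntip + seq_len(nnode)] <- grid[g, ]
    p <- prior[s[ntip + 1L]]
    for (i in seq_len(nrow(phy$edge))) {
      p <- p * Ps[[i]][s[phy$edge[i, 1L]], s[phy$edge[i, 2L]]]
    }
    w[g] <- p
  }
  list(grid = grid, weights = w)
}

enum_loglik <- function(phy, code, Q, prior) {
  log(sum(enum_likelihood_terms(phy, code, Q, prior)$weights))
}

# joint posterior over internal-node assignments (normalized enumeration)
enum_node_posterior <- function(phy, code, Q, prior) {
  terms <- enum_likelihood_terms(phy, code, Q, prior)
  list(grid = terms$grid, prob = terms$weights / sum(terms$weights))
}

# brute-force tip metrics: ape::nodepath + explicit run scan
brute_tip_metrics <- function(map, sp) {
  phy <- map$tree
  tipn <- match(sp, phy$tip.label)
  path <- ape::nodepath(phy, from = ape::Ntip(phy) + 1L, to = tipn)
  states <- integer(0)
  durs <- numeric(0)
  for (v in path[-1L]) {
    rows <- which(map$segments$node == v)
    rows <- rows[order(map$segments$seg[rows])]
    states <- c(states, map$segments$state[rows])
    durs <- c(durs, map$segments$duration[rows])
  }
  ns <- map$node_state[path]
  N <- length(path) - 1L
  t_chg <- 0L
  for (i in seq_len(length(ns) - 1L)) {
    if (ns[i] != ns[i + 1L]) t_chg <- t_chg + 1L
  }
  a <- ns[length(ns)]
  run_states <- integer(0)
  run_durs <- numeric(0)
  cur <- states[1L]
  len <- 0
  for (i in seq_along(states)) {
    if (states[i] != cur) {
      run_states <- c(run_states, cur)
      run_durs <- c(run_durs, len)
      cur <- states[i]
      len <- 0
    }
    len <- len + durs[i]
  }
  run_states <- c(run_states, cur)
  run_durs <- c(run_durs, len)
  list(
    tr = t_chg / N,
    st = max(run_durs[run_states == a]),
    lt = run_durs[length(run_durs)],
    t = t_chg, N = N
  )
}

# expected number of state changes of an endpoint-conditioned CTMC path,
# by quadrature over the transition flux
expected_cond_changes <- function(Q, a, b, t) {
  Pt <- series_expm(unclass(Q) * t)
  k <- nrow(Q)
  total <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      f <- function(s) {
        vapply(s, function(ss) {
          series_expm(unclass(Q) * ss)[a, i] * Q[i, j] *
            series_expm(unclass(Q) * (t - ss))[j, b]
        }, 1)
      }
      total <- total + stats::integrate(f, 0, t, rel.tol = 1e-8)$value
    }
  }
  total / Pt[a, b]
}

# chi-square goodness of fit with pooling of low-expectation cells
chisq_pooled_p <- function(counts, probs, min_expected = 5) {
  n <- sum(counts)
  exp_n <- probs * n
  ord <- order(exp_n, decreasing = TRUE)
  counts <- counts[ord]
  exp_n <- exp_n[ord]
  keep <- exp_n >= min_expected
  if (sum(!keep) > 0L) {
    counts <- c(counts[keep], sum(counts[!keep]))
    exp_n <- c(exp_n[keep], sum(exp_n[!keep]))
  }
  if (length(counts) < 2L) return(1)
  stat <- sum((counts - exp_n)^2 / exp_n)
  stats::pchisq(stat, df = length(counts) - 1L, lower.tail = FALSE)
}

# hand-built mapped_history: seg_df has node, seg, state, duration
make_map <- function(phy, node_state, seg_df, states) {
  seg_df <- seg_df[order(seg_df$node, seg_df$seg), ]
  seg_df$state_change <- seg_df$seg > 1L
  tiptempo:::new_mapped_history(phy, node_state, tibble::as_tibble(seg_df),
                                states)
}

# a random small tree with strictly positive branch lengths
random_small_tree <- function(n_tips, depth_scale = 1) {
  phy <- ape::rtree(n_tips)
  phy$edge.length <- (phy$edge.length + 0.05) * depth_scale
  phy
}

# random generator with off-diagonal rates in [lo, hi]
random_q <- function(k, lo = 0.1, hi = 1, model = "ARD") {
  nf <- if (model == "ARD") k * (k - 1L) else k * (k - 1L) / 2L
  build_rate_matrix(runif(nf, lo, hi), model, k)
}
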