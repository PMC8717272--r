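#' Extract a species' lineage history from a stochastic map
#'
#' Walks the root-to-tip path of one species through a sampled character
#' history and collects everything the tip-based metrics need: the node-state
#' sequence along the path (root, internal nodes, tip) and the concatenated
#' within-branch dwell segments.
#'
#' Conventions (configurable): `N` counts the internal nodes on the path,
#' root included and tip excluded, so the transition count `t` -- the number
#' of state changes over the `N` parent-child comparisons ending at the tip
#' -- satisfies `t <= N` and `TR = t/N` attains 1 when every comparison
#' changes state.  With `count_tip_node = TRUE` the tip itself is also
#' counted in `N`.
#'
#' @param map A `mapped_history` object.
#' @param species Tip label.
#' @param count_tip_node Include the tip in the node count `N`?
#' @return A `lineage_path` object: list with `species`, `tip_state`
#'   (integer code), `states` (labels), `nodes`, `node_states`, `node_ages`,
#'   `segments` (tibble `state`, `duration`, concatenated root-to-tip),
#'   `N`, `t`, and `depth` (root age minus tip age, Ma).
#' @export
extract_lineage <- function(map, species, count_tip_node = FALSE) {
  phy <- map$tree
  path <- lineage_nodes(phy, species)
  seg_by_node <- split(
    map$segments[c("state", "duration")],
    map$segments$node
  )
  segs <- dplyr::bind_rows(seg_by_node[as.character(path[-1L])])
  node_states <- map$node_state[path]
  ages <- node_ages(phy)[path]
  m <- length(path)
  N <- if (count_tip_node) m else m - 1L
  t_changes <- sum(node_states[-1L] != node_states[-m])
  structure(list(
    species = if (is.character(species)) species else phy$tip.label[species],
    tip_state = node_states[m],
    states = map$states,
    nodes = path,
    node_states = node_states,
    node_ages = ages,
    segments = segs,
    N = N,
    t = t_changes,
    depth = ages[1L] - ages[m],
    count_tip_node = count_tip_node
  ), class = "lineage_path")
}

#' @export
print.lineage_path <- function(x, ...) {
  cat("Lineage history of '", x$species, "': depth ", signif(x$depth, 4),
      " Ma, N = ", x$N, " nodes, t = ", x$t, " transitions, tip state '",
      x$states[x$tip_state], "'\n", sep = "")
  invisible(x)
}

# merge the concatenated segment sequence into maximal constant-state runs
lineage_runs <- function(states, durations) {
  if (!length(states)) return(list(state = integer(0), duration = numeric(0)))
  grp <- cumsum(c(TRUE, states[-1L] != states[-length(states)]))
  list(
    state = states[!duplicated(grp)],
    duration = as.numeric(rowsum(durations, grp))
  )
}

#' Transition rate of a lineage
#'
#' `TR = t / N`: the number of character-state transitions fixed at the
#' nodes of the species' root-to-tip path (including the final node-to-tip
#' comparison), divided by the number of nodes on that path.  Within-branch
#' excursions that return to the same state before the next node are not
#' counted.  `TR = 0` means the tip and all its ancestors share one state;
#' `TR = 1` means every comparison along the path changed state.
#'
#' @param path A `lineage_path` (see [extract_lineage()]).
#' @return A number in `[0, 1]`.
#' @export
transition_rate <- function(path) {
  if (path$N < 1L) stop("lineage has no nodes; cannot compute TR", call. = FALSE)
  path$t / path$N
}

#' Stasis time of a lineage
#'
#' The maximum contiguous time (Ma) the lineage spent in the current tip
#' state anywhere along its root-to-tip history.  Runs are built from the
#' within-branch dwell segments and merged across node boundaries when the
#' state does not change, so a brief within-branch excursion truncates a run
#' (and can reduce ST) even though it leaves TR unchanged.  If the lineage
#' never occupied the tip state before its terminal run, ST equals the
#' terminal run's duration.
#'
#' @inheritParams transition_rate
#' @param mode `"runs"` (default): maximum merged-run duration.
#'   `"branchwise"`: maximum single dwell interval, without merging across
#'   node boundaries (compatibility mode).
#' @return Stasis time in Ma, in `[0, depth]`.
#' @export
stasis_time <- function(path, mode = c("runs", "branchwise")) {
  mode <- match.arg(mode)
  a <- path$tip_state
  if (mode == "branchwise") {
    d <- path$segments$duration[path$segments$state == a]
    return(if (length(d)) max(d) else 0)
  }
  runs <- lineage_runs(path$segments$state, path$segments$duration)
  max(runs$duration[runs$state == a])
}

#' Last transition time of a lineage
#'
#' The duration (Ma) of the terminal contiguous run in the tip state: the
#' time elapsed since the lineage last entered the character state its tip
#' currently shows.  Equals the full lineage depth when the lineage never
#' changed state.
#'
#' @inheritParams transition_rate
#' @return Last transition time in Ma, in `[0, depth]`.
#' @export
last_transition_time <- function(path) {
  runs <- lineage_runs(path$segments$state, path$segments$duration)
  runs$duration[length(runs$duration)]
}

# fast per-tree path cache: node paths and per-path edge-child sequences
tree_path_cache <- function(phy, species) {
  lapply(setNames(species, species), function(sp) lineage_nodes(phy, sp))
}

#' Compute the estimate cube of tip-based metrics
#'
#' Evaluates TR, ST and LT for every species on every stochastic map,
#' yielding the species x phylogeny x simulation array of estimates (in long
#' form) that propagates both mapping and phylogenetic uncertainty.
#'
#' @param maps A list of `mapped_history` objects (see [simulate_maps()]).
#' @param species Species to include; default all tips.
#' @param count_tip_node Passed to [extract_lineage()].
#' @param st_mode Passed to [stasis_time()].
#' @return A tibble of class `"estimate_cube"` with one row per
#'   (species, tree, simulation): columns `species`, `tree_id`, `sim_id`,
#'   `n_nodes` (N), `n_transitions` (t), `tr`, `st`, `lt`.
#' @export
compute_cube <- function(maps, species = NULL, count_tip_node = FALSE,
                         st_mode = "runs") {
  if (inherits(maps, "mapped_history")) maps <- list(maps)
  stopifnot(length(maps) > 0L)
  species <- species %||% sort(maps[[1L]]$tree$tip.label)
  caches <- list()
  out <- vector("list", length(maps))
  for (mi in seq_along(maps)) {
    map <- maps[[mi]]
    missing <- setdiff(species, map$tree$tip.label)
    if (length(missing)) {
      stop("species absent from tree ", map$tree_id, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    key <- as.character(map$tree_id)
    if (is.null(caches[[key]])) {
      caches[[key]] <- tree_path_cache(map$tree, species)
    }
    paths <- caches[[key]]
    seg_state <- split(map$segments$state, map$segments$node)
    seg_dur <- split(map$segments$duration, map$segments$node)
    res <- matrix(0, length(species), 5L)
    for (si in seq_along(species)) {
      path <- paths[[species[si]]]
      m <- length(path)
      ns <- map$node_state[path]
      keys <- as.character(path[-1L])
      s_all <- unlist(seg_state[keys], use.names = FALSE)
      d_all <- unlist(seg_dur[keys], use.names = FALSE)
      N <- if (count_tip_node) m else m - 1L
      t_changes <- sum(ns[-1L] != ns[-m])
      a <- ns[m]
      if (st_mode == "runs") {
        runs <- lineage_runs(s_all, d_all)
        st <- max(runs$duration[runs$state == a])
        lt <- runs$duration[length(runs$duration)]
      } else {
        d <- d_all[s_all == a]
        st <- if (length(d)) max(d) else 0
        runs <- lineage_runs(s_all, d_all)
        lt <- runs$duration[length(runs$duration)]
      }
      res[si, ] <- c(N, t_changes, t_changes / N, st, lt)
    }
    out[[mi]] <- tibble::tibble(
      species = species, tree_id = map$tree_id, sim_id = map$sim_id,
      n_nodes = as.integer(res[, 1L]), n_transitions = as.integer(res[, 2L]),
      tr = res[, 3L], st = res[, 4L], lt = res[, 5L]
    )
  }
  cube <- dplyr::bind_rows(out)
  class(cube) <- c("estimate_cube", class(cube))
  cube
}

#' Grand means of an estimate cube
#'
#' One-row summary across all (species, phylogeny, simulation) records:
#' average transition count and path-node count, and average TR, ST and LT
#' with their standard deviations.
#'
#' @param x An `estimate_cube`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.estimate_cube <- function(x, ...) {
  tibble::tibble(
    n_species = dplyr::n_distinct(x$species),
    n_trees = dplyr::n_distinct(x$tree_id),
    n_sim = dplyr::n_distinct(x$sim_id),
    mean_transitions = mean(x$n_transitions),
    mean_nodes = mean(x$n_nodes),
    mean_tr = mean(x$tr), sd_tr = sd(x$tr),
    mean_st = mean(x$st), sd_st = sd(x$st),
    mean_lt = mean(x$lt), sd_lt = sd(x$lt)
  )
}

#' Per-species summary of an estimate cube
#'
#' @param cube An `estimate_cube`.
#' @return A tibble with per-species mean and SD of TR, ST and LT across all
#'   phylogenies and simulations.
#' @export
cube_species_summary <- function(cube) {
  dplyr::summarise(
    dplyr::group_by(cube, .data$species),
    dplyr::across(c("tr", "st", "lt"),
                  list(mean = mean, sd = sd)),
    n_estimates = dplyr::n(),
    .groups = "drop"
  )
}
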