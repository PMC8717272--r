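#' Read a set of dated phylogenies
#'
#' Reads one or more rooted, dated trees (branch lengths in Ma) from a Newick
#' or NEXUS file and validates them as a tree set: every tree must be rooted,
#' have finite non-negative branch lengths, unique tip labels, and all trees
#' must share an identical tip-label set (the tree axis of the estimate cube
#' assumes exchangeable tips across phylogenies).
#'
#' Polytomies are accepted; zero-length branches are legal.  Non-ultrametric
#' trees are tolerated with a warning, since trees containing taxonomically
#' imputed tips need not be exactly ultrametric.
#'
#' @param path Path to a tree file.
#' @param format `"auto"` (default; sniffs a leading `#NEXUS`), `"newick"` or
#'   `"nexus"`.
#' @return A validated `multiPhylo` object (length >= 1) with a
#'   `"provenance"` attribute recording the source path.
#' @seealso [write_trees()], [lineage_nodes()], [node_ages()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' trees <- read_trees(tf)
#' node_ages(trees[[1]])
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("tree file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- tryCatch(
    switch(format,
      newick = ape::read.tree(path),
      nexus  = ape::read.nexus(path)
    ),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(trees)) {
    stop("failed to parse ", format, " file '", path, "': no tree found",
         call. = FALSE)
  }
  if (inherits(trees, "phylo")) {
    trees <- c(trees)  # promote to multiPhylo
  }
  validate_tree_set(trees, provenance = path)
}

#' Write a tree set to Newick
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Validate a single dated tree
#'
#' Checks the structural invariants assumed throughout the package: rooted,
#' branch lengths present, finite and non-negative, unique tip labels.  Warns
#' (once) if the tree is not ultrametric beyond a small tolerance.
#'
#' @param phy A `phylo` object.
#' @param tol Relative tolerance on tip-age spread for the ultrametricity
#'   warning.
#' @return `phy`, invisibly.
#' @export
validate_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths (dated branches are required)", call. = FALSE)
  }
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    stop("tree has missing or non-finite branch lengths", call. = FALSE)
  }
  if (any(phy$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicated tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(phy)) stop("tree is not rooted", call. = FALSE)
  ages <- node_ages(phy)[seq_len(ape::Ntip(phy))]
  depth <- max(node_ages(phy))
  if (depth > 0 && diff(range(ages)) > tol * depth) {
    warning("tree is not ultrametric (tip ages span ",
            signif(diff(range(ages)), 3), " Ma); proceeding", call. = FALSE)
  }
  invisible(phy)
}

#' Validate a tree set
#'
#' Validates each member with [validate_tree()] and enforces identical tip
#' label sets across trees; a mismatch reports the symmetric difference.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) object.
#' @param provenance Optional string recorded on the result.
#' @return A `multiPhylo` object with a `"provenance"` attribute.
#' @export
validate_tree_set <- function(trees, provenance = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!length(trees)) stop("empty tree set", call. = FALSE)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_tree(trees[[i]])
    tips <- sort(trees[[i]]$tip.label)
    if (!identical(tips, ref)) {
      extra <- setdiff(tips, ref)
      missing <- setdiff(ref, tips)
      stop("tree ", i, " has a different tip set than tree 1; ",
           "only in tree ", i, ": {", paste(extra, collapse = ", "), "}; ",
           "only in tree 1: {", paste(missing, collapse = ", "), "}",
           call. = FALSE)
    }
  }
  if (!inherits(trees, "multiPhylo")) class(trees) <- "multiPhylo"
  attr(trees, "provenance") <- provenance %||% attr(trees, "provenance")
  trees
}

#' Node ages of a dated tree
#'
#' Ages in Ma before present, derived from branch lengths with the root age
#' set to the maximum root-to-tip path length.  Tips of an ultrametric tree
#' have age 0.
#'
#' @param phy A `phylo` object.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by node id.
#' @export
node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

# parent id of each node (0 for the root), indexed by node id
parent_map <- function(phy) {
  par <- integer(ape::Ntip(phy) + phy$Nnode)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

#' Root-to-tip node path
#'
#' Ordered node ids from the root down to a tip; consecutive elements are
#' parent and child.  This lineage (the rows of an adjacency matrix of a
#' species' evolutionary history) is the path on which all tip-based metrics
#' are computed.
#'
#' @param phy A `phylo` object.
#' @param tip A tip label or tip number.
#' @return Integer vector of node ids; first element is the root, last the tip.
#' @export
lineage_nodes <- function(phy, tip) {
  if (is.character(tip)) {
    idx <- match(tip, phy$tip.label)
    if (is.na(idx)) stop("unknown tip label: ", tip, call. = FALSE)
    tip <- idx
  }
  tip <- as.integer(tip)
  if (tip < 1L || tip > ape::Ntip(phy)) {
    stop("tip number out of range: ", tip, call. = FALSE)
  }
  par <- parent_map(phy)
  path <- tip
  while (par[path[1L]] != 0L) path <- c(par[path[1L]], path)
  path
}

#' Lineage depth of a tip
#'
#' Root age minus tip age: the total time span of a species' root-to-tip
#' history, the upper bound for its stasis and last-transition times.
#'
#' @inheritParams lineage_nodes
#' @return Numeric scalar (Ma).
#' @export
lineage_depth <- function(phy, tip) {
  ages <- node_ages(phy)
  path <- lineage_nodes(phy, tip)
  ages[path[1L]] - ages[path[length(path)]]
}
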