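#' Dated trees ("chronograms") and posterior traces of them
#'
#' A chronogram is a rooted phylogenetic tree whose branch lengths are
#' durations, so every node carries an age in Ma before present (larger =
#' older). Tips are extant by convention (age 0). Node ages are the
#' branch-length path sums from a node down to its descendant leaves; a valid
#' chronogram is ultrametric, i.e. all leaf path sums below a node agree.
#'
#' @name chronogram-class
#' @keywords internal
NULL

#' Construct a chronogram from a rooted `phylo` tree
#'
#' Node ages are computed as path sums from each node to its descendant
#' leaves. Non-ultrametric input is rejected by default; with
#' `on_violation = "repair"` each node is instead assigned the mean of its
#' leaf path sums. Strict parent-older-than-child ordering is enforced: a
#' parent/child age difference at or below `tol_tie` (absolute, Ma) is an
#' error, because zero-length time branches break the ordering semantics that
#' relative constraints rely on.
#'
#' @param phy a rooted `ape::phylo` object with unique, non-empty tip labels
#'   and branch lengths in time units (Ma).
#' @param on_violation `"reject"` (default) errors on ultrametricity
#'   violations; `"repair"` assigns each node the mean of its leaf path sums.
#' @param tol relative tolerance for the ultrametricity check (default 1e-6).
#' @param tol_tie absolute tolerance (Ma) below which a parent-child age
#'   difference is treated as a tie and rejected (default 1e-9).
#' @return an object of class `"chronogram"`: a list with elements `phy`
#'   (the topology) and `ages` (numeric, one age per node in `phy` node
#'   numbering; tips first).
#' @export
chronogram <- function(phy, on_violation = c("reject", "repair"),
                       tol = 1e-6, tol_tie = 1e-9) {
  on_violation <- match.arg(on_violation)
  if (!inherits(phy, "phylo"))
    abort_hgt("`phy` must be an ape 'phylo' object", "hgtclock_type_error")
  if (is.null(phy$edge.length))
    abort_hgt("tree has no branch lengths; cannot compute node ages",
              "hgtclock_parse_error")
  if (!ape::is.rooted(phy))
    abort_hgt("chronograms must be rooted", "hgtclock_parse_error")
  labs <- phy$tip.label
  if (anyDuplicated(labs) || any(!nzchar(labs)))
    abort_hgt("tip labels must be unique non-empty strings",
              "hgtclock_parse_error")

  paths <- leaf_path_stats(phy)
  viol <- ultrametric_violations(phy, paths, tol = tol)
  if (on_violation == "reject" && nrow(viol) > 0L)
    abort_hgt(sprintf(
      "tree is not ultrametric (%d leaf path-sum violation%s, first at leaf '%s'); parse with on_violation = \"repair\" to assign mean path sums",
      nrow(viol), if (nrow(viol) > 1L) "s" else "", viol$leaf[1L]),
      "hgtclock_not_ultrametric", violations = viol)

  ages <- paths$mean_tip_depth - paths$depth
  ages[seq_len(ape::Ntip(phy))] <- 0

  obj <- new_chronogram(phy, ages, check = FALSE)
  check_age_ordering(obj, tol_tie = tol_tie)
  obj
}

# Internal constructor used by the simulators, which build ages directly.
new_chronogram <- function(phy, ages, check = TRUE, tol_tie = 1e-9) {
  obj <- structure(list(phy = phy, ages = as.numeric(ages)),
                   class = "chronogram")
  if (check) check_age_ordering(obj, tol_tie = tol_tie)
  obj
}

# Depth (distance from root) per node, plus mean/min/max descendant tip depth.
leaf_path_stats <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  tipsum <- numeric(nn); tipmin <- rep(Inf, nn); tipmax <- rep(-Inf, nn)
  ntips_below <- integer(nn)
  tipsum[1:ntip] <- depth[1:ntip]
  tipmin[1:ntip] <- depth[1:ntip]
  tipmax[1:ntip] <- depth[1:ntip]
  ntips_below[1:ntip] <- 1L
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    tipsum[p] <- tipsum[p] + tipsum[ch]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
    tipmin[p] <- min(tipmin[p], tipmin[ch])
    tipmax[p] <- max(tipmax[p], tipmax[ch])
  }
  list(depth = depth, mean_tip_depth = tipsum / ntips_below,
       min_tip_depth = tipmin, max_tip_depth = tipmax)
}

# Per-leaf ultrametricity report: a leaf violates when its root-to-leaf path
# sum disagrees with the tree-wide median path sum beyond relative `tol`.
# The median is the reference so a single perturbed terminal branch flags
# only its own leaf.
ultrametric_violations <- function(phy, paths = leaf_path_stats(phy),
                                   tol = 1e-6) {
  ntip <- ape::Ntip(phy)
  tip_depth <- paths$depth[seq_len(ntip)]
  expected <- stats::median(tip_depth)
  scale <- max(expected, .Machine$double.eps)
  bad <- which(abs(tip_depth - expected) / scale > tol)
  data.frame(leaf = phy$tip.label[bad],
             expected_depth = rep(expected, length(bad)),
             observed_depth = tip_depth[bad],
             stringsAsFactors = FALSE)
}

#' Report ultrametricity violations of a tree
#'
#' Returns one row per leaf whose root-to-leaf path sum disagrees with the
#' tree-wide median path sum beyond the relative tolerance. An empty data
#' frame means the tree is ultrametric at that tolerance.
#'
#' @param x a `phylo` or `chronogram`.
#' @param tol relative tolerance (default 1e-6).
#' @return data frame with columns `leaf`, `expected_depth`, `observed_depth`.
#' @export
validate_ultrametric <- function(x, tol = 1e-6) {
  phy <- if (inherits(x, "chronogram")) x$phy else x
  ultrametric_violations(phy, tol = tol)
}

check_age_ordering <- function(x, tol_tie = 1e-9) {
  phy <- x$phy; ages <- x$ages
  d <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(d <= tol_tie)) {
    i <- which(d <= tol_tie)[1L]
    if (d[i] < -tol_tie)
      abort_hgt(sprintf(
        "age ordering violated: node %d (%.6g Ma) is not older than its child %d (%.6g Ma)",
        phy$edge[i, 1L], ages[phy$edge[i, 1L]],
        phy$edge[i, 2L], ages[phy$edge[i, 2L]]),
        "hgtclock_order_violation")
    abort_hgt(sprintf(
      "tie ages: node %d and its child %d have equal ages (%.6g Ma) within tolerance %g",
      phy$edge[i, 1L], phy$edge[i, 2L], ages[phy$edge[i, 1L]], tol_tie),
      "hgtclock_tie_age")
  }
  invisible(x)
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("<chronogram> %d tips, %d internal nodes, root age %.6g Ma\n",
              ape::Ntip(x$phy), x$phy$Nnode, root_age(x)))
  invisible(x)
}

#' Node ages of a chronogram
#' @param x a `chronogram`.
#' @return numeric vector of ages (Ma), one per node in `phylo` numbering
#'   (tips `1..Ntip`, then internal nodes).
#' @export
node_ages <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  x$ages
}

#' @rdname node_ages
#' @export
root_age <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  x$ages[root_node(x$phy)]
}

root_node <- function(phy) ape::Ntip(phy) + 1L

# phylo with branch lengths recomputed from node ages (for serialization)
as_dated_phylo <- function(x) {
  phy <- x$phy
  phy$edge.length <- x$ages[phy$edge[, 1L]] - x$ages[phy$edge[, 2L]]
  phy
}
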