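## Time trees are phylo objects whose edge lengths are durations in My.
## Node ages (Ma before present) are derived from the depth matrix plus an
## optional $root.age attribute; without it the youngest tip is placed at 0.

AGE_TOL <- 1e-6

#' Node ages of a dated tree
#'
#' @param tree a rooted \code{phylo} with branch lengths in My; if
#'   \code{tree$root.age} is set it anchors the depths, otherwise the
#'   youngest tip sits at age 0.
#' @return numeric vector of ages (Ma) indexed by node number
#'   (tips \code{1..n}, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  anchor <- if (!is.null(tree$root.age)) tree$root.age else max(depth)
  anchor - depth
}

#' Mark a dated tree's root age explicitly
#'
#' @param tree a \code{phylo}.
#' @param root_age age of the root in Ma.
#' @return the tree with \code{root.age} set.
#' @export
set_root_age <- function(tree, root_age) {
  tree$root.age <- root_age
  tree
}

## tips with age ~ 0 are extant
extant_tips <- function(tree, ages = node_ages(tree)) {
  n <- length(tree$tip.label)
  which(ages[seq_len(n)] < AGE_TOL)
}

## fossil tips attached by a zero-duration pendant branch represent sampled
## ancestors (degree-2 sampling events on the attachment node)
sampled_ancestor_tips <- function(tree, ages = node_ages(tree)) {
  n <- length(tree$tip.label)
  fossil <- setdiff(seq_len(n), extant_tips(tree, ages))
  pend <- tree$edge.length[match(fossil, tree$edge[, 2])]
  fossil[pend <= AGE_TOL]
}

#' Validate a dated tree against a tip-age table
#'
#' Checks that parent ages exceed child ages (zero-duration attachments
#' allowed only for sampled-ancestor fossils) and that every tip age lies in
#' its interval.
#'
#' @param tree a dated \code{phylo}.
#' @param ages a \code{tip_ages} table (optional).
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_time_tree <- function(tree, ages = NULL) {
  av <- node_ages(tree)
  parent_age <- av[tree$edge[, 1]]
  child_age <- av[tree$edge[, 2]]
  if (any(parent_age < child_age - AGE_TOL)) {
    stop("parent younger than child: tree is not a valid time tree")
  }
  if (!is.null(ages)) {
    idx <- match(tree$tip.label, ages$taxon)
    if (anyNA(idx)) {
      stop("tip-age table lacks: ",
           paste(tree$tip.label[is.na(idx)], collapse = ", "))
    }
    tip_age <- av[seq_along(tree$tip.label)]
    lo <- ages$min_ma[idx]; hi <- ages$max_ma[idx]
    bad <- tip_age < lo - AGE_TOL | tip_age > hi + AGE_TOL
    if (any(bad)) {
      stop("tip ages outside their intervals: ",
           paste(tree$tip.label[bad], collapse = ", "))
    }
  }
  invisible(TRUE)
}

## rebuild edge lengths of `tree` from a vector of node ages
tree_from_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree$root.age <- ages[length(tree$tip.label) + 1L]
  tree
}
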