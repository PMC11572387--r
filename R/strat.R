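## A-posteriori time-scaling of undated topologies against first-appearance
## dates and stratigraphic congruence indices (RCI, GER, MSM*) with
## permutation significance tests.

#' Basic time-scaling of a topology against tip ages
#'
#' Dates every node at the oldest first-appearance (interval maximum) among
#' its descendants. Zero-duration internal branches may be extended by a
#' minimum branch duration (default 0, i.e. none), pushing ancestral nodes
#' back in time.
#'
#' @param tree a \code{phylo} topology (branch lengths ignored).
#' @param ages a \code{tip_ages} table covering the tree's tips; the dating
#'   age of a tip is its first appearance, \code{max_ma} (configurable to
#'   the interval midpoint via \code{fad = "mid"}).
#' @param min_branch minimum internal branch duration (My).
#' @param fad \code{"max"} (first appearance) or \code{"mid"}.
#' @return dated \code{phylo} with \code{root.age} set.
#' @export
timescale_basic <- function(tree, ages, min_branch = 0, fad = "max") {
  idx <- match(tree$tip.label, ages$taxon)
  if (anyNA(idx)) {
    stop("missing ages for: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  tip_fad <- switch(fad,
    max = ages$max_ma[idx],
    mid = (ages$min_ma[idx] + ages$max_ma[idx]) / 2,
    stop("fad must be 'max' or 'mid'"))
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  av <- numeric(n_nodes)
  av[seq_len(n)] <- tip_fad
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    av[p] <- max(av[p], av[ch])
  }
  if (min_branch > 0) {     # push parents back to enforce minimum durations
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1]; ch <- edge[e, 2]
      if (ch > n) av[p] <- max(av[p], av[ch] + min_branch)
    }
  }
  tree$edge.length <- av[tree$edge[, 1]] - av[tree$edge[, 2]]
  tree$root.age <- av[n + 1L]
  tree
}

## minimum implied gap (sum of ghost ranges, My) of a topology dated by
## timescale_basic: every branch of the dated tree is unobserved lineage
mig_of_tree <- function(tree, tip_fad) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  av <- numeric(n_nodes)
  av[seq_len(n)] <- tip_fad
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    av[edge[e, 1]] <- max(av[edge[e, 1]], av[edge[e, 2]])
  }
  sum(av[edge[, 1]] - av[edge[, 2]])
}

## analytic bounds on MIG over all labeled binary topologies for a fixed
## set of first-appearance dates (perfectly age-ordered ladder vs the
## star-like worst case):
##   Gmin = oldest - youngest;  Gmax = sum_i (oldest - t_i)
mig_bounds <- function(tip_fad) {
  s <- sort(tip_fad, decreasing = TRUE)
  list(gmin = s[1] - s[length(s)], gmax = sum(s[1] - s[-1]))
}

## exhaustive bounds by enumerating all labeled topologies (small n)
mig_bounds_exhaustive <- function(tip_fad) {
  n <- length(tip_fad)
  labels <- paste0("t", seq_len(n))
  trees <- phangorn::allTrees(n, rooted = TRUE, tip.label = labels)
  migs <- vapply(trees, function(tr)
    mig_of_tree(tr, tip_fad[match(tr$tip.label, labels)]), 1)
  list(gmin = min(migs), gmax = max(migs))
}

#' Stratigraphic congruence indices with permutation tests
#'
#' Dates the topology with \code{\link{timescale_basic}}, computes the
#' minimum implied gap (MIG, the sum of ghost-range durations), the sum of
#' observed range lengths (SRL), the best and worst possible MIG over
#' labeled topologies (exhaustive enumeration for <= \code{exhaustive_n}
#' tips, analytic bounds otherwise) and the derived indices
#' RCI = (1 - MIG/SRL) * 100, GER = 1 - (MIG - Gmin)/(Gmax - Gmin),
#' MSM* = Gmin/MIG. Significance is assessed by permuting ages among tips:
#' p = (1 + #permutations with fit at least as good)/(permutations + 1).
#'
#' @param tree a \code{phylo} topology.
#' @param ages a \code{tip_ages} table (FAD = \code{max_ma}, LAD =
#'   \code{min_ma}; SRL is the sum of interval lengths).
#' @param permutations number of age permutations.
#' @param seed integer seed for the permutation test.
#' @param exhaustive_n exhaustive Gmin/Gmax for up to this many tips.
#' @return object of class \code{strat_fit}: list with \code{mig},
#'   \code{srl}, \code{gmin}, \code{gmax}, \code{rci}, \code{ger},
#'   \code{msm}, \code{p_values} (per index), \code{bounds_method},
#'   \code{degenerate}.
#' @export
strat_indices <- function(tree, ages, permutations = 1000, seed = NULL,
                          exhaustive_n = 8) {
  if (length(tree$tip.label) < 3) stop("need at least 3 tips")
  if (!is.null(seed)) set.seed(seed)
  idx <- match(tree$tip.label, ages$taxon)
  if (anyNA(idx)) stop("missing ages for some tips")
  fad <- ages$max_ma[idx]
  lad <- ages$min_ma[idx]
  srl <- sum(fad - lad)
  degenerate <- max(fad) - min(fad) < 1e-12
  mig <- mig_of_tree(tree, fad)
  n <- length(fad)
  bounds_method <- if (n <= exhaustive_n) "exhaustive" else "analytic"
  b <- if (bounds_method == "exhaustive") mig_bounds_exhaustive(fad)
       else mig_bounds(fad)
  rci <- (1 - mig / srl) * 100
  ger <- if (b$gmax > b$gmin) 1 - (mig - b$gmin) / (b$gmax - b$gmin)
         else NA_real_
  msm <- if (mig > 0) b$gmin / mig else NA_real_

  p_values <- c(rci = NA, ger = NA, msm = NA)
  if (!degenerate && permutations > 0) {
    hits <- c(rci = 0, ger = 0, msm = 0)
    for (b_i in seq_len(permutations)) {
      perm <- sample.int(n)
      mig_p <- mig_of_tree(tree, fad[perm])
      ## Gmin/Gmax and SRL are invariant under permutation, so all three
      ## indices are monotone in -MIG: "fit >= observed" <=> MIG_perm <= MIG
      if (mig_p <= mig + 1e-12) hits <- hits + 1
    }
    p_values <- (1 + hits) / (permutations + 1)
  }
  structure(list(mig = mig, srl = srl, gmin = b$gmin, gmax = b$gmax,
                 rci = rci, ger = ger, msm = msm, p_values = p_values,
                 bounds_method = bounds_method, degenerate = degenerate),
            class = "strat_fit")
}

#' @export
print.strat_fit <- function(x, ...) {
  cat(sprintf("strat_fit: MIG %.3f My, SRL %.3f My (%s bounds)\n",
              x$mig, x$srl, x$bounds_method))
  cat(sprintf("  RCI %.2f (p %.3g), GER %.3f (p %.3g), MSM* %.3f (p %.3g)\n",
              x$rci, x$p_values["rci"], x$ger, x$p_values["ger"],
              x$msm, x$p_values["msm"]))
  if (x$degenerate) cat("  NOTE: all tip ages equal; indices degenerate\n")
  invisible(x)
}
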