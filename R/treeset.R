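## Consensus construction, rogue-taxon detection and tree-set pruning.

#' Majority-rule consensus of a tree set
#'
#' Contains exactly the non-trivial splits whose frequency strictly exceeds
#' \code{threshold} (splits at exactly the threshold are excluded, keeping
#' the consensus a function of the sample alone), annotated with their
#' frequencies as node labels.
#'
#' @param trees \code{multiPhylo} (or list) of trees on one taxon set.
#' @param threshold frequency threshold in [0.5, 1).
#' @return a \code{phylo}, possibly multifurcating; node labels carry split
#'   frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  trees <- as_multiphylo(trees)
  if (threshold < 0.5 || threshold >= 1) stop("threshold must be in [0.5, 1)")
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) stop("trees have different taxon sets")
  }
  ## ape handles the split counting; p slightly above threshold excludes
  ## splits at exactly the threshold under strict majority
  cons <- ape::consensus(trees, p = threshold + 1e-9, check.labels = TRUE)
  freq <- split_frequencies(trees)
  keys <- vapply(seq_len(cons$Nnode), function(i) {
    node <- length(cons$tip.label) + i
    side <- cons$tip.label[unlist(phangorn::Descendants(cons, node, "tips"))]
    canonical_split(side, taxa)
  }, "")
  cons$node.label <- sprintf("%.3f", ifelse(keys %in% names(freq),
                                            freq[keys], 1))
  cons
}

as_multiphylo <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ## expand ape's compressed storage (shared TipLabel attribute) so that
  ## plain iteration sees each tree's labels
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees
}

canonical_split <- function(side, taxa) {
  if (taxa[1] %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "|")
}

#' Split frequencies of a tree set
#'
#' @param trees trees on a common taxon set.
#' @return named numeric vector: canonical split string -> frequency in
#'   [0, 1]; non-trivial splits only.
#' @export
split_frequencies <- function(trees) {
  trees <- as_multiphylo(trees)
  taxa <- sort(trees[[1]]$tip.label)
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (s in tree_splits(tr, taxa)) {
      counts[[s]] <- (if (is.null(counts[[s]])) 0 else counts[[s]]) + 1
    }
  }
  keys <- ls(counts)
  out <- vapply(keys, function(k) counts[[k]] / length(trees), 1)
  names(out) <- keys
  out
}

## phylogenetic information content of a split with side sizes a, b:
## -log2 P(a random unrooted binary tree contains it)
## = log2 U(a+b) - log2 U(a+1) - log2 U(b+1), with U(m) = (2m-5)!!
split_information <- function(a, b) {
  ldf <- function(m) {            # log2 (2m-5)!! for m >= 3
    if (m < 3) return(0)
    sum(log2(seq(2 * m - 5, 1, by = -2)))
  }
  ldf(a + b) - ldf(a + 1) - ldf(b + 1)
}

## total information content of the majority consensus of a tree sample:
## sum over retained splits of support * split information
consensus_information <- function(trees, threshold = 0.5) {
  trees <- as_multiphylo(trees)
  n <- length(trees[[1]]$tip.label)
  freq <- split_frequencies(trees)
  keep <- freq[freq > threshold]
  if (!length(keep)) return(0)
  sizes <- lengths(strsplit(names(keep), "|", fixed = TRUE))
  info <- vapply(seq_along(keep), function(i)
    split_information(sizes[i], n - sizes[i]), 1)
  sum(keep * info)
}

#' Detect rogue taxa by greedy consensus-information maximization
#'
#' Iteratively removes the taxon whose deletion most increases the
#' information content of the majority-rule consensus (the sum over retained
#' splits of per-split phylogenetic information weighted by support),
#' stopping when no single removal improves it.
#'
#' @param trees tree sample on a common taxon set (>= 2 distinct trees for
#'   a meaningful result).
#' @param threshold consensus threshold.
#' @param max_drop cap on the number of removals.
#' @return data.frame with columns \code{taxon} (in removal order) and
#'   \code{gain} (information increase); zero rows if no rogues.
#' @export
detect_rogues <- function(trees, threshold = 0.5, max_drop = NULL) {
  trees <- as_multiphylo(trees)
  taxa <- trees[[1]]$tip.label
  if (is.null(max_drop)) max_drop <- max(0L, length(taxa) - 4L)
  base <- consensus_information(trees, threshold)
  dropped <- character(0)
  gains <- numeric(0)
  current <- trees
  while (length(dropped) < max_drop) {
    remaining <- setdiff(taxa, dropped)
    if (length(remaining) <= 4) break
    cand <- vapply(remaining, function(tx) {
      consensus_information(prune_sample(current, tx), threshold)
    }, 1)
    best <- which.max(cand)
    if (cand[best] <= base + 1e-12) break
    gains <- c(gains, cand[best] - base)
    base <- cand[best]
    dropped <- c(dropped, remaining[best])
    current <- prune_sample(current, remaining[best])
  }
  data.frame(taxon = dropped, gain = gains, stringsAsFactors = FALSE)
}

#' Prune taxa from every tree of a sample
#'
#' Removes the given taxa with degree-2 suppression; on dated trees branch
#' durations merge so node ages are preserved.
#'
#' @param trees tree sample.
#' @param drop taxa to remove.
#' @return pruned \code{multiPhylo} (single \code{phylo} in, single out).
#' @export
prune_sample <- function(trees, drop) {
  single <- inherits(trees, "phylo")
  trees <- as_multiphylo(trees)
  drop <- normalize_labels(drop)
  taxa <- trees[[1]]$tip.label
  if (!all(drop %in% taxa)) {
    stop("taxa not in trees: ", paste(setdiff(drop, taxa), collapse = ", "))
  }
  if (length(taxa) - length(drop) < 3) stop("cannot prune below 3 taxa")
  out <- lapply(trees, function(tr) {
    has_age <- !is.null(tr$root.age)
    if (has_age) av <- node_ages(tr)
    tr2 <- if (length(drop)) ape::drop.tip(tr, drop) else tr
    if (has_age && !is.null(tr2)) {
      ## drop.tip preserves remaining edge lengths; re-anchor the root age
      ## at the oldest remaining node via any remaining tip
      keep1 <- tr2$tip.label[1]
      old_age <- av[match(keep1, tr$tip.label)]
      depth2 <- ape::node.depth.edgelength(tr2)
      tr2$root.age <- old_age + depth2[match(keep1, tr2$tip.label)]
    }
    tr2
  })
  if (single) return(out[[1]])
  class(out) <- "multiPhylo"
  out
}
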