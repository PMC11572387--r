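## ---- phylo -> pruning layout ----------------------------------------------

## Combined 0-based node indexing for the C++ kernels: tips 0..n-1 in
## tree$tip.label order, internal phylo node i -> i-1. Returns internal
## nodes in postorder plus a CSR children table and per-node branch lengths.
csr_from_phylo <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  n_nodes <- max(edge)
  kids <- split(edge[, 2], factor(edge[, 1], levels = seq_len(n_nodes)))
  root <- n + 1L
  ## iterative DFS for postorder of internal nodes
  stack <- root
  order <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    ch <- kids[[v]]
    stack <- c(stack, ch[ch > n])
  }
  internal_post <- rev(order)
  child_list <- kids[internal_post]
  child_vec <- unlist(child_list, use.names = FALSE)
  child_off <- c(0L, cumsum(lengths(child_list)))
  brlen <- numeric(n_nodes)
  if (!is.null(tree$edge.length)) brlen[edge[, 2]] <- tree$edge.length
  list(internal_post = as.integer(internal_post - 1L),
       child_vec = as.integer(child_vec - 1L),
       child_off = as.integer(child_off),
       brlen = brlen, n_tip = n, n_nodes = n_nodes)
}

## ---- character bounds ------------------------------------------------------

#' Per-character minimum conceivable steps
#'
#' The minimum number of steps a character can require on any tree: one less
#' than the smallest number of states that can cover every cell's state set
#' (uncertainty sets may realize any listed state at no cost).
#'
#' @param matrix a \code{char_matrix}.
#' @return integer vector, one entry per character.
#' @export
char_min_steps <- function(matrix) {
  vapply(seq_len(matrix$n_char), function(j) {
    ns <- matrix$n_states[j]
    cells <- matrix$masks[, j]
    full <- bitwShiftL(1L, ns) - 1L
    cells <- cells[cells != full]      # missing cells never constrain
    if (!length(cells)) return(0L)
    ## smallest state set intersecting every cell (alphabet <= 10 so
    ## exhaustive subset scan is cheap)
    subsets <- 1:full
    subsets <- subsets[order(popcount(subsets))]
    for (S in subsets) {
      if (all(bitwAnd(cells, S) != 0L)) return(popcount(S) - 1L)
    }
    ns - 1L
  }, 1L)
}

#' Per-character maximum steps (length on the worst tree)
#'
#' For unordered characters this is attained on the star tree: the number of
#' scored cells minus the count of cells compatible with the most frequent
#' state (a polymorphic cell counts towards its most frequent compatible
#' state; missing cells are always compatible and so contribute nothing).
#'
#' @param matrix a \code{char_matrix}.
#' @return integer vector, one entry per character.
#' @export
char_max_steps <- function(matrix) {
  vapply(seq_len(matrix$n_char), function(j) {
    ns <- matrix$n_states[j]
    cells <- matrix$masks[, j]
    counts <- vapply(0:(ns - 1L), function(s) {
      sum(bitwAnd(cells, bitwShiftL(1L, s)) != 0L)
    }, 1L)
    length(cells) - max(counts)
  }, 1L)
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

## ---- tree length and ensemble indices --------------------------------------

#' Parsimony score of a tree
#'
#' Computes the unordered (Fitch-type) parsimony length of a rooted or
#' unrooted tree, polytomies allowed, with missing and polymorphic cells
#' treated as uncertainty sets, plus the ensemble consistency and retention
#' indices and (optionally) the implied-weights fit.
#'
#' @param tree a \code{phylo}; tips must occur in \code{matrix}.
#' @param matrix a \code{char_matrix}.
#' @param k optional concavity constant; if given, per-character fits
#'   \code{k/(k+h)} and their sum are included.
#' @return object of class \code{parsimony_score}: list with \code{total},
#'   \code{steps}, \code{min_steps}, \code{max_steps}, \code{homoplasy},
#'   \code{ci}, \code{ri}, and when \code{k} is given \code{fit},
#'   \code{fit_per_char}, \code{k}.
#' @export
tree_length <- function(tree, matrix, k = NULL) {
  sub <- subset_matrix(matrix, tree$tip.label)
  csr <- csr_from_phylo(tree)
  res <- sankoff_unit_cpp(sub$masks, sub$n_states, csr$internal_post,
                          csr$child_vec, csr$child_off, FALSE)
  steps <- res$steps
  m <- char_min_steps(sub)
  g <- char_max_steps(sub)
  h <- steps - m
  out <- list(total = sum(steps), steps = steps, min_steps = m,
              max_steps = g, homoplasy = h,
              ci = sum(m) / sum(steps),
              ri = (sum(g) - sum(steps)) / (sum(g) - sum(m)))
  if (!is.null(k)) {
    out$k <- k
    out$fit_per_char <- k / (k + h)
    out$fit <- sum(out$fit_per_char)
  }
  class(out) <- "parsimony_score"
  out
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("parsimony score: %d steps, CI %.3f, RI %.3f", x$total,
              x$ci, x$ri))
  if (!is.null(x$fit)) cat(sprintf(", fit %.4f (k = %g)", x$fit, x$k))
  cat("\n")
  invisible(x)
}

#' Implied-weights fit of a parsimony score
#'
#' The Goloboff fit \eqn{\sum_i k/(k + h_i)} with \eqn{h_i} the per-character
#' homoplasy; implied-weights search maximizes this quantity.
#'
#' @param score a \code{parsimony_score}.
#' @param k concavity constant, > 0.
#' @return total fit (numeric scalar).
#' @export
implied_fit <- function(score, k) {
  stopifnot(k > 0)
  sum(k / (k + score$homoplasy))
}

## ---- parent-vector trees for search ----------------------------------------

## tips 1..n (fixed = matrix taxon order), internals n+1..2n-1, parent of
## root = 0, detached nodes = NA.

pt_other_child <- function(parent, p, v) {
  ch <- which(!is.na(parent) & parent == p)
  ch[ch != v][1L]
}

ptree_to_phylo <- function(parent, taxa) {
  n_tip <- length(taxa)
  act <- which(!is.na(parent))
  ints <- act[act > n_tip]
  root <- act[parent[act] == 0]
  ## ape numbering: tips 1..n, root n+1, other internals following
  remap <- integer(length(parent))
  remap[seq_len(n_tip)] <- seq_len(n_tip)
  remap[root] <- n_tip + 1L
  rest <- ints[ints != root]
  remap[rest] <- n_tip + 1L + seq_along(rest)
  children <- act[parent[act] != 0]
  edge <- cbind(remap[parent[children]], remap[children])
  tr <- list(edge = edge, tip.label = taxa, Nnode = length(ints))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

phylo_to_ptree <- function(tree, taxa) {
  n_tip <- length(taxa)
  stopifnot(setequal(tree$tip.label, taxa))
  tree <- ape::multi2di(tree)
  idx <- match(tree$tip.label, taxa)
  n_nodes <- max(tree$edge)
  remap <- integer(n_nodes)
  remap[seq_along(idx)] <- idx
  remap[(length(idx) + 1L):n_nodes] <- n_tip + seq_len(n_nodes - length(idx))
  parent <- rep(NA_integer_, 2L * n_tip - 1L)
  parent[remap[tree$edge[, 2]]] <- remap[tree$edge[, 1]]
  parent[remap[length(idx) + 1L]] <- 0L
  parent
}

## compact a partial ptree (NAs = detached) for the C++ scorer
score_ptree <- function(parent, n_tip, masks, n_states, weights, min_steps,
                        implied, k) {
  act <- which(!is.na(parent))
  if (length(act) == length(parent) && !anyNA(parent)) {
    return(ptree_objective_cpp(parent, n_tip, masks, n_states, weights,
                               min_steps, implied, k))
  }
  tips <- act[act <= n_tip]
  ints <- act[act > n_tip]
  id <- integer(length(parent))
  id[tips] <- seq_along(tips)
  id[ints] <- length(tips) + seq_along(ints)
  pc <- integer(length(act))
  pv <- parent[act]
  pv[pv != 0] <- id[pv[pv != 0]]
  pc[id[act]] <- pv
  ptree_objective_cpp(pc, length(tips), masks[tips, , drop = FALSE],
                      n_states, weights, min_steps, implied, k)
}

## ---- heuristic search ------------------------------------------------------

#' Heuristic maximum-parsimony search
#'
#' Random-addition starting trees improved by branch swapping (SPR sweeps,
#' then TBR, until no improvement), under equal weights (minimum length) or
#' implied weights (maximum total fit \code{k/(k+h)}). All distinct optimal
#' trees encountered (up to \code{hold}) are retained after collapsing
#' branches whose minimum length is zero.
#'
#' @param matrix a \code{char_matrix} with >= 4 taxa.
#' @param criterion \code{"ew"} or \code{"iw"}.
#' @param k concavity constant (implied weights only).
#' @param n_starts number of random-addition replicates (>= 1).
#' @param seed integer seed; the search is deterministic given it.
#' @param swap \code{"tbr"} (default), \code{"spr"}, or \code{"none"}.
#' @param hold maximum number of distinct optimal trees to keep.
#' @param weights optional per-character weights (bootstrap resampling).
#' @param ratchet number of reweighting-perturbation rounds per start (a
#'   random quarter of the characters is upweighted, the tree re-swapped,
#'   and the result re-swapped under the original weights; the perturbed
#'   tree is kept only if it improves the objective). 0 disables.
#' @return list of class \code{mp_search}: \code{trees} (multiPhylo of
#'   distinct optimal trees, zero-minimum-length branches collapsed),
#'   \code{best} (first optimal binary tree), \code{score}
#'   (\code{parsimony_score} of \code{best}), \code{objective},
#'   \code{criterion}, \code{k}.
#' @export
parsimony_search <- function(matrix, criterion = c("ew", "iw"), k = 12,
                             n_starts = 10, seed = NULL, swap = "tbr",
                             hold = 50, weights = NULL, ratchet = 4) {
  criterion <- match.arg(criterion)
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (matrix$n_taxa < 4) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- matrix$n_taxa
  masks <- matrix$masks
  n_states <- matrix$n_states
  if (is.null(weights)) weights <- rep(1, matrix$n_char)
  min_steps <- char_min_steps(matrix)
  implied <- criterion == "iw"
  obj_fun <- function(parent) {
    score_ptree(parent, n_tip, masks, n_states, weights, min_steps,
                implied, k)
  }

  best_obj <- Inf
  pool <- list()        # canonical key -> collapsed phylo
  pool_rep <- list()    # canonical key -> binary parent vector
  eps <- 1e-9

  add_to_pool <- function(parent) {
    ph <- ptree_to_phylo(parent, matrix$taxa)
    col <- collapse_min_zero(ph, matrix)
    key <- split_key(col)
    if (is.null(pool[[key]])) {
      pool[[key]] <<- col
      pool_rep[[key]] <<- parent
    }
  }

  for (start in seq_len(n_starts)) {
    parent <- random_addition(matrix, obj_fun)
    res <- branch_swap(parent, n_tip, obj_fun, swap)
    ## ratchet perturbations: swap under jittered weights, then re-swap
    ## under the real objective, keeping improvements
    for (rat in seq_len(ratchet)) {
      w2 <- weights
      up <- sample.int(matrix$n_char, max(1L, matrix$n_char %/% 4L))
      w2[up] <- w2[up] * 3
      obj2 <- function(p) score_ptree(p, n_tip, masks, n_states, w2,
                                      min_steps, implied, k)
      pert <- branch_swap(res$parent, n_tip, obj2, "spr")
      back <- branch_swap(pert$parent, n_tip, obj_fun, swap)
      if (back$obj < res$obj - eps) res <- back
    }
    if (res$obj < best_obj - eps) {
      best_obj <- res$obj
      pool <- list(); pool_rep <- list()
      add_to_pool(res$parent)
    } else if (res$obj < best_obj + eps && length(pool) < hold) {
      add_to_pool(res$parent)
    }
  }

  ## plateau exploration: swap over optimal trees to collect equal-score ones
  queue <- pool_rep
  seen_keys <- names(pool)
  while (length(queue) && length(pool) < hold) {
    parent <- queue[[1L]]
    queue <- queue[-1L]
    nb <- spr_neighbors_at_score(parent, n_tip, obj_fun, best_obj + eps)
    for (cand in nb) {
      if (length(pool) >= hold) break
      ph <- ptree_to_phylo(cand, matrix$taxa)
      col <- collapse_min_zero(ph, matrix)
      key <- split_key(col)
      if (!(key %in% seen_keys)) {
        seen_keys <- c(seen_keys, key)
        pool[[key]] <- col
        pool_rep[[key]] <- cand
        queue[[length(queue) + 1L]] <- cand
      }
    }
  }

  best_parent <- pool_rep[[1L]]
  best_phylo <- ptree_to_phylo(best_parent, matrix$taxa)
  trees <- unname(pool)
  class(trees) <- "multiPhylo"
  score <- tree_length(best_phylo, matrix, k = if (implied) k else NULL)
  structure(list(trees = trees, best = best_phylo, score = score,
                 objective = best_obj, criterion = criterion,
                 k = if (implied) k else NA_real_),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("mp_search (%s%s): %d optimal tree(s), %d steps, CI %.3f, RI %.3f\n",
              toupper(x$criterion),
              if (x$criterion == "iw") sprintf(", k=%g", x$k) else "",
              length(x$trees), x$score$total, x$score$ci, x$score$ri))
  invisible(x)
}

random_addition <- function(matrix, obj_fun) {
  n_tip <- matrix$n_taxa
  ord <- sample.int(n_tip)
  parent <- rep(NA_integer_, 2L * n_tip - 1L)
  r <- n_tip + 1L
  parent[r] <- 0L
  parent[ord[1L]] <- r
  parent[ord[2L]] <- r
  next_int <- n_tip + 2L
  for (i in seq(3L, n_tip)) {
    x <- ord[i]
    m <- next_int
    next_int <- next_int + 1L
    act <- which(!is.na(parent))
    targets <- act[parent[act] != 0]   # every node with a branch above it
    best <- Inf
    best_t <- integer(0)
    ties <- 0L
    for (w in targets) {
      pw <- parent[w]
      parent[m] <- pw; parent[w] <- m; parent[x] <- m
      o <- obj_fun(parent)
      parent[w] <- pw; parent[m] <- NA_integer_; parent[x] <- NA_integer_
      if (o < best - 1e-9) {
        best <- o; best_t <- w; ties <- 1L
      } else if (o < best + 1e-9) {   # uniform seeded tie-break (reservoir)
        ties <- ties + 1L
        if (runif(1) < 1 / ties) best_t <- w
      }
    }
    w <- best_t
    parent[m] <- parent[w]; parent[w] <- m; parent[x] <- m
  }
  parent
}

## detach subtree rooted at v; returns restore closure info
pt_detach <- function(parent, v) {
  p <- parent[v]
  if (parent[p] == 0) {                 # parent is root
    c2 <- pt_other_child(parent, p, v)
    parent[c2] <- 0L
    parent[p] <- NA_integer_
    parent[v] <- NA_integer_
    list(parent = parent, free = p, was_root = TRUE, c2 = c2)
  } else {
    g <- parent[p]
    c2 <- pt_other_child(parent, p, v)
    parent[c2] <- g
    parent[p] <- NA_integer_
    parent[v] <- NA_integer_
    list(parent = parent, free = p, was_root = FALSE, c2 = c2)
  }
}

pt_attach <- function(parent, v, w, m) {
  parent[m] <- parent[w]
  parent[w] <- m
  parent[v] <- m
  parent
}

## enumerate SPR moves. In first-improvement mode (the default during
## descent) the scan runs in random order and returns as soon as a better
## tree is found; with collect_at set, equal-score neighbors are gathered.
spr_sweep <- function(parent, n_tip, obj_fun, cur_obj, collect_at = NULL,
                      first_improvement = TRUE) {
  act <- which(!is.na(parent))
  root <- act[parent[act] == 0]
  prunable <- act[parent[act] != 0]
  if (first_improvement) prunable <- sample(prunable)
  best <- cur_obj
  best_parent <- NULL
  collected <- list()
  for (v in prunable) {
    sub <- subtree_nodes(parent, v)
    if (length(sub) >= length(act) - 2L) next   # nothing left to reattach to
    det <- pt_detach(parent, v)
    p2 <- det$parent
    act2 <- which(!is.na(p2))
    rem <- setdiff(act2, sub)
    root2 <- rem[p2[rem] == 0]
    rkids <- rem[p2[rem] == root2]
    skip1 <- rkids[1L]                # one root-child edge: duplicate unrooted
    targets <- rem[p2[rem] != 0]
    targets <- targets[targets != det$c2 & targets != skip1]
    for (w in targets) {
      cand <- pt_attach(p2, v, w, det$free)
      o <- obj_fun(cand)
      if (!is.null(collect_at) && o < collect_at) {
        collected[[length(collected) + 1L]] <- cand
      }
      if (o < best - 1e-9) {
        best <- o; best_parent <- cand
        if (first_improvement) {
          return(list(obj = best, parent = best_parent,
                      collected = collected))
        }
      }
    }
  }
  list(obj = best, parent = best_parent, collected = collected)
}

subtree_nodes <- function(parent, v) {
  act <- which(!is.na(parent))
  nodes <- v
  repeat {
    more <- act[parent[act] %in% nodes & !(act %in% nodes)]
    if (!length(more)) break
    nodes <- c(nodes, more)
  }
  nodes
}

## TBR: like SPR but the pruned subtree is also rerooted along each of its
## internal edges before reattachment.
tbr_sweep <- function(parent, n_tip, obj_fun, cur_obj) {
  act <- which(!is.na(parent))
  prunable <- act[parent[act] != 0]
  best <- cur_obj
  best_parent <- NULL
  act <- which(!is.na(parent))
  for (v in sample(prunable)) {
    sub <- subtree_nodes(parent, v)
    if (length(sub) >= length(act) - 2L) next
    det <- pt_detach(parent, v)
    p2 <- det$parent
    act2 <- which(!is.na(p2))
    rem <- setdiff(act2, sub)
    root2 <- rem[p2[rem] == 0]
    rkids <- rem[p2[rem] == root2]
    skip1 <- rkids[1L]
    targets <- rem[p2[rem] != 0]
    targets <- targets[targets != det$c2 & targets != skip1]
    ## rerootings of the pruned subtree (identity + each non-root-child edge)
    reroots <- list(p2)
    if (length(sub) > 3L) {
      cand_edges <- sub[sub != v]
      cand_edges <- cand_edges[!is.na(p2[cand_edges]) & p2[cand_edges] != v]
      for (x in cand_edges) {
        rr <- tbr_reroot(p2, v, x)
        if (!is.null(rr)) reroots[[length(reroots) + 1L]] <- rr
      }
    }
    for (p3 in reroots) {
      for (w in targets) {
        cand <- pt_attach(p3, v, w, det$free)
        o <- obj_fun(cand)
        if (o < best - 1e-9) {   # first improvement: return immediately
          return(list(obj = o, parent = cand))
        }
      }
    }
  }
  list(obj = best, parent = best_parent)
}

## reroot the (detached) subtree rooted at v so that the new subtree root
## lies on the edge above x; returns modified parent vector or NULL
tbr_reroot <- function(parent, v, x) {
  px <- parent[x]
  if (is.na(px) || px == v) return(NULL)
  ## walk path x -> v, reversing parent pointers above x
  path <- x
  cur <- px
  while (cur != v) { path <- c(path, cur); cur <- parent[cur] }
  ## v's child on the path is the last element; v's other child:
  top <- path[length(path)]
  d <- pt_other_child(parent, v, top)
  ## reverse parent pointers along the path, suppress v (d hangs under top),
  ## then root the subtree at v on the edge (x, old parent of x)
  for (i in seq(length(path), 2L)) parent[path[i]] <- path[i - 1L]
  parent[d] <- top
  parent[x] <- v
  parent[path[2L]] <- v
  parent[v] <- NA_integer_
  parent
}

branch_swap <- function(parent, n_tip, obj_fun, swap) {
  obj <- obj_fun(parent)
  if (swap == "none") return(list(obj = obj, parent = parent))
  repeat {
    res <- spr_sweep(parent, n_tip, obj_fun, obj)
    if (is.null(res$parent)) break
    parent <- res$parent; obj <- res$obj
  }
  if (swap == "tbr") {
    repeat {
      res <- tbr_sweep(parent, n_tip, obj_fun, obj)
      if (is.null(res$parent)) break
      parent <- res$parent; obj <- res$obj
      ## retry SPR after a TBR improvement
      repeat {
        r2 <- spr_sweep(parent, n_tip, obj_fun, obj)
        if (is.null(r2$parent)) break
        parent <- r2$parent; obj <- r2$obj
      }
    }
  }
  list(obj = obj, parent = parent)
}

spr_neighbors_at_score <- function(parent, n_tip, obj_fun, thresh) {
  res <- spr_sweep(parent, n_tip, obj_fun, Inf, collect_at = thresh,
                   first_improvement = FALSE)
  res$collected
}

## ---- canonical splits, collapsing ------------------------------------------

## unrooted splits of a phylo as canonical strings (side not containing the
## first taxon of `taxa`, sorted); non-trivial splits only
tree_splits <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  n <- length(tree$tip.label)
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  out <- character(0)
  for (p in bp) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (taxa[1L] %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

split_key <- function(tree) {
  paste(sort(tree_splits(tree, sort(tree$tip.label))), collapse = ";")
}

## collapse branches whose minimum number of changes is zero (parent and
## child MPR sets intersect for every character)
collapse_min_zero <- function(tree, matrix) {
  sub <- subset_matrix(matrix, tree$tip.label)
  csr <- csr_from_phylo(tree)
  res <- sankoff_unit_cpp(sub$masks, sub$n_states, csr$internal_post,
                          csr$child_vec, csr$child_off, TRUE)
  mpr <- res$mpr
  n <- length(tree$tip.label)
  edge <- tree$edge
  internal_child <- edge[, 2] > n
  min_len <- vapply(which(internal_child), function(i) {
    u <- edge[i, 1]; v <- edge[i, 2]
    sum(bitwAnd(mpr[u, ], mpr[v, ]) == 0L)
  }, 1)
  el <- rep(1, nrow(edge))
  el[which(internal_child)] <- min_len
  tree$edge.length <- el
  col <- ape::di2multi(tree, tol = 1e-8)
  col$edge.length <- NULL
  col
}

## ---- bootstrap -------------------------------------------------------------

#' Bootstrap support for splits
#'
#' Resamples characters with replacement \code{B} times, reruns the search on
#' each pseudoreplicate, and reports for every split the percentage of
#' replicate best trees that contain it.
#'
#' @param matrix a \code{char_matrix}.
#' @param B number of replicates (>= 1).
#' @param criterion \code{"ew"} or \code{"iw"}.
#' @param k concavity (implied weights).
#' @param seed integer seed.
#' @param n_starts addition-sequence replicates per bootstrap replicate.
#' @param swap branch swapping used within replicates.
#' @return data.frame with columns \code{split} (canonical taxon-set string)
#'   and \code{support} (percent), sorted by support.
#' @export
bootstrap_support <- function(matrix, B = 100, criterion = "ew", k = 12,
                              seed = NULL, n_starts = 1, swap = "spr",
                              ratchet = 0) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(matrix$n_char, replace = TRUE), matrix$n_char)
    res <- parsimony_search(matrix, criterion, k = k, n_starts = n_starts,
                            swap = swap, hold = 1, weights = w,
                            ratchet = ratchet)
    for (s in tree_splits(res$best, sort(matrix$taxa))) {
      counts[[s]] <- (if (is.null(counts[[s]])) 0 else counts[[s]]) + 1
    }
  }
  splits <- ls(counts)
  sup <- vapply(splits, function(s) 100 * counts[[s]] / B, 1)
  out <- data.frame(split = splits, support = unname(sup),
                    stringsAsFactors = FALSE)
  out[order(-out$support), , drop = FALSE]
}
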