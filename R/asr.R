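## Ancestral-state reconstruction: parsimony (MPR) mapping on a consensus
## tree and stochastic character mapping on a dated tree with per-character
## rate-model selection (ER / SYM / ARD) by AIC.

#' Parsimony mapping of character changes
#'
#' Computes exact MPR (most-parsimonious-reconstruction) state sets for
#' every node of a (possibly multifurcating) tree and reads off per-branch
#' changes: a branch carries a change when the parent and child MPR sets are
#' disjoint; the change is flagged ambiguous when either endpoint set has
#' more than one state (as happens with polymorphic codings).
#'
#' @param tree a \code{phylo}; tips in \code{matrix}.
#' @param matrix a \code{char_matrix}.
#' @param characters character indices (default all).
#' @return object of class \code{parsimony_map}: list with \code{changes}
#'   (data.frame: character, node = child node of the branch, from, to
#'   (comma-collapsed state sets), ambiguous), \code{mpr} (list per
#'   character of per-node state sets), \code{steps} (per-character length),
#'   \code{tree}.
#' @export
parsimony_map <- function(tree, matrix, characters = NULL) {
  sub <- subset_matrix(matrix, tree$tip.label)
  if (is.null(characters)) characters <- seq_len(sub$n_char)
  csr <- csr_from_phylo(tree)
  res <- sankoff_unit_cpp(sub$masks, sub$n_states, csr$internal_post,
                          csr$child_vec, csr$child_off, TRUE)
  mpr <- res$mpr       # node x char bitmasks (rows align with phylo ids)
  n <- length(tree$tip.label)
  edge <- tree$edge
  rows <- list()
  for (j in characters) {
    pm <- mpr[edge[, 1], j]
    cm <- mpr[edge[, 2], j]
    chg <- which(bitwAnd(pm, cm) == 0L)
    for (e in chg) {
      from <- mask_to_states(pm[e]); to <- mask_to_states(cm[e])
      rows[[length(rows) + 1L]] <- data.frame(
        character = j, node = edge[e, 2],
        from = paste(from, collapse = ","),
        to = paste(to, collapse = ","),
        ambiguous = length(from) > 1L || length(to) > 1L)
    }
  }
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = integer(0), node = integer(0),
               from = character(0), to = character(0),
               ambiguous = logical(0))
  structure(list(changes = changes,
                 mpr = lapply(characters, function(j)
                   apply(mpr[, j, drop = FALSE], 1, mask_to_states)),
                 steps = res$steps[characters], characters = characters,
                 tree = tree),
            class = "parsimony_map")
}

## tip state priors for phytools: rows taxa, cols states 0..k-1, equal
## weight on the allowed set
tip_prior_matrix <- function(matrix, char) {
  k <- max(2L, matrix$n_states[char])
  out <- t(vapply(seq_len(matrix$n_taxa), function(t) {
    m <- matrix$masks[t, char]
    v <- as.numeric(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    v / sum(v)
  }, numeric(k)))
  rownames(out) <- matrix$taxa
  colnames(out) <- as.character(0:(k - 1L))
  out
}

#' Fit an Mk rate-model variant to one character on a dated tree
#'
#' Maximum-likelihood fit of the k-state generator under equal ("ER"),
#' symmetric ("SYM") or all-rates-different ("ARD") constraints, with
#' AIC = 2p - 2 lnL.
#'
#' @param tree dated \code{phylo} with positive branch durations.
#' @param matrix a \code{char_matrix}.
#' @param char character index.
#' @param model \code{"ER"}, \code{"SYM"} or \code{"ARD"}.
#' @return list with \code{model}, \code{loglik}, \code{aic}, \code{Q},
#'   \code{k}, \code{boundary} (TRUE for invariant characters, fitted rate
#'   ~ 0).
#' @export
fit_mk_variant <- function(tree, matrix, char, model = c("ER", "SYM", "ARD")) {
  model <- match.arg(model)
  if (is.null(tree$edge.length)) stop("a dated tree is required")
  if (any(tree$edge.length < 0)) stop("negative branch durations")
  sub <- subset_matrix(matrix, tree$tip.label)
  k <- max(2L, sub$n_states[char])
  x <- tip_prior_matrix(sub, char)
  observed <- which(colSums(x == 1) > 0)
  n_free <- switch(model, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
                   ARD = k * (k - 1L))
  if (length(observed) <= 1L) {
    ## invariant character: likelihood maximized as rate -> 0
    Q <- matrix(0, k, k, dimnames = list(colnames(x), colnames(x)))
    return(list(model = model, loglik = 0, aic = 2 * n_free, Q = Q, k = k,
                boundary = TRUE))
  }
  tr <- tree
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  fit <- phytools::fitMk(tr, x, model = model)
  ll <- as.numeric(stats::logLik(fit))
  Q <- as.Qmatrix_matrix(fit)
  list(model = model, loglik = ll, aic = 2 * n_free - 2 * ll, Q = Q, k = k,
       boundary = FALSE)
}

as.Qmatrix_matrix <- function(fit) {
  Q <- matrix(0, length(fit$states), length(fit$states),
              dimnames = list(fit$states, fit$states))
  Q[] <- fit$rates[fit$index.matrix]
  Q[is.na(Q)] <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Select the best-fitting Mk variant by AIC
#'
#' @param tree dated \code{phylo}.
#' @param matrix a \code{char_matrix}.
#' @param char character index.
#' @param models candidate models.
#' @return the \code{\link{fit_mk_variant}} result of the AIC-best model,
#'   with \code{aic_table} attached.
#' @export
select_mk_model <- function(tree, matrix, char,
                            models = c("ER", "SYM", "ARD")) {
  fits <- lapply(models, function(m) fit_mk_variant(tree, matrix, char, m))
  aic <- vapply(fits, `[[`, 1, "aic")
  best <- fits[[which.min(aic)]]
  best$aic_table <- data.frame(model = models, aic = aic)
  best
}

#' Stochastic character mapping for one character
#'
#' Samples \code{n_maps} character histories conditional on the tip data
#' under the given fitted model: joint node states are drawn from their
#' conditional distributions (pruning partials combined pre-order), then
#' each branch's path is simulated conditional on its endpoint states, by
#' rejection sampling with a uniformization fallback for stiff branches.
#' Summaries are node posterior state probabilities and per-branch expected
#' change counts.
#'
#' @param tree dated \code{phylo}.
#' @param matrix a \code{char_matrix}.
#' @param char character index.
#' @param fit result of \code{\link{select_mk_model}} /
#'   \code{\link{fit_mk_variant}} (default: AIC-best among ER/SYM/ARD).
#' @param n_maps number of sampled histories.
#' @param seed integer seed.
#' @return list with \code{node_probs} (internal nodes x states),
#'   \code{expected_changes} (per branch, ordered as \code{tree$edge}),
#'   \code{n_changes} (mean total changes), \code{fit}.
#' @export
stochastic_map <- function(tree, matrix, char, fit = NULL, n_maps = 1000,
                           seed = NULL) {
  if (n_maps < 1) stop("n_maps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sub <- subset_matrix(matrix, tree$tip.label)
  if (is.null(fit)) fit <- select_mk_model(tree, sub, char)
  x <- tip_prior_matrix(sub, char)
  n <- length(tree$tip.label)
  states <- colnames(x)
  k <- length(states)
  if (fit$boundary) {
    ## invariant character: all nodes share the observed state
    s <- states[which.max(colSums(x))]
    probs <- matrix(0, tree$Nnode, k, dimnames = list(NULL, states))
    probs[, s] <- 1
    return(list(node_probs = probs,
                expected_changes = numeric(nrow(tree$edge)),
                n_changes = 0, fit = fit))
  }
  Q <- fit$Q
  edge <- tree$edge
  elen <- pmax(tree$edge.length, 1e-6)
  Pmats <- lapply(seq_len(nrow(edge)), function(e)
    ape::matexpo(Q * elen[e]))
  ## pruning partials (conditional likelihood of the subtree below node)
  n_nodes <- n + tree$Nnode
  L <- matrix(1, n_nodes, k)
  L[seq_len(n), ] <- x[tree$tip.label, , drop = FALSE]
  post <- ape::reorder.phylo(tree, "postorder")
  e_post <- match(paste(post$edge[, 1], post$edge[, 2]),
                  paste(edge[, 1], edge[, 2]))
  for (i in seq_len(nrow(post$edge))) {
    e <- e_post[i]
    p <- edge[e, 1]; ch <- edge[e, 2]
    L[p, ] <- L[p, ] * as.vector(Pmats[[e]] %*% L[ch, ])
  }
  root <- n + 1L
  ## preorder edges for joint node-state sampling
  pre <- rev(seq_len(nrow(post$edge)))
  probs <- matrix(0, tree$Nnode, k, dimnames = list(NULL, states))
  exp_changes <- numeric(nrow(edge))
  unif <- uniformization_setup(Q)
  for (s_i in seq_len(n_maps)) {
    node_state <- integer(n_nodes)
    rp <- L[root, ] / k
    node_state[root] <- sample.int(k, 1, prob = rp / sum(rp))
    for (i in pre) {
      e <- e_post[i]
      p <- edge[e, 1]; ch <- edge[e, 2]
      w <- Pmats[[e]][node_state[p], ] * L[ch, ]
      node_state[ch] <- sample.int(k, 1, prob = w / sum(w))
    }
    ints <- (root):(n_nodes)
    idx <- cbind(ints - n, node_state[ints])
    probs[idx] <- probs[idx] + 1
    for (e in seq_len(nrow(edge))) {
      exp_changes[e] <- exp_changes[e] +
        sample_path_changes(node_state[edge[e, 1]], node_state[edge[e, 2]],
                            elen[e], Q, Pmats[[e]], unif)
    }
  }
  probs <- probs / n_maps
  exp_changes <- exp_changes / n_maps
  list(node_probs = probs, expected_changes = exp_changes,
       n_changes = sum(exp_changes), fit = fit)
}

uniformization_setup <- function(Q, max_jumps = 200L) {
  omega <- max(-diag(Q), 1e-12)
  R <- diag(nrow(Q)) + Q / omega
  Rpow <- vector("list", max_jumps + 1L)
  Rpow[[1]] <- diag(nrow(Q))
  for (i in seq_len(max_jumps)) Rpow[[i + 1L]] <- Rpow[[i]] %*% R
  list(omega = omega, R = R, Rpow = Rpow, max_jumps = max_jumps)
}

## number of real state changes on one endpoint-conditioned CTMC path
sample_path_changes <- function(a, b, t, Q, P, unif, max_reject = 50L) {
  ## rejection: forward-simulate until the endpoint matches
  for (try in seq_len(max_reject)) {
    cur <- a; tm <- 0; changes <- 0L
    repeat {
      rate <- -Q[cur, cur]
      if (rate <= 0) break
      tm <- tm + stats::rexp(1, rate)
      if (tm >= t) break
      nxt <- sample.int(nrow(Q), 1, prob = pmax(Q[cur, ], 0))
      if (nxt != cur) changes <- changes + 1L
      cur <- nxt
    }
    if (cur == b) return(changes)
  }
  ## uniformization fallback: sample the number of virtual jumps, then the
  ## jump-chain bridge, counting only real changes
  omega <- unif$omega; R <- unif$Rpow
  pois <- stats::dpois(0:unif$max_jumps, omega * t)
  pab <- vapply(0:unif$max_jumps, function(nn) R[[nn + 1L]][a, b], 1)
  w <- pois * pab
  if (sum(w) <= 0) return(if (a == b) 0L else 1L)
  nj <- sample.int(unif$max_jumps + 1L, 1, prob = w) - 1L
  changes <- 0L
  cur <- a
  if (nj > 0) {
    for (i in seq_len(nj)) {
      wts <- unif$R[cur, ] * vapply(seq_len(nrow(unif$R)), function(cc)
        R[[nj - i + 1L]][cc, b], 1)
      nxt <- sample.int(nrow(unif$R), 1, prob = pmax(wts, 0))
      if (nxt != cur) changes <- changes + 1L
      cur <- nxt
    }
  }
  changes
}

#' Synapomorphies on a clade's stem branch
#'
#' Reads the changes assigned to the branch subtending the most recent
#' common ancestor of \code{clade} from a \code{\link{parsimony_map}} and
#' reports, for each, whether the derived state arises on that branch only
#' (an exclusive synapomorphy).
#'
#' @param map a \code{parsimony_map}.
#' @param clade character vector of tip labels (>= 1).
#' @return data.frame: character, from, to, ambiguous, exclusive. Zero rows
#'   for the root (no stem branch).
#' @export
synapomorphies <- function(map, clade) {
  tree <- map$tree
  missing <- setdiff(clade, tree$tip.label)
  if (length(missing)) stop("unknown tips: ", paste(missing, collapse = ", "))
  n <- length(tree$tip.label)
  node <- if (length(clade) == 1L) match(clade, tree$tip.label) else
    ape::getMRCA(tree, clade)
  if (node == n + 1L) {
    return(data.frame(character = integer(0), from = character(0),
                      to = character(0), ambiguous = logical(0),
                      exclusive = logical(0)))
  }
  ch <- map$changes
  stem <- ch[ch$node == node, , drop = FALSE]
  if (!nrow(stem)) return(cbind(stem, exclusive = logical(0)))
  stem$exclusive <- vapply(seq_len(nrow(stem)), function(i) {
    same <- ch$character == stem$character[i] & ch$to == stem$to[i]
    sum(same) == 1L
  }, TRUE)
  rownames(stem) <- NULL
  stem
}
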