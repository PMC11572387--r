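## Bayesian tip-dating under the FBD tree prior with Mkv+gamma likelihood
## and strict / IGR / TK02 clocks. The sampler state is a parent-vector
## binary tree with node ages plus per-branch latent clock variables:
##   parent: int[2n-1], age: num[2n-1] (Ma),
##   nu:     effective branch length above each node (IGR),
##   logr:   nodal log rate (TK02),
##   scalars c (clock rate), v (clock variance), lambda, mu, psi, alpha.
## Sampled ancestors (strategy "random") are fossil tips whose pendant
## duration is exactly zero.

#' Run the tip-dating MCMC
#'
#' Samples dated trees and model parameters from the posterior given a
#' morphological matrix and tip-age intervals, under the fossilized
#' birth-death tree prior (conditioned on the root age, which carries an
#' offset-exponential prior), uniform tip-age priors, a lognormal clock-rate
#' prior, and exponential hyperpriors on the FBD rates, the clock variance
#' and the gamma shape. Proposals: node-age and tip-age slides, root scaling,
#' dated SPR, clock/FBD scalar multipliers, per-branch rate moves, and (under
#' \code{"random"}) sampled-ancestor collapse/expand jumps.
#'
#' @param matrix a \code{char_matrix}.
#' @param ages a \code{tip_ages} table covering the matrix taxa.
#' @param clock \code{"igr"}, \code{"tk02"} or \code{"strict"}.
#' @param strategy FBD sampling strategy, \code{"fossiltip"} or
#'   \code{"random"}.
#' @param rho extant sampling probability (fixed).
#' @param clock_prior list with \code{mean_log}, \code{sd_log} (see
#'   \code{\link{derive_clock_prior}}).
#' @param root_prior an \code{\link{offset_exp_prior}}.
#' @param ingroup character vector of ingroup taxa to constrain monophyletic
#'   (NULL = unconstrained).
#' @param generations number of MCMC generations.
#' @param sample_every thinning interval.
#' @param burnin_frac fraction of samples discarded as burn-in.
#' @param n_cat gamma categories.
#' @param hyper exponential hyperprior rates, list with elements
#'   \code{lambda}, \code{mu}, \code{psi}, \code{v}, \code{alpha}.
#' @param power likelihood power (stepping-stone); 1 = posterior.
#' @param use_likelihood FALSE samples from the prior.
#' @param tree_prior \code{"fbd"} (default) or \code{"uniform"} (flat over
#'   valid age configurations; a validation mode in which the calibration
#'   priors are not distorted by the tree process).
#' @param seed integer seed (deterministic trace for a fixed seed).
#' @param init optional initial state (as returned by this function's
#'   \code{$final_state}).
#' @return object of class \code{tip_dating}: \code{trees} (thinned
#'   post-burn-in dated trees), \code{params} (data.frame trace),
#'   \code{ess} (per-parameter effective sample sizes, with
#'   \code{low_ess} flagging any below 200), \code{acceptance},
#'   \code{final_state}, \code{config}.
#' @export
run_tip_dating <- function(matrix, ages,
                           clock = c("igr", "tk02", "strict"),
                           strategy = c("fossiltip", "random"),
                           rho = 0.1,
                           clock_prior = list(mean_log = -2.45367,
                                              sd_log = 1.08978),
                           root_prior = offset_exp_prior(33, 41.2),
                           ingroup = NULL,
                           generations = 10000, sample_every = 100,
                           burnin_frac = 0.3, n_cat = 4,
                           hyper = list(lambda = 10, mu = 10, psi = 10,
                                        v = 10, alpha = 1),
                           power = 1, use_likelihood = TRUE,
                           tree_prior = c("fbd", "uniform"),
                           seed = NULL, init = NULL) {
  clock <- match.arg(clock)
  strategy <- match.arg(strategy)
  tree_prior <- match.arg(tree_prior)
  if (!is.null(seed)) set.seed(seed)
  ages <- tip_ages(ages$taxon, ages$min_ma, ages$max_ma, matrix = matrix)
  n <- matrix$n_taxa
  if (n < 4) stop("need at least 4 taxa")
  cfg <- list(
    masks = matrix$masks, n_states = pmax(2L, matrix$n_states),
    taxa = matrix$taxa, n = n,
    lo = ages$min_ma, hi = ages$max_ma,
    clock = clock, strategy = strategy, rho = rho,
    clock_prior = clock_prior, root_prior = root_prior,
    hyper = hyper, n_cat = n_cat, power = power,
    use_lik = use_likelihood, tree_prior = tree_prior,
    ingroup_idx = if (is.null(ingroup)) NULL else {
      idx <- match(normalize_labels(ingroup), matrix$taxa)
      if (anyNA(idx)) stop("ingroup taxa not in matrix")
      sort(idx)
    })
  if (any(cfg$hi < cfg$lo)) stop("empty tip-age interval")

  st <- if (is.null(init)) init_state(cfg) else init
  check_state(st, cfg)

  gamma_rates <- discrete_gamma_rates(st$alpha, n_cat)
  cur_lik <- state_loglik(st, cfg, gamma_rates)
  cur_prior <- state_logprior(st, cfg)
  if (!is.finite(cur_prior)) stop("initial state has zero prior probability")

  moves <- move_table(cfg)
  acc <- att <- setNames(numeric(length(moves)), names(moves))

  n_samp <- floor(generations / sample_every)
  keep_from <- ceiling(burnin_frac * n_samp) + 1L
  trees <- vector("list", n_samp)
  trace <- vector("list", n_samp)

  move_w <- vapply(moves, `[[`, 1, "weight")
  for (gen in seq_len(generations)) {
    mv <- sample.int(length(moves), 1, prob = move_w)
    prop <- moves[[mv]]$fun(st, cfg)
    att[mv] <- att[mv] + 1
    if (!is.null(prop)) {
      new_rates <- if (prop$st$alpha != st$alpha)
        discrete_gamma_rates(prop$st$alpha, n_cat) else gamma_rates
      new_prior <- state_logprior(prop$st, cfg)
      if (is.finite(new_prior)) {
        new_lik <- if (prop$lik_changed || !identical(new_rates, gamma_rates))
          state_loglik(prop$st, cfg, new_rates) else cur_lik
        d <- cfg$power * (new_lik - cur_lik) + (new_prior - cur_prior) +
          prop$log_hastings
        if (is.finite(d) && log(stats::runif(1)) < d) {
          st <- prop$st; cur_lik <- new_lik; cur_prior <- new_prior
          gamma_rates <- new_rates
          acc[mv] <- acc[mv] + 1
        }
      }
    }
    if (gen %% sample_every == 0) {
      i <- gen %/% sample_every
      trees[[i]] <- state_to_phylo(st, cfg)
      trace[[i]] <- data.frame(
        gen = gen, loglik = cur_lik, logprior = cur_prior,
        tree_length = sum(eff_lengths(st, cfg)[-st$root], na.rm = TRUE),
        root_age = st$age[st$root], clock_rate = st$c, clock_var = st$v,
        lambda = st$lambda, mu = st$mu, psi = st$psi, alpha = st$alpha,
        n_sa = n_sampled_ancestors(st, cfg))
    }
  }

  params <- do.call(rbind, trace[keep_from:n_samp])
  kept <- trees[keep_from:n_samp]
  class(kept) <- "multiPhylo"
  ess_cols <- c("loglik", "tree_length", "root_age", "clock_rate",
                "clock_var", "lambda", "mu", "psi", "alpha")
  ess_v <- vapply(ess_cols, function(cn) ess(params[[cn]]), 1)
  structure(list(
    trees = kept, params = params,
    ess = ess_v, low_ess = names(ess_v)[ess_v < 200],
    acceptance = ifelse(att > 0, acc / att, NA),
    final_state = st, config = cfg), class = "tip_dating")
}

#' @export
print.tip_dating <- function(x, ...) {
  cat(sprintf("tip_dating: %d samples, %d taxa\n", length(x$trees),
              x$config$n))
  cat(sprintf("  posterior median root age: %.2f Ma\n",
              stats::median(x$params$root_age)))
  if (length(x$low_ess)) {
    cat("  WARNING: ESS < 200 for:", paste(x$low_ess, collapse = ", "), "\n")
  }
  invisible(x)
}

## ---- state -----------------------------------------------------------------

init_state <- function(cfg) {
  n <- cfg$n
  tip_age <- (cfg$lo + cfg$hi) / 2
  parent <- rep(NA_integer_, 2L * n - 1L)
  age <- numeric(2L * n - 1L)
  age[seq_len(n)] <- tip_age
  next_id <- n + 1L
  join <- function(a, b) {
    id <- next_id; next_id <<- next_id + 1L
    parent[a] <<- id; parent[b] <<- id
    age[id] <<- max(age[a], age[b]) + stats::runif(1, 0.5, 2)
    id
  }
  ingroup <- if (is.null(cfg$ingroup_idx)) seq_len(n) else cfg$ingroup_idx
  rest <- setdiff(seq_len(n), ingroup)
  cluster <- function(ids) {        # sequential joins, youngest first
    while (length(ids) > 1L) {
      ids <- ids[order(age[ids])]
      ids <- c(join(ids[1L], ids[2L]), ids[-(1:2)])
    }
    ids
  }
  top <- cluster(ingroup)
  for (o in rest) top <- join(top, o)
  root <- top
  parent[root] <- 0L
  age[root] <- max(age[root], cfg$root_prior$offset + 0.5)
  st <- list(parent = parent, age = age, root = root,
             c = exp(cfg$clock_prior$mean_log), v = 0.05,
             lambda = 0.15, mu = 0.1, psi = 0.1, alpha = 1)
  dt <- branch_dt(st)
  st$nu <- ifelse(is.na(dt), NA_real_, st$c * pmax(dt, 0))
  st$logr <- rep(log(st$c), length(parent))
  st
}

check_state <- function(st, cfg) {
  dt <- branch_dt(st)
  if (any(dt < -AGE_TOL, na.rm = TRUE)) stop("invalid ages in state")
  tipa <- st$age[seq_len(cfg$n)]
  if (any(tipa < cfg$lo - AGE_TOL | tipa > cfg$hi + AGE_TOL)) {
    stop("tip age outside its interval in initial state")
  }
  if (!is.null(cfg$ingroup_idx) && !is_clade(st, cfg$ingroup_idx)) {
    stop("initial tree violates the ingroup monophyly constraint")
  }
  invisible(TRUE)
}

branch_dt <- function(st) {
  dt <- rep(NA_real_, length(st$parent))
  idx <- which(!is.na(st$parent) & st$parent > 0L)
  dt[idx] <- st$age[st$parent[idx]] - st$age[idx]
  dt
}

n_sampled_ancestors <- function(st, cfg) {
  tipa <- st$age[seq_len(cfg$n)]
  fossil <- which(tipa > AGE_TOL)
  sum(abs(st$age[st$parent[fossil]] - tipa[fossil]) <= AGE_TOL)
}

is_clade <- function(st, tips) {
  n_below <- integer(length(st$parent))
  in_below <- integer(length(st$parent))
  n <- (length(st$parent) + 1L) / 2L
  n_below[seq_len(n)] <- 1L
  in_below[tips] <- 1L
  ord <- order(st$age)                 # children before parents (ages strict
  for (v in ord) {                     # except SA pendants, harmless here)
    p <- st$parent[v]
    if (p > 0L) {
      n_below[p] <- n_below[p] + n_below[v]
      in_below[p] <- in_below[p] + in_below[v]
    }
  }
  any(n_below == length(tips) & in_below == length(tips))
}

## nodal log rates with the root anchored at log(c) (TK02)
logr_full <- function(st) {
  lr <- st$logr
  lr[st$root] <- log(st$c)
  lr
}

eff_lengths <- function(st, cfg) {
  dt <- branch_dt(st)
  switch(cfg$clock,
    strict = st$c * dt,
    igr = st$nu,
    tk02 = {
      lr <- logr_full(st)
      out <- rep(NA_real_, length(dt))
      idx <- which(!is.na(dt))
      out[idx] <- (exp(lr[idx]) + exp(lr[st$parent[idx]])) / 2 * dt[idx]
      out
    })
}

state_loglik <- function(st, cfg, gamma_rates) {
  if (!cfg$use_lik) return(0)
  eff <- eff_lengths(st, cfg)
  eff[st$root] <- 0
  ptree_mk_loglik_cpp(st$parent, cfg$n, cfg$masks, cfg$n_states,
                      eff, gamma_rates, TRUE)
}

state_logprior <- function(st, cfg) {
  n <- cfg$n
  tipa <- st$age[seq_len(n)]
  if (any(tipa < cfg$lo - AGE_TOL | tipa > cfg$hi + AGE_TOL)) return(-Inf)
  dt <- branch_dt(st)
  if (any(dt < -AGE_TOL, na.rm = TRUE)) return(-Inf)
  if (!is.null(cfg$ingroup_idx) && !is_clade(st, cfg$ingroup_idx)) {
    return(-Inf)
  }
  lp <- cfg$root_prior$logpdf(st$age[st$root])
  if (!is.finite(lp)) return(-Inf)
  ## scalar priors
  lp <- lp + stats::dlnorm(st$c, cfg$clock_prior$mean_log,
                           cfg$clock_prior$sd_log, log = TRUE)
  lp <- lp + stats::dexp(st$lambda, cfg$hyper$lambda, log = TRUE) +
    stats::dexp(st$mu, cfg$hyper$mu, log = TRUE) +
    stats::dexp(st$psi, cfg$hyper$psi, log = TRUE) +
    stats::dexp(st$alpha, cfg$hyper$alpha, log = TRUE)
  if (cfg$clock != "strict") {
    lp <- lp + stats::dexp(st$v, cfg$hyper$v, log = TRUE)
  }
  ## FBD tree prior given root age
  if (cfg$tree_prior == "fbd") lp <- lp + fbd_logdens_state(st, cfg)
  if (!is.finite(lp)) return(lp)
  ## latent clock variables
  if (cfg$clock == "igr") {
    b <- which(st$parent > 0L & !is.na(dt))
    pos <- b[dt[b] > AGE_TOL]
    zer <- b[dt[b] <= AGE_TOL]
    if (any(st$nu[zer] > 1e-9)) return(-Inf)
    lp <- lp + sum(stats::dgamma(st$nu[pos],
                                 shape = st$c^2 * dt[pos] / st$v,
                                 rate = st$c / st$v, log = TRUE))
  } else if (cfg$clock == "tk02") {
    lr <- logr_full(st)
    b <- which(st$parent > 0L & !is.na(dt))
    pos <- b[dt[b] > AGE_TOL]
    lp <- lp + sum(stats::dnorm(lr[pos],
                                lr[st$parent[pos]] - st$v * dt[pos] / 2,
                                sqrt(st$v * dt[pos]), log = TRUE))
  }
  lp
}

## FBD density on the parent-vector state (same math as fbd_log_density)
fbd_logdens_state <- function(st, cfg) {
  p <- list(lambda = st$lambda, mu = st$mu, psi = st$psi, rho = cfg$rho,
            strategy = cfg$strategy)
  k <- fbd_consts(p)
  n <- cfg$n
  tipa <- st$age[seq_len(n)]
  extant <- which(tipa <= AGE_TOL)
  fossil <- which(tipa > AGE_TOL)
  sa <- fossil[abs(st$age[st$parent[fossil]] - tipa[fossil]) <= AGE_TOL]
  if (cfg$strategy == "fossiltip" && length(sa)) return(-Inf)
  r <- if (cfg$strategy == "fossiltip") 1 else 0
  terminal <- setdiff(fossil, sa)
  internal <- which(seq_along(st$parent) > n & !is.na(st$parent))
  branching <- setdiff(internal, c(st$root, st$parent[sa]))
  lp <- 2 * fbd_log_q(st$age[st$root], p, k)
  if (length(branching)) {
    if (st$lambda <= 0) return(-Inf)
    lp <- lp + sum(log(st$lambda) + fbd_log_q(st$age[branching], p, k))
  }
  if (length(extant)) lp <- lp + length(extant) * log(cfg$rho)
  if (length(terminal)) {
    if (st$psi <= 0) return(-Inf)
    y <- tipa[terminal]
    surv <- r + (1 - r) * fbd_p0(y, p, k)
    lp <- lp + sum(log(st$psi) + log(surv) - fbd_log_q(y, p, k))
  }
  if (length(sa)) {
    if (st$psi <= 0 || r == 1) return(-Inf)
    lp <- lp + length(sa) * log(st$psi)
  }
  lp
}

state_to_phylo <- function(st, cfg) {
  tr <- ptree_to_phylo(st$parent, cfg$taxa)
  ## map ages from state node ids to ape ids: tips keep order, internals
  ## are matched through the edge structure of ptree_to_phylo (root first)
  n <- cfg$n
  av <- numeric(2L * n - 1L)
  av[seq_len(n)] <- st$age[seq_len(n)]
  ## rebuild internal ages: ptree_to_phylo assigns root = n+1 and the rest
  ## in their original relative order
  act <- which(!is.na(st$parent))
  ints <- act[act > n]
  root <- st$root
  rest <- ints[ints != root]
  av[n + 1L] <- st$age[root]
  av[n + 1L + seq_along(rest)] <- st$age[rest]
  tr$edge.length <- av[tr$edge[, 1]] - av[tr$edge[, 2]]
  tr$edge.length[tr$edge.length < 0] <- 0
  tr$root.age <- st$age[root]
  tr
}

## ---- moves -----------------------------------------------------------------

move_table <- function(cfg) {
  mv <- list(
    node_age = list(weight = 4, fun = move_node_age),
    tip_age = list(weight = 3, fun = move_tip_age),
    root_age = list(weight = 1, fun = move_root_age),
    spr = list(weight = 3, fun = move_spr),
    clock_rate = list(weight = 3, fun = scalar_move("c")),
    lambda = list(weight = 1, fun = scalar_move("lambda")),
    mu = list(weight = 1, fun = scalar_move("mu")),
    psi = list(weight = 1, fun = scalar_move("psi")),
    alpha = list(weight = 1, fun = scalar_move("alpha")))
  if (cfg$clock != "strict") {
    mv$clock_var <- list(weight = 1, fun = scalar_move("v"))
  }
  if (cfg$clock == "igr") {
    mv$nu <- list(weight = 4, fun = move_nu)
  }
  if (cfg$clock == "tk02") {
    mv$logr <- list(weight = 4, fun = move_logr)
  }
  if (cfg$strategy == "random") {
    mv$sa_jump <- list(weight = 2, fun = move_sa_jump)
  }
  mv
}

## nodes whose age is tied to a zero-pendant fossil child (SA attachments)
sa_attach_nodes <- function(st, cfg) {
  tipa <- st$age[seq_len(cfg$n)]
  fossil <- which(tipa > AGE_TOL)
  unique(st$parent[fossil[abs(st$age[st$parent[fossil]] - tipa[fossil]) <=
                            AGE_TOL]])
}

move_node_age <- function(st, cfg) {
  internal <- which(seq_along(st$parent) > cfg$n & !is.na(st$parent) &
                      st$parent > 0L)
  internal <- setdiff(internal, sa_attach_nodes(st, cfg))
  if (!length(internal)) return(NULL)
  v <- internal[sample.int(length(internal), 1)]
  kids <- which(!is.na(st$parent) & st$parent == v)
  lo <- max(st$age[kids]); hi <- st$age[st$parent[v]]
  if (hi - lo <= 0) return(NULL)
  st$age[v] <- stats::runif(1, lo, hi)
  list(st = st, log_hastings = 0, lik_changed = cfg$clock != "igr")
}

move_root_age <- function(st, cfg) {
  kids <- which(!is.na(st$parent) & st$parent == st$root)
  lo <- max(st$age[kids])
  x <- st$age[st$root] - lo
  if (x <= 0) return(NULL)
  u <- stats::runif(1, -0.7, 0.7)
  st$age[st$root] <- lo + x * exp(u)
  list(st = st, log_hastings = u, lik_changed = cfg$clock != "igr")
}

move_tip_age <- function(st, cfg) {
  tipa <- st$age[seq_len(cfg$n)]
  movable <- which(cfg$hi - cfg$lo > 0 & tipa > AGE_TOL)
  if (!length(movable)) return(NULL)
  f <- movable[sample.int(length(movable), 1)]
  p <- st$parent[f]
  if (abs(st$age[p] - st$age[f]) <= AGE_TOL) {
    ## sampled ancestor: move tip and attachment node jointly
    sib <- pt_other_child(st$parent, p, f)
    g <- st$parent[p]
    lo <- max(cfg$lo[f], st$age[sib])
    hi <- min(cfg$hi[f], if (g > 0) st$age[g] else Inf)
    if (hi - lo <= 0) return(NULL)
    a <- stats::runif(1, lo, hi)
    st$age[f] <- a; st$age[p] <- a
    list(st = st, log_hastings = 0, lik_changed = cfg$clock != "igr")
  } else {
    lo <- cfg$lo[f]
    hi <- min(cfg$hi[f], st$age[p])
    if (hi - lo <= 0) return(NULL)
    st$age[f] <- stats::runif(1, lo, hi)
    list(st = st, log_hastings = 0, lik_changed = cfg$clock != "igr")
  }
}

scalar_move <- function(name, eta = 0.8) {
  force(name); force(eta)
  function(st, cfg) {
    u <- stats::runif(1, -eta, eta)
    st[[name]] <- st[[name]] * exp(u)
    ## c rescales branches under strict and anchors the root rate under
    ## tk02; under igr the effective lengths are latent, so prior-only
    lik <- (name == "c" && cfg$clock %in% c("strict", "tk02")) ||
      name == "alpha"
    list(st = st, log_hastings = u, lik_changed = lik)
  }
}

move_nu <- function(st, cfg) {
  dt <- branch_dt(st)
  b <- which(st$parent > 0L & !is.na(dt) & dt > AGE_TOL)
  if (!length(b)) return(NULL)
  v <- b[sample.int(length(b), 1)]
  u <- stats::runif(1, -1, 1)
  st$nu[v] <- st$nu[v] * exp(u)
  list(st = st, log_hastings = u, lik_changed = TRUE)
}

move_logr <- function(st, cfg) {
  act <- setdiff(which(!is.na(st$parent)), st$root)  # root rate == c
  v <- act[sample.int(length(act), 1)]
  st$logr[v] <- st$logr[v] + stats::rnorm(1, 0, 0.3)
  list(st = st, log_hastings = 0, lik_changed = TRUE)
}

## dated subtree-prune-regraft
move_spr <- function(st, cfg) {
  n <- cfg$n
  act <- which(!is.na(st$parent))
  eligible <- act[st$parent[act] > 0L & st$parent[act] != st$root]
  if (!length(eligible)) return(NULL)
  v <- eligible[sample.int(length(eligible), 1)]
  p <- st$parent[v]
  g <- st$parent[p]
  c2 <- pt_other_child(st$parent, p, v)
  ## SA attachments cannot be broken by SPR (handled by sa_jump)
  if (abs(st$age[p] - st$age[v]) <= AGE_TOL && v <= n) return(NULL)
  if (abs(st$age[p] - st$age[c2]) <= AGE_TOL && c2 <= n) return(NULL)
  ## detach: c2 takes p's place under g
  sub <- subtree_nodes_fast(st, v)
  parent2 <- st$parent
  parent2[c2] <- g
  parent2[p] <- NA_integer_
  parent2[v] <- NA_integer_
  av <- st$age[v]
  ## feasible target branches (w, parent(w)) in the remaining tree with
  ## parent age > max(age_v, age_w); also the branch above the remaining
  ## root is not a target (root stays root)
  act2 <- setdiff(which(!is.na(parent2)), sub)
  targets <- act2[parent2[act2] > 0L]
  feas <- targets[st$age[parent2[targets]] > pmax(av, st$age[targets])]
  if (!length(feas)) return(NULL)
  w <- feas[sample.int(length(feas), 1)]
  lo_f <- max(av, st$age[w]); hi_f <- st$age[parent2[w]]
  ## backward window (reattaching above c2 under g)
  lo_b <- max(av, st$age[c2]); hi_b <- st$age[g]
  new_age <- stats::runif(1, lo_f, hi_f)
  parent2[p] <- parent2[w]
  parent2[w] <- p
  parent2[v] <- p
  st$parent <- parent2
  st$age[p] <- new_age
  list(st = st, log_hastings = log(hi_f - lo_f) - log(hi_b - lo_b),
       lik_changed = TRUE)
}

subtree_nodes_fast <- function(st, v) {
  act <- which(!is.na(st$parent))
  nodes <- v
  repeat {
    more <- act[st$parent[act] %in% nodes & !(act %in% nodes)]
    if (!length(more)) break
    nodes <- c(nodes, more)
  }
  nodes
}

## reversible jump between ordinary fossil tip and sampled ancestor
move_sa_jump <- function(st, cfg) {
  n <- cfg$n
  tipa <- st$age[seq_len(n)]
  fossil <- which(tipa > AGE_TOL)
  if (!length(fossil)) return(NULL)
  f <- fossil[sample.int(length(fossil), 1)]
  p <- st$parent[f]
  if (p == st$root) return(NULL)            # no SA at the root
  sib <- pt_other_child(st$parent, p, f)
  g <- st$parent[p]
  lo <- max(st$age[f], st$age[sib])
  hi <- st$age[g]
  if (hi - lo <= 0) return(NULL)
  dt_f <- st$age[p] - st$age[f]
  igr <- cfg$clock == "igr"
  if (dt_f > AGE_TOL) {
    ## collapse to sampled ancestor; only valid if the fossil is the
    ## older child (p's age must reach down to the fossil age).
    ## Backward move (expand) draws the attachment age uniformly on
    ## (lo, hi) and, under IGR, the pendant nu from its prior.
    if (st$age[f] < st$age[sib]) return(NULL)
    lh <- -log(hi - lo)
    if (igr) {
      lh <- lh + stats::dgamma(st$nu[f], shape = st$c^2 * dt_f / st$v,
                               rate = st$c / st$v, log = TRUE)
      st$nu[f] <- 0
    }
    st$age[p] <- st$age[f]
    list(st = st, log_hastings = lh, lik_changed = TRUE)
  } else {
    ## expand: draw a new attachment age above the fossil
    a <- stats::runif(1, lo, hi)
    lh <- log(hi - lo)
    st$age[p] <- a
    if (igr) {
      dt_new <- a - st$age[f]
      nu_new <- stats::rgamma(1, shape = st$c^2 * dt_new / st$v,
                              rate = st$c / st$v)
      if (!is.finite(nu_new) || nu_new <= 0) return(NULL)
      lh <- lh - stats::dgamma(nu_new, shape = st$c^2 * dt_new / st$v,
                               rate = st$c / st$v, log = TRUE)
      st$nu[f] <- nu_new
    }
    list(st = st, log_hastings = lh, lik_changed = TRUE)
  }
}

## ---- diagnostics and summaries ---------------------------------------------

#' Effective sample size of a scalar trace
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence
#' truncation.
#'
#' @param x numeric vector.
#' @return effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 2000), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

#' Shortest (highest-density) posterior interval
#'
#' @param x numeric draws.
#' @param prob coverage probability.
#' @return numeric c(lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Maximum clade credibility tree with age summaries
#'
#' Picks the sampled tree maximizing the product of its clades' posterior
#' frequencies and annotates each clade with its posterior probability,
#' median age across matching clades, and 95% HPD interval.
#'
#' @param trees a \code{multiPhylo} of dated trees (same taxa).
#' @return list with \code{tree} (the MCC tree, node labels = posterior
#'   probabilities), \code{clades} (data.frame: clade, prob, age_median,
#'   age_lo, age_hi).
#' @export
mcc_tree <- function(trees) {
  stopifnot(length(trees) >= 1)
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  freq <- attr(pp, "number") / length(trees)
  key_of <- function(idx) paste(sort(labs[idx]), collapse = ",")
  freq_map <- new.env(parent = emptyenv())
  for (i in seq_along(pp)) assign(key_of(pp[[i]]), freq[i], envir = freq_map)
  clade_keys <- function(tr) {
    cp <- ape::prop.part(tr)
    l2 <- attr(cp, "labels")
    vapply(cp, function(ix) paste(sort(l2[ix]), collapse = ","), "")
  }
  score <- vapply(trees, function(tr)
    sum(log(vapply(clade_keys(tr), function(k) get(k, envir = freq_map), 1))),
    1)
  best <- trees[[which.max(score)]]
  ## per-clade ages across the sample
  age_map <- new.env(parent = emptyenv())
  for (tr in trees) {
    av <- node_ages(tr)
    cp <- ape::prop.part(tr)
    l2 <- attr(cp, "labels")
    for (i in seq_along(cp)) {
      k <- paste(sort(l2[cp[[i]]]), collapse = ",")
      node <- length(tr$tip.label) + i
      prev <- if (exists(k, envir = age_map)) get(k, envir = age_map)
              else numeric(0)
      assign(k, c(prev, av[node]), envir = age_map)
    }
  }
  keys <- clade_keys(best)
  probs <- vapply(keys, function(k) get(k, envir = freq_map), 1)
  ages_list <- lapply(keys, function(k) get(k, envir = age_map))
  med <- vapply(ages_list, stats::median, 1)
  hpds <- t(vapply(ages_list, hpd_interval, numeric(2)))
  best$node.label <- sprintf("%.2f", probs)
  clades <- data.frame(clade = keys, prob = unname(probs),
                       age_median = unname(med),
                       age_lo = hpds[, 1], age_hi = hpds[, 2],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(tree = best, clades = clades)
}
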