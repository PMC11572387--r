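## Forward simulator: FBD time trees with fossil samples, relaxed-clock
## branch lengths, Mk(+gamma) characters, and tip-age uncertainty tables.
## This is the generative counterpart of the inference machinery and is used
## throughout the test suite in place of downloaded data.

#' Simulate a fossilized birth-death tree
#'
#' Forward birth-death simulation from a single lineage at the origin age.
#' Fossils are sampled as a Poisson process with rate \code{psi} along
#' lineages; extant lineages at age 0 are retained with probability
#' \code{rho}. Under \code{"fossiltip"} a fossil sample removes its lineage
#' (fossils are always terminal tips); under \code{"random"} lineages
#' continue after sampling, so fossils with sampled descendants become
#' sampled ancestors (zero-length pendant tips in the returned tree).
#'
#' @param params an \code{\link{fbd_params}}.
#' @param origin age (Ma) at which the process starts.
#' @param min_tips minimum number of samples required (default 3).
#' @param max_try resimulation cap before giving up.
#' @param max_lineages abort a replicate whose radiation exceeds this many
#'   lineages (it is resimulated); bounds worst-case runtime.
#' @return list with \code{tree} (sampled dated \code{phylo} with
#'   \code{root.age}), \code{complete} (all lineage ends, dated),
#'   \code{n_fossils}, \code{n_extant}, \code{total_duration} (sum of
#'   lineage durations of the complete process).
#' @export
simulate_fbd_tree <- function(params, origin, min_tips = 3, max_try = 200,
                              max_lineages = 2000) {
  stopifnot(inherits(params, "fbd_params"), origin > 0)
  for (try in seq_len(max_try)) {
    sim <- fbd_forward_once(params, origin, max_lineages)
    if (is.null(sim)) next
    if (length(sim$tree$tip.label) >= min_tips) return(sim)
  }
  stop("no simulation with >= ", min_tips, " samples in ", max_try, " tries")
}

## one forward pass; returns NULL if nothing sampled
fbd_forward_once <- function(p, origin, max_lineages = 2000) {
  removal <- p$strategy == "fossiltip"
  ## lineage records grown in lists; ages decrease toward the present
  birth <- c(origin); death <- c(NA_real_)
  type <- c(NA_character_)               # end type
  kids <- list(integer(0))
  samples <- list(numeric(0))            # fossil sample ages per lineage
  sampled_extant <- c(FALSE)
  active <- 1L
  total_dur <- 0
  n_lin_cap <- max_lineages
  while (length(active)) {
    i <- active[1L]; active <- active[-1L]
    t <- birth[i]
    repeat {
      tot <- p$lambda + p$mu + p$psi
      wait <- if (tot > 0) stats::rexp(1, tot) else Inf
      if (t - wait <= 0) {               # reached the present
        total_dur <- total_dur + t
        death[i] <- 0; type[i] <- "present"
        sampled_extant[i] <- stats::runif(1) < p$rho
        break
      }
      t2 <- t - wait
      total_dur <- total_dur + wait
      u <- stats::runif(1) * tot
      if (u < p$lambda) {                # speciation
        death[i] <- t2; type[i] <- "speciation"
        for (jj in 1:2) {
          birth <- c(birth, t2); death <- c(death, NA_real_)
          type <- c(type, NA_character_)
          kids[[length(kids) + 1L]] <- integer(0)
          samples[[length(samples) + 1L]] <- numeric(0)
          sampled_extant <- c(sampled_extant, FALSE)
          kids[[i]] <- c(kids[[i]], length(birth))
          active <- c(active, length(birth))
        }
        break
      } else if (u < p$lambda + p$mu) {  # extinction
        death[i] <- t2; type[i] <- "extinction"
        break
      } else {                           # fossil sample
        samples[[i]] <- c(samples[[i]], t2)
        if (removal) {
          death[i] <- t2; type[i] <- "fossil_removal"
          break
        }
        t <- t2
      }
    }
    if (length(birth) > n_lin_cap) return(NULL)   # runaway radiation
  }

  counter <- new.env(parent = emptyenv())
  counter$fossil <- 0L; counter$extant <- 0L
  ## sampled subtree below the top of lineage i: list(newick, age) or NULL
  rec <- function(i) {
    below <- NULL
    if (type[i] == "speciation") {
      ch <- lapply(kids[[i]], rec)
      ch <- ch[!vapply(ch, is.null, TRUE)]
      if (length(ch) == 2L) {
        below <- list(
          str = sprintf("(%s:%.12g,%s:%.12g)",
                        ch[[1]]$str, death[i] - ch[[1]]$age,
                        ch[[2]]$str, death[i] - ch[[2]]$age),
          age = death[i])
      } else if (length(ch) == 1L) below <- ch[[1]]
    } else if (type[i] == "present" && sampled_extant[i]) {
      counter$extant <- counter$extant + 1L
      below <- list(str = sprintf("x%d", counter$extant), age = 0)
    }
    ## fossil samples on this lineage, youngest first
    for (y in sort(samples[[i]])) {
      counter$fossil <- counter$fossil + 1L
      lab <- sprintf("f%d", counter$fossil)
      if (is.null(below)) {
        below <- list(str = lab, age = y)         # terminal fossil
      } else {                                    # sampled ancestor
        below <- list(
          str = sprintf("(%s:%.12g,%s:0)", below$str, y - below$age, lab),
          age = y)
      }
    }
    below
  }
  sampled <- rec(1L)
  if (is.null(sampled)) return(NULL)
  tree <- ape::read.tree(text = paste0(sampled$str, ";"))
  if (is.null(tree) || length(tree$tip.label) < 2) return(NULL)
  tree$root.age <- sampled$age

  ## complete tree over all lineage ends
  ccount <- new.env(parent = emptyenv()); ccount$i <- 0L
  crec <- function(i) {
    if (type[i] == "speciation") {
      ch <- lapply(kids[[i]], crec)
      list(str = sprintf("(%s:%.12g,%s:%.12g)",
                         ch[[1]]$str, death[i] - ch[[1]]$age,
                         ch[[2]]$str, death[i] - ch[[2]]$age),
           age = death[i])
    } else {
      ccount$i <- ccount$i + 1L
      list(str = sprintf("L%d", ccount$i), age = death[i])
    }
  }
  comp <- crec(1L)
  complete <- if (type[1L] == "speciation") {
    ct <- ape::read.tree(text = paste0(comp$str, ";"))
    ct$root.age <- comp$age
    ct
  } else NULL

  list(tree = tree, complete = complete,
       n_fossils = counter$fossil, n_extant = counter$extant,
       total_duration = total_dur)
}

#' Relaxed-clock effective branch lengths for a dated tree
#'
#' Draws per-branch expected numbers of changes per character. Under
#' \code{"strict"} each branch of duration t gets c*t. Under \code{"igr"}
#' effective lengths are independent Gamma draws with mean c*t and variance
#' v*t. Under \code{"tk02"} nodal rates evolve as a mean-preserving
#' lognormal process with log-variance v*t along branches, starting at c at
#' the root, and a branch's rate is the mean of its endpoint rates.
#'
#' @param tree dated \code{phylo}.
#' @param clock list with \code{type} ("strict", "igr", "tk02"), \code{c}
#'   (rate, changes/character/My) and \code{v} (variance parameter).
#' @return numeric vector of effective lengths indexed like
#'   \code{tree$edge} rows.
#' @export
simulate_branch_lengths <- function(tree, clock) {
  t <- tree$edge.length
  type <- clock$type
  if (type == "strict" || isTRUE(clock$v == 0)) return(clock$c * t)
  if (type == "igr") {
    shape <- clock$c^2 * t / clock$v
    out <- stats::rgamma(length(t), shape = shape, rate = clock$c / clock$v)
    return(out)
  }
  if (type == "tk02") {
    n_nodes <- max(tree$edge)
    logr <- numeric(n_nodes)
    root <- length(tree$tip.label) + 1L
    logr[root] <- log(clock$c)
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    for (e in seq_len(nrow(ord))) {
      par <- ord[e, 1]; ch <- ord[e, 2]
      dt <- tree$edge.length[match(ch, tree$edge[, 2])]
      logr[ch] <- stats::rnorm(1, logr[par] - clock$v * dt / 2,
                               sqrt(clock$v * dt))
    }
    rates <- (exp(logr[tree$edge[, 1]]) + exp(logr[tree$edge[, 2]])) / 2
    return(rates * t)
  }
  stop("unknown clock type: ", type)
}

#' Simulate an Mk character matrix on a dated tree
#'
#' Characters evolve under the symmetric Mk model from a uniform root state,
#' with per-character state counts drawn from \code{state_probs}, a
#' per-character gamma rate multiplier of shape \code{alpha}, and effective
#' branch lengths drawn once per matrix from the clock model. When
#' \code{mkv} is TRUE constant characters are discarded and redrawn, so the
#' matrix emulates variable-only coding. Missing and polymorphic masking is
#' applied afterwards (a polymorphic cell is the union of the true state and
#' a random other state).
#'
#' @param tree dated \code{phylo}.
#' @param clock clock model list (see
#'   \code{\link{simulate_branch_lengths}}).
#' @param n_char number of characters.
#' @param state_probs named probability vector over state counts, e.g.
#'   \code{c("2" = .7, "3" = .3)}.
#' @param alpha gamma shape across characters (\code{Inf} = equal rates).
#' @param missing_frac,poly_frac cell masking fractions.
#' @param mkv redraw constant characters.
#' @param max_redraw per-character redraw cap under \code{mkv}.
#' @return a \code{char_matrix}; the effective branch lengths used are
#'   attached as attribute \code{"eff_len"}.
#' @export
simulate_characters <- function(tree, clock, n_char,
                                state_probs = c("2" = 0.75, "3" = 0.2,
                                                "4" = 0.05),
                                alpha = Inf, missing_frac = 0,
                                poly_frac = 0, mkv = TRUE,
                                max_redraw = 500) {
  n <- length(tree$tip.label)
  eff <- simulate_branch_lengths(tree, clock)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  eff_ord <- eff[match(edge[, 2], tree$edge[, 2])]
  root <- n + 1L
  masks <- matrix(0L, n, n_char)
  ks <- as.integer(sample(names(state_probs), n_char, replace = TRUE,
                          prob = state_probs))
  for (j in seq_len(n_char)) {
    k <- ks[j]
    for (redraw in seq_len(max_redraw)) {
      rate <- if (is.finite(alpha)) stats::rgamma(1, alpha, alpha) else 1
      states <- integer(max(edge))
      states[root] <- sample.int(k, 1) - 1L
      for (e in seq_len(nrow(edge))) {
        t_eff <- eff_ord[e] * rate
        psame <- 1 / k + (k - 1) / k * exp(-t_eff * k / (k - 1))
        par_s <- states[edge[e, 1]]
        states[edge[e, 2]] <- if (stats::runif(1) < psame) par_s else
          sample(setdiff(0:(k - 1L), par_s), 1)
      }
      tip_states <- states[seq_len(n)]
      if (!mkv || length(unique(tip_states)) > 1L) break
    }
    masks[, j] <- bitwShiftL(1L, tip_states)
    ## masking
    u <- stats::runif(n)
    miss <- u < missing_frac
    poly <- !miss & u < missing_frac + poly_frac
    if (any(miss)) masks[miss, j] <- bitwShiftL(1L, k) - 1L
    if (any(poly) && k > 1) {
      for (t_i in which(poly)) {
        other <- sample(setdiff(0:(k - 1L), tip_states[t_i]), 1)
        masks[t_i, j] <- bitwOr(masks[t_i, j], bitwShiftL(1L, other))
      }
    }
  }
  out <- char_matrix(tree$tip.label, masks)
  attr(out, "eff_len") <- eff
  out
}

#' Build a tip-age table with uncertainty intervals around true ages
#'
#' Fossil tips get an interval of width drawn uniformly from
#' \code{width_range} positioned uniformly around the true age (clipped at
#' 0), so the true age always lies inside. Extant tips get [0, 0].
#'
#' @param tree dated \code{phylo}.
#' @param width_range interval-width range in My.
#' @return a \code{tip_ages} table; true ages attached as attribute
#'   \code{"true_age"}.
#' @export
make_age_table <- function(tree, width_range = c(0.5, 2)) {
  av <- node_ages(tree)
  n <- length(tree$tip.label)
  tip_age <- av[seq_len(n)]
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    if (tip_age[i] < AGE_TOL) { lo[i] <- hi[i] <- 0; next }
    w <- stats::runif(1, width_range[1], width_range[2])
    off <- stats::runif(1, 0, w)
    lo[i] <- max(0, tip_age[i] - off)
    hi[i] <- lo[i] + w
  }
  out <- tip_ages(tree$tip.label, lo, hi)
  attr(out, "true_age") <- tip_age
  out
}

#' Simulate a complete analysis-ready dataset
#'
#' One call producing a dated FBD tree, an Mk character matrix and a tip-age
#' table, optionally written to NEXUS/CSV/Newick files (byte-identical for a
#' fixed seed).
#'
#' @param params \code{fbd_params}.
#' @param origin origin age (Ma).
#' @param clock clock model list.
#' @param n_char number of characters.
#' @param seed integer seed.
#' @param out_prefix if non-NULL, write \code{<prefix>.nex},
#'   \code{<prefix>_ages.csv}, \code{<prefix>_true.nwk}.
#' @param ... passed to \code{\link{simulate_characters}}.
#' @return list with \code{tree}, \code{matrix}, \code{ages}, \code{truth}
#'   (true parameters and ages).
#' @export
simulate_dataset <- function(params, origin, clock, n_char, seed = NULL,
                             out_prefix = NULL, min_tips = 6,
                             max_try = 200, max_lineages = 2000, ...) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_fbd_tree(params, origin, min_tips = min_tips,
                           max_try = max_try, max_lineages = max_lineages)
  m <- simulate_characters(sim$tree, clock, n_char, ...)
  ages <- make_age_table(sim$tree)
  truth <- list(params = params, clock = clock, origin = origin,
                root_age = sim$tree$root.age,
                true_tip_ages = attr(ages, "true_age"),
                eff_len = attr(m, "eff_len"))
  if (!is.null(out_prefix)) {
    write_nexus_matrix(m, paste0(out_prefix, ".nex"))
    write_tip_ages(ages, paste0(out_prefix, "_ages.csv"))
    ape::write.tree(sim$tree, paste0(out_prefix, "_true.nwk"))
  }
  list(tree = sim$tree, matrix = m, ages = ages, truth = truth)
}
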