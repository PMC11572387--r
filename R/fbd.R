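#' Fossilized birth-death parameters
#'
#' @param lambda speciation rate (events/lineage/My), >= 0.
#' @param mu extinction rate, >= 0.
#' @param psi fossil-sampling rate, >= 0.
#' @param rho extant sampling probability in (0, 1].
#' @param strategy \code{"fossiltip"} (fossils terminate their lineage
#'   representation; no sampled ancestors) or \code{"random"} (sampled
#'   ancestors allowed). The \code{"diversity"} strategy is not supported.
#' @return list of class \code{fbd_params}.
#' @export
fbd_params <- function(lambda, mu, psi, rho,
                       strategy = c("fossiltip", "random")) {
  if (identical(strategy, "diversity")) {
    stop("the 'diversity' sampling strategy is excluded")
  }
  strategy <- match.arg(strategy)
  if (lambda < 0 || mu < 0 || psi < 0) stop("rates must be non-negative")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  structure(list(lambda = lambda, mu = mu, psi = psi, rho = rho,
                 strategy = strategy),
            class = "fbd_params")
}

fbd_consts <- function(p) {
  c1 <- sqrt((p$lambda - p$mu - p$psi)^2 + 4 * p$lambda * p$psi)
  c2 <- if (c1 > 0) -(p$lambda - p$mu - 2 * p$lambda * p$rho - p$psi) / c1
        else 0
  list(c1 = c1, c2 = c2)
}

## log q(t): probability-flow factor for an observed lineage crossing time t;
## q(0) = 1
fbd_log_q <- function(t, p, k = fbd_consts(p)) {
  log(4) - k$c1 * t -
    2 * log((1 - k$c2) * exp(-k$c1 * t) + (1 + k$c2))
}

## p0(t): probability a lineage alive at time t leaves no sample at all
fbd_p0 <- function(t, p, k = fbd_consts(p)) {
  if (k$c1 == 0) return(rep(1 - p$rho, length(t)))
  e <- exp(-k$c1 * t)
  1 + (-(p$lambda - p$mu - p$psi) +
         k$c1 * (e * (1 - k$c2) - (1 + k$c2)) /
               (e * (1 - k$c2) + (1 + k$c2))) / (2 * p$lambda)
}

#' Log density of a dated tree under the fossilized birth-death prior
#'
#' Computes the FBD probability density of a dated tree, conditioned on the
#' root age. Each branching event contributes \eqn{\lambda q(x)}; each
#' extant tip contributes \eqn{\rho}; each terminal fossil tip at age y
#' contributes \eqn{\psi (r + (1-r) p_0(y)) / q(y)}; each sampled ancestor
#' (a fossil attached by a zero-duration pendant) contributes
#' \eqn{\psi (1-r)}, its attachment node not being a branching event. Under
#' \code{"fossiltip"} the lineage-removal probability is r = 1 and sampled
#' ancestors are rejected; under \code{"random"} r = 0.
#'
#' @param tree a dated \code{phylo} (see \code{\link{node_ages}}).
#' @param params an \code{fbd_params}.
#' @return log density (numeric scalar).
#' @export
fbd_log_density <- function(tree, params) {
  stopifnot(inherits(params, "fbd_params"))
  ages <- node_ages(tree)
  n <- length(tree$tip.label)
  k <- fbd_consts(params)
  sa <- sampled_ancestor_tips(tree, ages)
  if (params$strategy == "fossiltip" && length(sa)) {
    stop("sampled ancestors are not allowed under the 'fossiltip' strategy")
  }
  r <- if (params$strategy == "fossiltip") 1 else 0
  extant <- extant_tips(tree, ages)
  fossil <- setdiff(seq_len(n), extant)
  terminal_fossil <- setdiff(fossil, sa)
  root <- n + 1L
  internal <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  sa_nodes <- tree$edge[match(sa, tree$edge[, 2]), 1]
  branching <- setdiff(internal, sa_nodes)

  lp <- 2 * fbd_log_q(ages[root], params, k)  # flow factors of both root edges
  ## branching events (root excluded: we condition on its age)
  if (length(branching)) {
    if (params$lambda == 0) return(-Inf)
    lp <- lp + sum(log(params$lambda) + fbd_log_q(ages[branching], params, k))
  }
  ## q-flow at tips (q(0) = 0 on the log scale for extant tips)
  if (length(extant)) lp <- lp + length(extant) * log(params$rho)
  if (length(terminal_fossil)) {
    if (params$psi == 0) return(-Inf)
    y <- ages[terminal_fossil]
    surv <- r + (1 - r) * fbd_p0(y, params, k)
    lp <- lp + sum(log(params$psi) + log(surv) - fbd_log_q(y, params, k))
  }
  if (length(sa)) {
    if (params$psi == 0 || r == 1) return(-Inf)
    lp <- lp + length(sa) * (log(params$psi) + log1p(-r))
  }
  lp
}
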