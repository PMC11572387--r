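#' Discrete-gamma rate categories
#'
#' Equal-weight discretization of the Gamma(shape = alpha, rate = alpha)
#' distribution into \code{n_cat} categories, each represented by the mean of
#' its quantile slice, so the category rates average exactly 1.
#'
#' @param alpha gamma shape (> 0); \code{Inf} gives a single unit rate.
#' @param n_cat number of categories.
#' @return numeric vector of category rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, n_cat = 4) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(alpha) || n_cat == 1) return(rep(1, 1))
  q <- stats::qgamma(seq(0, 1, length.out = n_cat + 1), shape = alpha,
                     rate = alpha)
  ## mean of a Gamma(a, a) slice: P(a+1)-increments scaled by n_cat
  upper <- stats::pgamma(q[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(q[-(n_cat + 1)], shape = alpha + 1, rate = alpha)
  rates <- n_cat * (upper - lower)
  rates / mean(rates)   # guard against roundoff; mean is already ~1
}

#' Mk / Mkv log-likelihood of a character matrix on a tree
#'
#' Felsenstein pruning under the symmetric k-state Mk model, with the state
#' count taken per character from its observed alphabet, discrete-gamma rate
#' heterogeneity across characters, and optional conditioning on characters
#' being variable (the Mkv ascertainment correction, applied per state-count
#' class). Branch lengths are expected substitutions per character. Missing
#' and polymorphic cells enter as partial likelihoods of 1 on each allowed
#' state.
#'
#' @param tree a \code{phylo} with non-negative branch lengths.
#' @param matrix a \code{char_matrix}; every tree tip must be present.
#' @param alpha gamma shape for rate heterogeneity (\code{Inf} = equal rates).
#' @param n_cat number of gamma categories.
#' @param condition \code{"none"} or \code{"variable"} (Mkv).
#' @return list with \code{total}, \code{per_char}, \code{log_p_variable}.
#' @export
mk_loglik <- function(tree, matrix, alpha = Inf, n_cat = 4,
                      condition = c("none", "variable")) {
  condition <- match.arg(condition)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  sub <- subset_matrix(matrix, tree$tip.label)
  csr <- csr_from_phylo(tree)
  rates <- discrete_gamma_rates(alpha, n_cat)
  k_c <- pmax(2L, sub$n_states)   # single-state alphabets still evolve binary
  res <- mk_loglik_cpp(sub$masks, k_c, csr$internal_post, csr$child_vec,
                       csr$child_off, csr$brlen, rates,
                       condition == "variable")
  list(total = res$total, per_char = res$per_char,
       log_p_variable = res$log_p_variable)
}

#' Probability that a character is variable on a tree
#'
#' The Mkv normalizing constant: one minus the probability that all tips
#' display the same state, for a k-state symmetric Mk character with
#' discrete-gamma rates, on the given tree.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param k state count (>= 2).
#' @param alpha gamma shape.
#' @param n_cat gamma categories.
#' @return probability in [0, 1].
#' @export
p_variable <- function(tree, k, alpha = Inf, n_cat = 4) {
  stopifnot(k >= 2)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  csr <- csr_from_phylo(tree)
  rates <- discrete_gamma_rates(alpha, n_cat)
  p_variable_cpp(as.integer(k), csr$n_tip, csr$internal_post, csr$child_vec,
                 csr$child_off, csr$brlen, rates)
}

#' Maximum-likelihood gamma shape for a fixed tree
#'
#' One-dimensional optimization of \code{\link{mk_loglik}} over the gamma
#' shape parameter.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param matrix a \code{char_matrix}.
#' @param interval search interval for alpha.
#' @param n_cat gamma categories.
#' @param condition as in \code{mk_loglik}.
#' @return list with \code{alpha} and \code{loglik}.
#' @export
mk_fit_alpha <- function(tree, matrix, interval = c(0.02, 50), n_cat = 4,
                         condition = "variable") {
  opt <- stats::optimize(function(a)
    mk_loglik(tree, matrix, alpha = a, n_cat = n_cat,
              condition = condition)$total,
    interval = interval, maximum = TRUE)
  list(alpha = opt$maximum, loglik = opt$objective)
}
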