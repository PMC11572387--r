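#' Stepping-stone power schedule
#'
#' Powers descending from 1 to 0, spaced as quantiles of a Beta(a, 1)
#' distribution (the usual schedule concentrating steps near the prior).
#'
#' @param K number of stones (intervals), >= 2.
#' @param a Beta shape (default 0.3).
#' @return numeric vector of K + 1 powers, descending from 1 to 0.
#' @export
stepping_stone_powers <- function(K, a = 0.3) {
  if (K < 2) stop("need at least 2 power steps")
  (seq(K, 0) / K)^(1 / a)
}

#' Generic stepping-stone estimate of a log marginal likelihood
#'
#' For each pair of adjacent powers, draws are taken from the lower-power
#' posterior and the ratio of normalizing constants is estimated by
#' importance sampling, giving
#' \eqn{\ln \hat m = \sum_k \ln \frac{1}{n}\sum_j e^{(\beta_{k+1}-\beta_k)
#' \ell_j}} with \eqn{\ell_j} log-likelihood draws.
#'
#' @param loglik_sampler function(beta, n) returning n log-likelihood values
#'   of draws from the power-beta posterior.
#' @param powers descending power vector from
#'   \code{\link{stepping_stone_powers}} (must start at 1 and end at 0).
#' @param n_per_step Monte-Carlo draws per stone.
#' @return list with \code{log_ml}, \code{per_step}, \code{powers}.
#' @export
stepping_stone_logml <- function(loglik_sampler, powers, n_per_step = 500) {
  if (is.unsorted(rev(powers)) || powers[1] != 1 ||
      powers[length(powers)] != 0) {
    stop("powers must descend from 1 to 0")
  }
  K <- length(powers) - 1L
  per_step <- numeric(K)
  for (k in seq_len(K)) {
    b_hi <- powers[k]; b_lo <- powers[k + 1]
    ll <- loglik_sampler(b_lo, n_per_step)
    w <- (b_hi - b_lo) * ll
    mx <- max(w)
    per_step[k] <- mx + log(mean(exp(w - mx)))
  }
  list(log_ml = sum(per_step), per_step = per_step, powers = powers)
}

#' Stepping-stone marginal likelihood for a tip-dating model
#'
#' Runs one MCMC per power step (likelihood raised to the power) and feeds
#' the log-likelihood draws to \code{\link{stepping_stone_logml}}.
#'
#' @param matrix,ages,... model arguments passed to
#'   \code{\link{run_tip_dating}}.
#' @param K number of stones.
#' @param generations_per_step MCMC generations per stone.
#' @param sample_every thinning within each stone.
#' @param seed integer seed.
#' @return as \code{\link{stepping_stone_logml}}.
#' @export
stepping_stone_tip_dating <- function(matrix, ages, K = 8,
                                      generations_per_step = 2000,
                                      sample_every = 10, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  powers <- stepping_stone_powers(K)
  state <- NULL
  sampler <- function(beta, n) {
    res <- run_tip_dating(matrix, ages, power = beta,
                          generations = generations_per_step,
                          sample_every = sample_every,
                          burnin_frac = 0.3, init = state, ...)
    state <<- res$final_state
    ll <- res$params$loglik
    if (length(ll) > n) ll <- ll[seq(length(ll) - n + 1L, length(ll))]
    ll
  }
  n_per <- floor(generations_per_step / sample_every * 0.7)
  stepping_stone_logml(sampler, powers, n_per_step = n_per)
}

#' Compare two models by Bayes factor
#'
#' @param log_ml_a,log_ml_b log marginal likelihoods.
#' @return list with \code{two_ln_bf} = 2(log_ml_a - log_ml_b), the verbal
#'   evidence category for the better model (\code{"none"} below 2,
#'   \code{"positive"} 2-6, \code{"substantial"} 6-10, \code{"strong"}
#'   above 10), and \code{better} ("a", "b" or "tie").
#' @export
compare_models <- function(log_ml_a, log_ml_b) {
  bf <- 2 * (log_ml_a - log_ml_b)
  a <- abs(bf)
  category <- if (a > 10) "strong" else if (a > 6) "substantial"
    else if (a > 2) "positive" else "none"
  list(two_ln_bf = bf, category = category,
       better = if (bf > 0) "a" else if (bf < 0) "b" else "tie")
}
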