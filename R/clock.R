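#' Derive the informative clock-rate prior from a non-clock analysis
#'
#' The base clock rate (expected character changes per My) is estimated as
#' the median posterior tree length of a non-clock analysis divided by the
#' median of the root-age prior. The clock-rate prior is then lognormal with
#' mean (on the log scale) equal to the log of that rate and standard
#' deviation equal to the exponential of the rate itself.
#'
#' @param tree_lengths numeric vector of posterior tree lengths (expected
#'   substitutions per character) from a non-clock run, or a single
#'   precomputed median.
#' @param root_prior_median median of the root-age prior in My. The default
#'   37.1 is the operational value used with an offset-exponential root prior
#'   with offset 33 and mean 41.2 (see the methods vignette for why it is
#'   not the analytic median of that distribution).
#' @return list with \code{rate}, \code{mean_log} (= log rate) and
#'   \code{sd_log} (= exp(rate)), parameterizing the lognormal prior.
#' @export
derive_clock_prior <- function(tree_lengths, root_prior_median = 37.1) {
  if (!length(tree_lengths)) stop("empty tree-length sample")
  rate <- stats::median(tree_lengths) / root_prior_median
  list(rate = rate, mean_log = log(rate), sd_log = exp(rate))
}

#' Offset-exponential root-age prior
#'
#' @param offset minimum root age (Ma).
#' @param mean mean of the distribution (Ma), > offset.
#' @return list with \code{offset}, \code{mean}, \code{rate}
#'   (= 1/(mean-offset)), \code{median}, and functions \code{logpdf(x)} and
#'   \code{sample(n)}.
#' @export
offset_exp_prior <- function(offset = 33, mean = 41.2) {
  stopifnot(mean > offset)
  scale <- mean - offset
  list(offset = offset, mean = mean, rate = 1 / scale,
       median = offset + scale * log(2),
       logpdf = function(x) stats::dexp(x - offset, 1 / scale, log = TRUE),
       sample = function(n) offset + stats::rexp(n, 1 / scale))
}
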