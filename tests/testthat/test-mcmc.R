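small_dataset <- function(seed = 3, strategy = "fossiltip", psi = 0.2,
                          n_char = 20, origin = 15, min_tips = 7) {
  p <- fbd_params(0.3, 0.1, psi, rho = 1, strategy = strategy)
  simulate_dataset(p, origin = origin,
                   clock = list(type = "strict", c = 0.1, v = 0),
                   n_char = n_char, alpha = Inf, seed = seed,
                   min_tips = min_tips)
}

test_that("prior-only sampling recovers the calibration priors", {
  d <- small_dataset(seed = 3)
  rp <- offset_exp_prior(max(d$ages$max_ma) + 0.01, max(d$ages$max_ma) + 6)
  res <- run_tip_dating(d$matrix, d$ages, clock = "strict",
                        strategy = "fossiltip", rho = 1,
                        clock_prior = list(mean_log = log(0.1), sd_log = 1),
                        root_prior = rp, generations = 60000,
                        sample_every = 150, use_likelihood = FALSE,
                        tree_prior = "uniform", seed = 2)
  ## fossil tip age ~ Uniform on its interval
  f <- which(d$ages$max_ma - d$ages$min_ma > 0.8)[1]
  lab <- d$ages$taxon[f]
  draws <- vapply(res$trees, function(tr)
    node_ages(tr)[match(lab, tr$tip.label)], 1)
  draws <- draws + stats::runif(length(draws), -1e-9, 1e-9)  # break ties
  expect_gt(stats::ks.test(draws, "punif", d$ages$min_ma[f],
                           d$ages$max_ma[f])$p.value, 0.01)
  ## clock rate ~ lognormal, FBD hyperparameters ~ their exponentials
  expect_gt(stats::ks.test(log(res$params$clock_rate), "pnorm",
                           log(0.1), 1)$p.value, 0.01)
  expect_gt(stats::ks.test(res$params$lambda, "pexp", 10)$p.value, 0.01)
  expect_gt(stats::ks.test(res$params$psi, "pexp", 10)$p.value, 0.01)
})

test_that("the trace is deterministic under a fixed seed", {
  d <- small_dataset(seed = 4)
  rp <- offset_exp_prior(max(d$ages$max_ma) + 0.01, max(d$ages$max_ma) + 6)
  args <- list(d$matrix, d$ages, clock = "igr", strategy = "fossiltip",
               rho = 1, clock_prior = list(mean_log = log(0.1), sd_log = 1),
               root_prior = rp, generations = 1500, sample_every = 50,
               seed = 77)
  r1 <- do.call(run_tip_dating, args)
  r2 <- do.call(run_tip_dating, args)
  expect_identical(r1$params, r2$params)
  expect_identical(ape::write.tree(r1$trees[[1]]),
                   ape::write.tree(r2$trees[[1]]))
})

test_that("posterior trees respect the taxon set, ages and constraints", {
  d <- small_dataset(seed = 5)
  rp <- offset_exp_prior(max(d$ages$max_ma) + 0.01, max(d$ages$max_ma) + 6)
  out <- d$ages$taxon[which.max(d$ages$max_ma)]
  ingroup <- setdiff(d$matrix$taxa, out)
  res <- run_tip_dating(d$matrix, d$ages, clock = "igr",
                        strategy = "fossiltip", rho = 1,
                        clock_prior = list(mean_log = log(0.1), sd_log = 1),
                        root_prior = rp, ingroup = ingroup,
                        generations = 3000, sample_every = 50, seed = 8)
  for (tr in res$trees) {
    expect_setequal(tr$tip.label, d$matrix$taxa)
    validate_time_tree(tr, d$ages)
    ## ingroup stays monophyletic in every sampled tree
    mrca <- ape::getMRCA(tr, ingroup)
    below <- tr$tip.label[unlist(phangorn::Descendants(tr, mrca, "tips"))]
    expect_setequal(below, ingroup)
    ## no sampled ancestors under fossiltip
    expect_length(paleotip:::sampled_ancestor_tips(tr), 0)
  }
  expect_true(all(res$params$n_sa == 0))
})

test_that("sampled ancestors are visited under 'random' with high psi", {
  set.seed(31)
  d <- small_dataset(seed = 31, strategy = "random", psi = 0.6,
                     origin = 10, min_tips = 6)
  rp <- offset_exp_prior(max(d$ages$max_ma) + 0.01, max(d$ages$max_ma) + 5)
  res <- run_tip_dating(d$matrix, d$ages, clock = "strict",
                        strategy = "random", rho = 1,
                        clock_prior = list(mean_log = log(0.1), sd_log = 1),
                        root_prior = rp, generations = 6000,
                        sample_every = 20,
                        hyper = list(lambda = 10, mu = 10, psi = 2,
                                     v = 10, alpha = 1),
                        seed = 13)
  expect_gt(sum(res$params$n_sa), 0)
})

test_that("posterior medians of net diversification and clock rate are unbiased", {
  ## short SBC-style check: across replicates with parameters drawn from
  ## their priors, posterior medians should scatter around the truth with
  ## no systematic sign bias (the full calibration experiment lives with
  ## the coverage checks)
  set.seed(77)
  signs_c <- numeric(0)
  for (r in 1:12) {
    c_true <- stats::rlnorm(1, log(0.08), 0.6)
    p <- fbd_params(0.3, 0.1, 0.2, rho = 1, strategy = "fossiltip")
    d <- simulate_dataset(p, origin = 15,
                          clock = list(type = "strict", c = c_true, v = 0),
                          n_char = 25, alpha = Inf, min_tips = 6)
    rp <- offset_exp_prior(max(d$ages$max_ma) + 0.01,
                           max(d$ages$max_ma) + 6)
    res <- run_tip_dating(d$matrix, d$ages, clock = "strict",
                          strategy = "fossiltip", rho = 1,
                          clock_prior = list(mean_log = log(0.08),
                                             sd_log = 0.6),
                          root_prior = rp, generations = 2000,
                          sample_every = 20, n_cat = 1, seed = r)
    signs_c <- c(signs_c,
                 sign(stats::median(res$params$clock_rate) - c_true))
  }
  ## binomial: 12 fair signs rarely all agree
  expect_gt(sum(signs_c > 0), 0)
  expect_lt(sum(signs_c > 0), 12)
})

test_that("MCC of a single-topology sample returns it with probability 1", {
  trs <- lapply(1:6, function(i) {
    tr <- ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);")
    tr$root.age <- 3 + i / 10     # same topology, varying ages
    tr$edge.length <- tr$edge.length * (1 + i / 20)
    tr
  })
  class(trs) <- "multiPhylo"
  mcc <- mcc_tree(trs)
  expect_equal(phangorn::RF.dist(ape::unroot(mcc$tree),
                                 ape::unroot(trs[[1]])), 0)
  expect_true(all(mcc$clades$prob == 1))
  expect_equal(nrow(mcc$clades), trs[[1]]$Nnode)
  ## node-age summaries are medians over the sample
  root_key <- paste(sort(c("a", "b", "c", "d")), collapse = ",")
  med <- mcc$clades$age_median[mcc$clades$clade == root_key]
  expect_equal(med, stats::median(vapply(trs, function(t)
    node_ages(t)[5], 1)))
})

test_that("hpd_interval is the shortest covering interval", {
  x <- c(stats::rnorm(900), stats::rnorm(100, 10))  # skewed mixture
  h <- hpd_interval(x, 0.9)
  expect_lte(h[2] - h[1],
             diff(stats::quantile(x, c(0.05, 0.95))) + 1e-9)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.9 - 1e-9)
  expect_equal(hpd_interval(c(1, 2), 0.95), c(1, 2))
})

test_that("ess reflects autocorrelation", {
  set.seed(6)
  x <- stats::rnorm(2000)
  expect_gt(ess(x), 1200)
  y <- stats::filter(stats::rnorm(2000), rep(1, 20), sides = 1)
  y <- y[!is.na(y)]
  expect_lt(ess(y), length(y) / 4)
  expect_equal(ess(rep(1, 50)), 50)
})
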