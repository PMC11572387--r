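test_that("psi = 0 yields no fossil tips; full sampling returns all lineages", {
  set.seed(10)
  p0 <- fbd_params(0.4, 0.1, 0, rho = 1)
  sim <- simulate_fbd_tree(p0, origin = 10, min_tips = 4)
  expect_equal(sim$n_fossils, 0)
  av <- node_ages(sim$tree)
  expect_true(all(av[seq_along(sim$tree$tip.label)] < 1e-6))

  ## rho = 1, mu = 0, psi = 0: sampled tree == complete tree
  p1 <- fbd_params(0.35, 0, 0, rho = 1)
  sim1 <- simulate_fbd_tree(p1, origin = 8, min_tips = 4)
  expect_equal(length(sim1$tree$tip.label),
               length(sim1$complete$tip.label))
  expect_equal(sort(ape::branching.times(sim1$tree)),
               sort(ape::branching.times(sim1$complete)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fossil counts follow the Poisson expectation", {
  set.seed(22)
  p <- fbd_params(0.3, 0.15, 0.2, rho = 1)
  n_f <- dur <- numeric(300)
  for (r in seq_len(300)) {
    sim <- paleotip:::fbd_forward_once(p, 6)
    while (is.null(sim)) sim <- paleotip:::fbd_forward_once(p, 6)
    n_f[r] <- sim$n_fossils
    dur[r] <- sim$total_duration
  }
  ## E[fossils] = psi * E[total lineage duration]
  expected <- 0.2 * mean(dur)
  se <- sqrt(stats::var(n_f - 0.2 * dur) / 300)
  expect_lt(abs(mean(n_f) - expected), 3 * se + 1e-9)
})

test_that("sampled ancestors appear under 'random' and never under 'fossiltip'", {
  set.seed(33)
  pr <- fbd_params(0.35, 0.1, 0.6, rho = 1, strategy = "random")
  n_sa <- 0
  for (r in 1:40) {
    sim <- simulate_fbd_tree(pr, origin = 8, min_tips = 4)
    n_sa <- n_sa + length(paleotip:::sampled_ancestor_tips(sim$tree))
  }
  expect_gt(n_sa, 0)
  pf <- fbd_params(0.35, 0.1, 0.6, rho = 1, strategy = "fossiltip")
  for (r in 1:20) {
    sim <- simulate_fbd_tree(pf, origin = 8, min_tips = 4)
    expect_length(paleotip:::sampled_ancestor_tips(sim$tree), 0)
  }
})

test_that("zero branch lengths give constant characters; long branches mix", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  set.seed(4)
  m0 <- simulate_characters(tr, clock = list(type = "strict", c = 1, v = 0),
                            n_char = 50, mkv = FALSE,
                            state_probs = c("2" = 1))
  expect_true(all(m0$masks[1, ] == m0$masks[2, ]))

  tr2 <- ape::read.tree(text = "(a:40,b:40);")
  m1 <- simulate_characters(tr2, clock = list(type = "strict", c = 1, v = 0),
                            n_char = 2000, mkv = FALSE,
                            state_probs = c("2" = 1))
  p_diff <- mean(m1$masks[1, ] != m1$masks[2, ])
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(p_diff - 0.5), 3 * se)
})

test_that("IGR effective lengths approach c*t as v -> 0", {
  set.seed(7)
  tr <- ape::rtree(10)
  t <- tr$edge.length
  eff <- simulate_branch_lengths(tr, clock = list(type = "igr", c = 0.3,
                                                  v = 1e-8))
  expect_lt(max(abs(eff - 0.3 * t) / (0.3 * t)), 1e-2)
  ## and have the right first two moments at moderate v
  effs <- replicate(800, simulate_branch_lengths(
    tr, clock = list(type = "igr", c = 0.3, v = 0.05))[1])
  expect_equal(mean(effs), 0.3 * t[1], tolerance = 0.1)
  expect_equal(stats::var(effs), 0.05 * t[1], tolerance = 0.2)
})

test_that("age tables always contain the true age; extant tips are [0,0]", {
  set.seed(12)
  total <- 0
  while (total < 1000) {
    sim <- simulate_fbd_tree(fbd_params(0.3, 0.1, 0.4, rho = 1),
                             origin = 10, min_tips = 4)
    tab <- make_age_table(sim$tree)
    true_age <- attr(tab, "true_age")
    expect_true(all(tab$min_ma - 1e-9 <= true_age &
                      true_age <= tab$max_ma + 1e-9))
    extant <- true_age < 1e-6
    expect_true(all(tab$min_ma[extant] == 0 & tab$max_ma[extant] == 0))
    total <- total + nrow(tab)
  }
  ## zero-width intervals collapse to the true age
  tab0 <- make_age_table(sim$tree, width_range = c(0, 0))
  expect_equal(tab0$max_ma, unname(attr(tab0, "true_age")), tolerance = 1e-9)
})

test_that("same seed gives byte-identical output files", {
  p <- fbd_params(0.3, 0.1, 0.2, rho = 1)
  cl <- list(type = "igr", c = 0.1, v = 0.02)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_dataset(p, 12, cl, 20, seed = 99, out_prefix = f1,
                   missing_frac = 0.1, poly_frac = 0.05)
  simulate_dataset(p, 12, cl, 20, seed = 99, out_prefix = f2,
                   missing_frac = 0.1, poly_frac = 0.05)
  for (suf in c(".nex", "_ages.csv", "_true.nwk")) {
    expect_identical(readLines(paste0(f1, suf)), readLines(paste0(f2, suf)))
  }
})

test_that("study-sized simulated matrices run through the core stages", {
  set.seed(2024)
  p <- fbd_params(0.35, 0.15, 0.3, rho = 2 / 18, strategy = "fossiltip")
  d <- simulate_dataset(p, origin = 22, clock = list(type = "igr", c = 0.09,
                                                     v = 0.02),
                        n_char = 116, alpha = 1, missing_frac = 0.25,
                        poly_frac = 0.03, min_tips = 20)
  expect_gte(d$matrix$n_taxa, 20)
  expect_equal(d$matrix$n_char, 116L)
  ## parsimony scoring and likelihood evaluate cleanly at this size
  tr <- ape::rtree(d$matrix$n_taxa, tip.label = d$matrix$taxa)
  sc <- tree_length(tr, d$matrix)
  expect_true(sc$total > 0 && sc$ci > 0 && sc$ci <= 1)
  ll <- mk_loglik(tr, d$matrix, alpha = 1, condition = "variable")
  expect_true(is.finite(ll$total))
})
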