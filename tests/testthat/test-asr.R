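test_that("invariant characters map no changes anywhere", {
  m <- matrix_from_rows(c(a = "00", b = "00", c = "00", d = "00"))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  pm <- parsimony_map(tr, m)
  expect_equal(nrow(pm$changes), 0)
  expect_equal(pm$steps, c(0L, 0L))
})

test_that("parsimony mapping matches exhaustive minimum-cost enumeration", {
  set.seed(19)
  for (rep in 1:3) {
    m <- random_matrix(4, 4, n_states = 2:3, p_missing = 0.15, p_poly = 0.1)
    tr <- ape::rtree(4, tip.label = m$taxa)
    tr$edge.length <- NULL
    pm <- parsimony_map(tr, m)
    expect_equal(pm$steps, brute_force_steps(tr, m))
    ## every unambiguous change is real: total changes <= steps, and for
    ## characters whose MPR sets are all singletons, equality holds
    for (j in seq_len(m$n_char)) {
      n_chg <- sum(pm$changes$character == j)
      expect_lte(n_chg, pm$steps[j])
      sets <- pm$mpr[[j]]
      if (all(lengths(sets) == 1)) expect_equal(n_chg, pm$steps[j])
    }
  }
})

test_that("a derived cherry on a ladder maps one unambiguous stem change", {
  ## outgroup-heavy ladder: the root state is resolved to 0, so the single
  ## 0 -> 1 change sits unambiguously on the (a,b) stem
  m <- matrix_from_rows(c(a = "1", b = "1", c = "0", d = "0", e = "0",
                          f = "0"))
  tr <- ape::read.tree(text = "(f,(e,(d,(c,(a,b)))));")
  pm <- parsimony_map(tr, m)
  expect_equal(nrow(pm$changes), 1)
  expect_equal(pm$changes$ambiguous, FALSE)
  expect_equal(pm$changes$from, "0")
  expect_equal(pm$changes$to, "1")
  expect_equal(pm$steps, 1L)
})

test_that("rate-model fits are nested and match a grid-search oracle", {
  set.seed(23)
  tr <- fixed_dated_tree()
  m <- matrix_from_rows(c(a = "01", b = "01", c = "10", d = "11",
                          e = "00", f = "10"))
  fits <- lapply(c("ER", "SYM", "ARD"), function(mod)
    fit_mk_variant(tr, m, 1, mod))
  ll <- vapply(fits, `[[`, 1, "loglik")
  expect_true(ll[3] >= ll[2] - 1e-6 && ll[2] >= ll[1] - 1e-6)
  expect_equal(fits[[1]]$aic, 2 * 1 - 2 * ll[1])
  expect_equal(fits[[3]]$aic, 2 * 2 - 2 * ll[3])  # binary ARD: 2 free rates

  ## ER grid-search oracle via the package's own pruning at fixed rates
  rates <- exp(seq(log(0.005), log(3), length.out = 400))
  grid_ll <- vapply(rates, function(q) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * q
    mk_loglik(tr2, char_matrix(m$taxa, m$masks[, 1, drop = FALSE]),
              n_cat = 1)$total
  }, 1)
  best_grid <- rates[which.max(grid_ll)]
  er_rate <- fits[[1]]$Q["0", "1"]
  expect_equal(er_rate, best_grid, tolerance = 0.02)
  expect_equal(ll[1], max(grid_ll), tolerance = 1e-4)
})

test_that("model selection handles invariant characters at the boundary", {
  m <- matrix_from_rows(c(a = "0", b = "0", c = "0", d = "0", e = "0",
                          f = "0"))
  tr <- fixed_dated_tree()
  sel <- select_mk_model(tr, m, 1)
  expect_equal(sel$model, "ER")
  expect_true(sel$boundary)
  expect_true(all(sel$Q == 0))
})

test_that("stochastic maps recover certainty and exact marginals", {
  tr <- fixed_dated_tree()
  ## invariant character: all node probabilities 1 on the observed state
  m0 <- matrix_from_rows(c(a = "1", b = "1", c = "1", d = "1", e = "1",
                           f = "1"))
  sm0 <- stochastic_map(tr, m0, 1, n_maps = 10, seed = 1)
  expect_true(all(sm0$node_probs[, "1"] == 1))
  expect_equal(sm0$n_changes, 0)

  ## binary character: node probabilities vs exact marginal reconstruction
  m <- matrix_from_rows(c(a = "0", b = "0", c = "1", d = "1", e = "0",
                          f = "1"))
  fit <- fit_mk_variant(tr, m, 1, "ER")
  n_maps <- 1500
  sm <- stochastic_map(tr, m, 1, fit = fit, n_maps = n_maps, seed = 7)
  exact <- ape::ace(setNames(c(0, 0, 1, 1, 0, 1), m$taxa), tr,
                    type = "discrete", model = "ER")
  for (node in seq_len(tr$Nnode)) {
    p_hat <- sm$node_probs[node, "1"]
    p_ex <- exact$lik.anc[node, 2]
    se <- sqrt(max(p_ex * (1 - p_ex), 0.25 / n_maps) / n_maps)
    expect_lt(abs(p_hat - p_ex), 3 * se + 0.02)
  }
  expect_error(stochastic_map(tr, m, 1, n_maps = 0), "n_maps")
})

test_that("stochastic-map probabilities converge across seeds", {
  tr <- fixed_dated_tree()
  m <- matrix_from_rows(c(a = "0", b = "1", c = "1", d = "1", e = "0",
                          f = "2"))
  fit <- select_mk_model(tr, m, 1, models = c("ER", "SYM"))
  s1 <- stochastic_map(tr, m, 1, fit = fit, n_maps = 2000, seed = 11)
  s2 <- stochastic_map(tr, m, 1, fit = fit, n_maps = 2000, seed = 22)
  tv <- max(rowSums(abs(s1$node_probs - s2$node_probs)) / 2)
  expect_lt(tv, 0.05)
})

test_that("synapomorphies report stem changes and exclusivity", {
  ## state 1 arises once on the stem of (a,b); state 2 arises twice
  m <- matrix_from_rows(c(a = "10", b = "10", c = "02", d = "00",
                          e = "02", f = "00"))
  tr <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  pm <- parsimony_map(tr, m)
  syn_ab <- synapomorphies(pm, c("a", "b"))
  expect_true(any(syn_ab$character == 1 & syn_ab$to == "1" &
                    syn_ab$exclusive))
  ## convergent gains of state 2 in c and e are non-exclusive
  syn_c <- synapomorphies(pm, "c")
  row <- syn_c[syn_c$character == 2 & syn_c$to == "2", ]
  expect_equal(nrow(row), 1)
  expect_false(row$exclusive)
  ## the root has no stem branch
  expect_equal(nrow(synapomorphies(pm, tr$tip.label)), 0)
  expect_error(synapomorphies(pm, "zz"), "unknown")
})
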