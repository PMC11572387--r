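## independent enumeration oracle: sum over all internal-node state
## assignments, averaged over gamma categories
enum_loglik <- function(tree, matrix, alpha = Inf, n_cat = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  edge <- tree$edge
  masks <- matrix$masks[tree$tip.label, , drop = FALSE]
  rates <- paleotip::discrete_gamma_rates(alpha, n_cat)
  ptrans <- function(k, t) {
    e <- exp(-t * k / (k - 1))
    m <- matrix(1 / k - e / k, k, k)
    diag(m) <- 1 / k + (k - 1) / k * e
    m
  }
  total <- 0
  for (j in seq_len(matrix$n_char)) {
    k <- max(2L, matrix$n_states[j])
    Lcat <- numeric(length(rates))
    for (g in seq_along(rates)) {
      P <- lapply(seq_len(nrow(edge)), function(e)
        ptrans(k, tree$edge.length[e] * rates[g]))
      grid <- as.matrix(expand.grid(rep(list(1:k), tree$Nnode)))
      L <- 0
      for (r in seq_len(nrow(grid))) {
        assign <- grid[r, ]
        pr <- 1 / k
        for (e in seq_len(nrow(edge))) {
          ps <- assign[edge[e, 1] - n]
          ch <- edge[e, 2]
          if (ch <= n) {
            allowed <- which(bitwAnd(masks[ch, j],
                                     bitwShiftL(1L, 0:(k - 1))) != 0L)
            pr <- pr * sum(P[[e]][ps, allowed])
          } else {
            pr <- pr * P[[e]][ps, assign[ch - n]]
          }
        }
        L <- L + pr
      }
      Lcat[g] <- L
    }
    total <- total + log(mean(Lcat))
  }
  total
}

test_that("two-tip binary character matches the closed form", {
  m <- matrix_from_rows(c(a = "0", b = "1"))
  for (t in c(0.1, 0.7, 3)) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t / 2, t / 2))
    ## P(observe 0,1) = (1/2) * P(diff) = (1/4)(1 - exp(-2t))
    expect_equal(mk_loglik(tr, m, n_cat = 1)$total,
                 log(0.25 * (1 - exp(-2 * t))), tolerance = 1e-10)
  }
  ## stationary independence limit: likelihood -> 1/4
  tr <- ape::read.tree(text = "(a:60,b:60);")
  expect_equal(exp(mk_loglik(tr, m, n_cat = 1)$total), 0.25,
               tolerance = 1e-6)
})

test_that("pruning equals explicit summation over internal states", {
  set.seed(8)
  for (rep in 1:3) {
    m <- random_matrix(4, 5, n_states = 2:3, p_missing = 0.2, p_poly = 0.1)
    tr <- ape::rtree(4, tip.label = m$taxa)
    expect_equal(mk_loglik(tr, m, n_cat = 1)$total, enum_loglik(tr, m),
                 tolerance = 1e-8)
    ## with gamma rate heterogeneity
    expect_equal(mk_loglik(tr, m, alpha = 0.5, n_cat = 4)$total,
                 enum_loglik(tr, m, alpha = 0.5, n_cat = 4),
                 tolerance = 1e-8)
  }
})

test_that("likelihood agrees with phangorn on unambiguous data", {
  set.seed(14)
  m <- random_matrix(7, 40, n_states = 2)
  tr <- ape::unroot(ape::rtree(7, tip.label = m$taxa))
  dat <- t(vapply(m$taxa, function(tx)
    as.character(vapply(seq_len(m$n_char), function(j)
      cell_states(m, tx, j), 1L)), character(m$n_char)))
  pd <- phangorn::phyDat(dat, type = "USER", levels = c("0", "1"))
  fit <- phangorn::pml(tr, pd, rate = 1)
  expect_equal(mk_loglik(tr, m, n_cat = 1)$total, as.numeric(logLik(fit)),
               tolerance = 1e-6)
})

test_that("log-likelihood is invariant under rerooting", {
  set.seed(2)
  m <- random_matrix(6, 10, n_states = 2:3, p_missing = 0.1, p_poly = 0.1)
  tr <- ape::rtree(6, tip.label = m$taxa)
  l0 <- mk_loglik(tr, m, alpha = 1, n_cat = 4, condition = "variable")$total
  rr <- ape::root(ape::unroot(tr), outgroup = "t4", resolve.root = TRUE)
  l1 <- mk_loglik(rr, m, alpha = 1, n_cat = 4, condition = "variable")$total
  expect_equal(l0, l1, tolerance = 1e-8)
})

test_that("shrinking a tip's state set can only lower the likelihood", {
  set.seed(6)
  m <- random_matrix(5, 8, n_states = 3, p_missing = 0)
  tr <- ape::rtree(5, tip.label = m$taxa)
  full <- m
  full$masks[2, ] <- bitwShiftL(1L, full$n_states) - 1L  # tip 2 all-missing
  full <- char_matrix(m$taxa, full$masks)
  l_full <- mk_loglik(tr, full, n_cat = 1)$per_char
  l_obs <- mk_loglik(tr, m, n_cat = 1)$per_char
  expect_true(all(l_obs <= l_full + 1e-12))
})

test_that("errors on invalid inputs", {
  m <- matrix_from_rows(c(a = "0", b = "1"))
  tr <- ape::read.tree(text = "(a:1,b:1);")
  expect_error(mk_loglik(tr, m, alpha = -1), "alpha")
  tr2 <- tr; tr2$edge.length <- c(-1, 1)
  expect_error(mk_loglik(tr2, m), "negative")
  tr3 <- tr; tr3$edge.length <- NULL
  expect_error(mk_loglik(tr3, m), "branch lengths")
})

test_that("P(variable) limits and simulation check", {
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(p_variable(tr0, k = 2), 0)
  tr_inf <- ape::read.tree(text = "(a:80,b:80);")
  expect_equal(p_variable(tr_inf, k = 2), 0.5, tolerance = 1e-6)

  ## 5-taxon fixed tree vs Monte-Carlo constant-pattern frequency
  tr <- ape::read.tree(text = "((a:0.3,b:0.5):0.2,(c:0.4,(d:0.2,e:0.3):0.3):0.1);")
  k <- 2
  set.seed(31)
  nsim <- 4000
  psame <- function(t) 0.5 + 0.5 * exp(-2 * t)
  sim_const <- replicate(nsim, {
    tp <- ape::reorder.phylo(tr, "cladewise")
    states <- integer(max(tp$edge))
    states[6] <- sample(0:1, 1)
    for (e in seq_len(nrow(tp$edge))) {
      p <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
      same <- runif(1) < psame(tp$edge.length[e])
      states[ch] <- if (same) states[p] else 1L - states[p]
    }
    length(unique(states[1:5])) == 1L
  })
  p_const_mc <- mean(sim_const)
  se <- sqrt(p_const_mc * (1 - p_const_mc) / nsim)
  expect_lt(abs((1 - p_variable(tr, k = 2)) - p_const_mc), 3 * se)
})

test_that("Mkv conditioning raises per-character log-likelihoods", {
  set.seed(12)
  m <- random_matrix(6, 10, n_states = 2)
  tr <- ape::rtree(6, tip.label = m$taxa)
  l_raw <- mk_loglik(tr, m, n_cat = 1)$per_char
  cond <- mk_loglik(tr, m, n_cat = 1, condition = "variable")
  expect_true(all(cond$per_char > l_raw))
  expect_true(all(cond$log_p_variable < 0))
})

test_that("gamma discretization has unit mean and ML alpha is recoverable", {
  for (a in c(0.3, 1, 5)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  expect_identical(discrete_gamma_rates(Inf, 4), 1)

  ## simulate 1000 binary characters under alpha = 0.5 on a fixed tree and
  ## re-estimate alpha by ML (variable-only characters, Mkv conditioning)
  set.seed(77)
  tr <- ape::rtree(8)
  tr$edge.length <- tr$edge.length * 2
  psame <- function(t) 0.5 + 0.5 * exp(-2 * t)
  sim_char <- function(rate) {
    tp <- ape::reorder.phylo(tr, "cladewise")
    states <- integer(max(tp$edge))
    states[9] <- sample(0:1, 1)
    for (e in seq_len(nrow(tp$edge))) {
      p <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
      same <- runif(1) < psame(tp$edge.length[e] * rate)
      states[ch] <- if (same) states[p] else 1L - states[p]
    }
    states[1:8]
  }
  cats <- discrete_gamma_rates(0.5, 4)   # simulate from the fitted family
  chars <- list()
  while (length(chars) < 1000) {
    rate <- sample(cats, 1)
    x <- sim_char(rate)
    if (length(unique(x)) > 1) chars[[length(chars) + 1]] <- x
  }
  masks <- do.call(cbind, lapply(chars, function(x) bitwShiftL(1L, x)))
  m <- char_matrix(tr$tip.label, masks)
  fit <- mk_fit_alpha(tr, m, condition = "variable")
  ## shape is weakly identified from binary characters on 8 taxa; the bound
  ## reflects the Monte-Carlo spread observed across simulation seeds
  expect_gt(fit$alpha, 0.25)
  expect_lt(fit$alpha, 0.95)
})
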