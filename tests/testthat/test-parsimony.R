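test_that("a single binary contrast costs one step", {
  m <- matrix_from_rows(c(a = "0", b = "1"))
  tr <- ape::read.tree(text = "(a,b);")
  expect_equal(tree_length(tr, m)$total, 1L)
})

test_that("tree length matches brute-force assignment enumeration", {
  set.seed(42)
  for (rep in 1:6) {
    m <- random_matrix(5, 4, n_states = 2:3,
                       p_missing = 0.15, p_poly = 0.1)
    tr <- ape::rtree(5, tip.label = m$taxa)
    tr$edge.length <- NULL
    expect_equal(tree_length(tr, m)$steps, brute_force_steps(tr, m))
  }
  ## including a tree with a polytomy (Hartigan case)
  m <- random_matrix(6, 5, n_states = 2:3, p_missing = 0.1)
  tr <- ape::read.tree(text = "((t1,t2,t3),(t4,(t5,t6)));")
  expect_equal(tree_length(tr, m)$steps, brute_force_steps(tr, m))
})

test_that("tree length agrees with phangorn on unambiguous binary trees", {
  set.seed(11)
  m <- random_matrix(8, 30, n_states = 2:3)
  tr <- ape::rtree(8, tip.label = m$taxa)
  dat <- lapply(m$taxa, function(t) {
    as.character(vapply(seq_len(m$n_char), function(j)
      cell_states(m, t, j), 1L))
  })
  names(dat) <- m$taxa
  pd <- phangorn::phyDat(do.call(rbind, dat), type = "USER",
                         levels = as.character(0:3))
  expect_equal(tree_length(tr, m)$total,
               phangorn::parsimony(tr, pd, method = "sankoff"))
})

test_that("length is invariant to taxon order and rerooting", {
  set.seed(3)
  m <- random_matrix(7, 12, n_states = 2:4, p_missing = 0.2, p_poly = 0.1)
  tr <- ape::rtree(7, tip.label = m$taxa)
  s0 <- tree_length(tr, m)$total
  perm <- subset_ok <- sample(m$taxa)
  m2 <- char_matrix(perm, m$masks[perm, ])
  expect_equal(tree_length(tr, m2)$total, s0)
  rerooted <- ape::root(tr, outgroup = m$taxa[3], resolve.root = TRUE)
  expect_equal(tree_length(rerooted, m)$total, s0)
})

test_that("character addition and taxon removal move length one way", {
  set.seed(5)
  m <- random_matrix(6, 10, n_states = 2:3, p_missing = 0.1)
  tr <- ape::rtree(6, tip.label = m$taxa)
  s_all <- tree_length(tr, m)$total
  m_sub <- char_matrix(m$taxa, m$masks[, 1:6])
  expect_lte(tree_length(tr, m_sub)$total, s_all)
  tr_drop <- ape::drop.tip(tr, "t3")
  expect_lte(tree_length(tr_drop, m)$total, s_all)
})

test_that("per-character bounds and ensemble indices hold", {
  set.seed(9)
  for (rep in 1:4) {
    m <- random_matrix(8, 15, n_states = 2:4, p_missing = 0.2, p_poly = 0.15)
    tr <- ape::rtree(8, tip.label = m$taxa)
    sc <- tree_length(tr, m, k = 12)
    expect_true(all(sc$min_steps <= sc$steps))
    expect_true(all(sc$steps <= sc$max_steps))
    expect_true(sc$ci > 0 && sc$ci <= 1)
    expect_true(sc$ri >= 0 && sc$ri <= 1)
    expect_true(all(sc$fit_per_char > 0 & sc$fit_per_char <= 1))
  }
})

test_that("implied-weights fit follows k/(k+h)", {
  m <- matrix_from_rows(c(a = "00", b = "00", c = "11", d = "11"))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  sc <- tree_length(tr, m)
  expect_equal(sc$homoplasy, c(0L, 0L))
  expect_equal(implied_fit(sc, 12), m$n_char)  # no homoplasy -> fit = n_char
  ## one character with h = 12 contributes k/(k+h) = 0.5 at k = 12
  sc2 <- sc
  sc2$homoplasy <- c(12L, 0L)
  expect_equal(implied_fit(sc2, 12), 0.5 + 1)
  expect_error(implied_fit(sc, 0))
})

test_that("search recovers the exhaustive-enumeration optimum", {
  set.seed(21)
  for (rep in 1:3) {
    m <- random_matrix(6, 8, n_states = 2:3, p_missing = 0.1, p_poly = 0.05)
    all_tr <- phangorn::allTrees(6, rooted = FALSE, tip.label = m$taxa)
    best_exh <- min(vapply(all_tr, function(t) tree_length(t, m)$total, 1L))
    res <- parsimony_search(m, "ew", n_starts = 3, seed = rep, swap = "tbr")
    expect_equal(res$score$total, best_exh)
  }
})

test_that("IW and EW optima coincide on homoplasy-free data", {
  ## a clean nested matrix: every character fits the same ladder tree
  m <- matrix_from_rows(c(a = "1100", b = "1100", c = "0100",
                          d = "0011", e = "0011", f = "0001"))
  ew <- parsimony_search(m, "ew", n_starts = 4, seed = 1)
  iw <- parsimony_search(m, "iw", k = 12, n_starts = 4, seed = 1)
  expect_equal(ew$score$total, iw$score$total)
  expect_equal(sum(ew$score$homoplasy), 0L)
  expect_equal(phangorn::RF.dist(ape::unroot(ew$best), ape::unroot(iw$best)),
               0)
})

test_that("search under implied weights maximizes total fit", {
  set.seed(33)
  m <- random_matrix(6, 10, n_states = 2, p_missing = 0.1)
  all_tr <- phangorn::allTrees(6, rooted = FALSE, tip.label = m$taxa)
  fits <- vapply(all_tr, function(t) implied_fit(tree_length(t, m), 12), 1)
  res <- parsimony_search(m, "iw", k = 12, n_starts = 3, seed = 2)
  expect_equal(implied_fit(res$score, 12), max(fits), tolerance = 1e-9)
})

test_that("search is deterministic under a fixed seed", {
  set.seed(1)
  m <- random_matrix(7, 12, n_states = 2:3, p_missing = 0.1)
  r1 <- parsimony_search(m, "ew", n_starts = 3, seed = 99)
  r2 <- parsimony_search(m, "ew", n_starts = 3, seed = 99)
  expect_identical(ape::write.tree(r1$best), ape::write.tree(r2$best))
  expect_identical(r1$objective, r2$objective)
})

test_that("bootstrap gives unanimity for a clean split and {0,100} at B=1", {
  m <- matrix_from_rows(c(a = "1111", b = "1111", c = "0000",
                          d = "0000", e = "0000"))
  bs <- bootstrap_support(m, B = 20, seed = 4)
  key <- paste(sort(c("d", "e")), collapse = "|")  # depends on canonical side
  ## the a|b vs rest split is in every replicate tree
  expect_true(any(bs$support == 100))
  clean <- bs$split[bs$support == 100]
  expect_true(any(vapply(strsplit(clean, "\\|"),
                         function(s) setequal(s, c("a", "b")) ||
                           setequal(s, c("c", "d", "e")), TRUE)))
  bs1 <- bootstrap_support(m, B = 1, seed = 5)
  expect_true(all(bs1$support %in% c(0, 100)))
})

test_that("bootstrap supports approach a large-B reference", {
  set.seed(17)
  m <- random_matrix(5, 12, n_states = 2)
  ref <- bootstrap_support(m, B = 600, seed = 100)
  obs <- bootstrap_support(m, B = 200, seed = 200)
  shared <- intersect(ref$split, obs$split)
  shared <- shared[ref$support[match(shared, ref$split)] > 20]
  for (s in shared) {
    p <- ref$support[match(s, ref$split)]
    ## 3 binomial standard errors at B = 200
    se <- 100 * sqrt(p / 100 * (1 - p / 100) / 200)
    expect_lt(abs(obs$support[match(s, obs$split)] - p), 3 * se + 3)
  }
})
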