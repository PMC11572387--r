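## Shared fixtures and independent oracles. Oracles are deliberately naive
## (enumeration / closed form) and never call the code paths they check.

## random character matrix with optional missing / polymorphic cells
random_matrix <- function(n_taxa, n_char, n_states = 2, p_missing = 0,
                          p_poly = 0) {
  taxa <- paste0("t", seq_len(n_taxa))
  masks <- matrix(0L, n_taxa, n_char)
  for (j in seq_len(n_char)) {
    ns <- if (length(n_states) > 1) sample(n_states, 1) else n_states
    full <- bitwShiftL(1L, ns) - 1L
    for (t in seq_len(n_taxa)) {
      u <- runif(1)
      if (u < p_missing) {
        masks[t, j] <- full
      } else if (u < p_missing + p_poly && ns > 1) {
        st <- sample(ns, 2) - 1L
        masks[t, j] <- sum(bitwShiftL(1L, st))
      } else {
        masks[t, j] <- bitwShiftL(1L, sample(ns, 1) - 1L)
      }
    }
    ## ensure at least two singleton states so the alphabet is as intended
    masks[1, j] <- 1L
    masks[2, j] <- bitwShiftL(1L, ns - 1L)
  }
  char_matrix(taxa, masks)
}

## brute-force parsimony: minimize changes over every assignment of single
## states to internal nodes (tip sets resolved optimally per assignment)
brute_force_steps <- function(tree, matrix) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  edge <- tree$edge
  n_int <- tree$Nnode
  masks <- matrix$masks[tree$tip.label, , drop = FALSE]
  vapply(seq_len(matrix$n_char), function(j) {
    ns <- matrix$n_states[j]
    grid <- as.matrix(expand.grid(rep(list(0:(ns - 1L)), n_int)))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      assign <- grid[r, ]
      cost <- 0
      for (e in seq_len(nrow(edge))) {
        p_state <- assign[edge[e, 1] - n]
        ch <- edge[e, 2]
        if (ch <= n) {
          if (!bitwAnd(masks[ch, j], bitwShiftL(1L, p_state))) cost <- cost + 1
        } else {
          if (assign[ch - n] != p_state) cost <- cost + 1
        }
      }
      if (cost < best) best <- cost
    }
    as.integer(best)
  }, 1L)
}

as_multiphylo_safe <- function(x) {
  if (inherits(x, "phylo")) x <- list(x)
  x
}

## a fixed dated 6-taxon tree used by several modules
fixed_dated_tree <- function() {
  txt <- "((a:1,b:2):3,((c:1.5,d:2.5):2,(e:1,f:4):1.5):2.5);"
  ape::read.tree(text = txt)
}

## matrix from rows of state strings, e.g. c(a = "010", b = "0?1")
matrix_from_rows <- function(rows) {
  taxa <- names(rows)
  nch <- nchar(gsub("\\([0-9]+\\)", "P", rows[1]))
  parse_cells <- function(s) {
    out <- integer(0)
    i <- 1
    chs <- strsplit(s, "")[[1]]
    while (i <= length(chs)) {
      if (chs[i] == "(") {
        k <- which(chs[-seq_len(i)] == ")")[1] + i
        st <- as.integer(chs[(i + 1):(k - 1)])
        out <- c(out, sum(bitwShiftL(1L, st)))
        i <- k + 1
      } else if (chs[i] == "?") {
        out <- c(out, -1L)
        i <- i + 1
      } else {
        out <- c(out, bitwShiftL(1L, as.integer(chs[i])))
        i <- i + 1
      }
    }
    out
  }
  raw <- do.call(rbind, lapply(rows, parse_cells))
  for (j in seq_len(ncol(raw))) {
    obs <- raw[raw[, j] > 0, j]
    ns <- 1L
    while (bitwShiftL(1L, ns) <= max(obs)) ns <- ns + 1L
    raw[raw[, j] < 0, j] <- bitwShiftL(1L, ns) - 1L
  }
  char_matrix(taxa, raw)
}
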