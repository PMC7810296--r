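# Independent oracles: brute-force enumeration implementations kept free of
# the package's dynamic programs and search heuristics.

# minimum changes of one character by enumerating every assignment of
# states to internal nodes (and to leaves with missing data)
oracle_char_length <- function(phy, leaf_tokens, states = 0:3) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  leaf <- suppressWarnings(as.integer(leaf_tokens[phy$tip.label]))
  free_leaves <- which(is.na(leaf))
  n_free <- nn + length(free_leaves)
  grid <- as.matrix(expand.grid(rep(list(states), n_free)))
  asg <- matrix(0L, nrow(grid), nt + nn)
  for (i in seq_len(nt)) asg[, i] <- leaf[i]
  if (length(free_leaves)) {
    asg[, free_leaves] <- grid[, nn + seq_along(free_leaves), drop = FALSE]
  }
  asg[, nt + seq_len(nn)] <- grid[, seq_len(nn), drop = FALSE]
  cost <- rep(0L, nrow(grid))
  for (k in seq_len(nrow(phy$edge))) {
    cost <- cost + (asg[, phy$edge[k, 1L]] != asg[, phy$edge[k, 2L]])
  }
  min(cost)
}

oracle_matrix_length <- function(phy, cmat, states = 0:3) {
  sum(vapply(seq_len(cmat$n_char), function(j) {
    oracle_char_length(phy, cmat$cells[, j], states)
  }, 0))
}

# every unrooted topology on the given taxa, as rooted Newick strings
# (rooted at the first taxon), built by sequential edge insertion
oracle_all_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3L)
  paths <- function(S) {
    out <- list(integer(0))
    if (is.list(S)) {
      for (i in 1:2) {
        for (p in paths(S[[i]])) out <- c(out, list(c(i, p)))
      }
    }
    out
  }
  replace_at <- function(S, path, t) {
    if (!length(path)) return(list(S, t))
    S[[path[1L]]] <- replace_at(S[[path[1L]]], path[-1L], t)
    S
  }
  to_newick <- function(S) {
    if (!is.list(S)) return(S)
    paste0("(", to_newick(S[[1L]]), ",", to_newick(S[[2L]]), ")")
  }
  grow <- function(S, rest) {
    if (!length(rest)) return(list(S))
    out <- list()
    for (p in paths(S)) {
      out <- c(out, grow(replace_at(S, p, rest[1L]), rest[-1L]))
    }
    out
  }
  start <- if (length(taxa) == 3L) {
    grow(list(taxa[2L], taxa[3L]), character(0))
  } else {
    grow(list(taxa[2L], taxa[3L]), taxa[-(1:3)])
  }
  vapply(start, function(S) paste0("(", taxa[1L], ",", to_newick(S), ");"),
         "")
}

# exhaustive minimization of the event-model reconstruction cost over all
# internal-node ranges (bitmask subsets of the terminal pixel universe)
oracle_gem_best_cost <- function(phy, terminal_ranges, z = 10L) {
  universe <- sort(unique(unlist(terminal_ranges)))
  np <- length(universe)
  stopifnot(np <= 8L)
  all_masks <- 1:(2^np - 1L)
  pc <- vapply(0:(2^np - 1L), function(m) sum(bitwAnd(m, 2^(0:(np - 1L))) > 0L),
               0L)
  cand <- all_masks[pc[all_masks + 1L] <= z]
  to_mask <- function(px) sum(2^(match(px, universe) - 1L))
  nt <- length(phy$tip.label)
  internals <- sort(unique(phy$edge[, 1L]))
  kids <- lapply(seq_len(nt + phy$Nnode), function(v) {
    phy$edge[phy$edge[, 1L] == v, 2L]
  })
  grid <- as.matrix(expand.grid(rep(list(cand), length(internals))))
  mask_of <- function(v) {
    if (v <= nt) {
      rep(to_mask(terminal_ranges[[phy$tip.label[v]]]), nrow(grid))
    } else {
      grid[, match(v, internals)]
    }
  }
  total <- rep(0, nrow(grid))
  NOT <- function(m) bitwAnd(bitwNot(m), 2^np - 1L)
  for (v in internals) {
    a <- mask_of(v)
    d1 <- mask_of(kids[[v]][1L])
    d2 <- mask_of(kids[[v]][2L])
    u <- bitwOr(d1, d2)
    vic <- pc[bitwAnd(d1, d2) + 1L] + pc[bitwXor(a, u) + 1L] + 1
    sym <- pc[bitwXor(a, d1) + 1L] + pc[bitwXor(a, d2) + 1L] + 1
    ov <- pc[bitwAnd(d1, d2) + 1L]
    pnt_core <- ifelse(ov >= 1L, ov - 1L, 1L) + pc[bitwAnd(u, NOT(a)) + 1L]
    pnt1 <- pnt_core + pc[bitwAnd(a, NOT(d1)) + 1L] + 1
    pnt2 <- pnt_core + pc[bitwAnd(a, NOT(d2)) + 1L] + 1
    fnd1 <- (pc[d2 + 1L] - 1L) + pc[bitwAnd(d2, a) + 1L] +
      pc[bitwXor(a, d1) + 1L] + 1
    fnd2 <- (pc[d1 + 1L] - 1L) + pc[bitwAnd(d1, a) + 1L] +
      pc[bitwXor(a, d2) + 1L] + 1
    total <- total + pmin(vic, sym, pnt1, pnt2, fnd1, fnd2)
  }
  min(total)
}

# random fully-observed test matrix on a random tree
random_case <- function(seed, n_taxa = NULL, n_char = NULL, n_states = NULL) {
  set.seed(seed)
  if (is.null(n_taxa)) n_taxa <- sample(4:8, 1L)
  if (is.null(n_char)) n_char <- sample(2:6, 1L)
  if (is.null(n_states)) n_states <- sample(2:4, 1L)
  tree <- simulate_tree(n_taxa, "random", seed = seed + 1000L)
  cells <- matrix(as.character(sample.int(n_states, n_taxa * n_char,
                                          replace = TRUE) - 1L),
                  n_taxa, n_char)
  # guarantee at least one observed state per character (all observed here)
  rownames(cells) <- tree$tip.label
  list(tree = tree, matrix = character_matrix(cells), n_states = n_states)
}
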