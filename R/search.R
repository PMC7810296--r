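# ---- unrooted binary trees as adjacency lists ----------------------------
# Tips are nodes 1..n_tip (labelled by taxa); internal nodes are allocated
# above n_tip and have degree 3. This light representation makes the search
# moves (taxon insertion, bisection/reconnection) cheap pointer surgery.

ut_new <- function(taxa) {
  n <- length(taxa)
  list(nbr = vector("list", 2L * n), tip_label = taxa, n_tip = n)
}

ut_edges <- function(ut) {
  out <- list()
  for (a in seq_along(ut$nbr)) {
    nb <- ut$nbr[[a]]
    for (b in nb) if (b > a) out[[length(out) + 1L]] <- c(a, b)
  }
  do.call(rbind, out)
}

ut_nodes <- function(ut) which(lengths(ut$nbr) > 0L)

# replace `old` with `new` in the neighbour list of `at`
.swap_nbr <- function(ut, at, old, new) {
  nb <- ut$nbr[[at]]
  nb[match(old, nb)] <- new
  ut$nbr[[at]] <- nb
  ut
}

# insert tip `t` on edge (a, b) using fresh internal node `w`
ut_insert <- function(ut, a, b, t, w) {
  ut <- .swap_nbr(ut, a, b, w)
  ut <- .swap_nbr(ut, b, a, w)
  ut$nbr[[w]] <- c(a, b, t)
  ut$nbr[[t]] <- w
  ut
}

# component of `start` after conceptually deleting edge (cut_a, cut_b)
ut_component <- function(ut, start, cut_a, cut_b) {
  seen <- integer(0)
  queue <- start
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    nb <- ut$nbr[[v]]
    if (v == cut_a) nb <- nb[nb != cut_b]
    if (v == cut_b) nb <- nb[nb != cut_a]
    queue <- c(queue, nb[!(nb %in% seen)])
  }
  sort(seen)
}

# postorder traversal (node, parent) entering at `root_tip`'s neighbour
.ut_order <- function(ut, root_tip = NULL) {
  if (is.null(root_tip)) {
    # first tip actually present (partial trees arise during stepwise
    # addition)
    root_tip <- which(lengths(ut$nbr[seq_len(ut$n_tip)]) > 0L)[1L]
  }
  start <- ut$nbr[[root_tip]][1L]
  stack <- list(c(start, root_tip))
  out <- list()
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    out[[length(out) + 1L]] <- top
    v <- top[1L]
    for (w in ut$nbr[[v]]) {
      if (w != top[2L] && length(ut$nbr[[w]]) > 1L) {
        stack[[length(stack) + 1L]] <- c(w, v)
      }
    }
  }
  rev(out)
}

# Fitch length of an unrooted binary tree over bitmask characters.
# `masks` is an n_tip x n_char integer matrix of state bitmasks.
ut_fitch <- function(ut, masks) {
  present <- which(lengths(ut$nbr[seq_len(ut$n_tip)]) > 0L)
  if (length(present) == 2L) {
    return(sum(bitwAnd(masks[present[1L], ], masks[present[2L], ]) == 0L))
  }
  ord <- .ut_order(ut)
  M <- matrix(0L, length(ut$nbr), ncol(masks))
  M[seq_len(ut$n_tip), ] <- masks
  steps <- 0L
  for (k in seq_along(ord)) {
    v <- ord[[k]][1L]
    from <- ord[[k]][2L]
    if (v <= ut$n_tip) next
    acc <- NULL
    for (w in ut$nbr[[v]]) {
      if (w == from) next
      mc <- M[w, ]
      if (is.null(acc)) {
        acc <- mc
      } else {
        t <- bitwAnd(acc, mc)
        z <- t == 0L
        steps <- steps + sum(z)
        if (any(z)) t[z] <- bitwOr(acc, mc)[z]
        acc <- t
      }
    }
    M[v, ] <- acc
  }
  root <- ord[[length(ord)]]
  t <- bitwAnd(M[root[1L], ], M[root[2L], ])
  steps + sum(t == 0L)
}

# bipartition signature (collapse-free identity)
ut_signature <- function(ut) {
  ed <- ut_edges(ut)
  keys <- character(0)
  for (k in seq_len(nrow(ed))) {
    a <- ed[k, 1L]
    b <- ed[k, 2L]
    if (a <= ut$n_tip || b <= ut$n_tip) next
    side <- ut_component(ut, a, a, b)
    side <- side[side <= ut$n_tip]
    if (1L %in% side) {
      side <- setdiff(seq_len(ut$n_tip), side)
    }
    if (length(side) >= 2L && length(side) <= ut$n_tip - 2L) {
      keys <- c(keys, paste(side, collapse = ","))
    }
  }
  paste(sort(unique(keys)), collapse = ";")
}

ut_has_clade <- function(ut, clade_idx) {
  n <- ut$n_tip
  clade_idx <- sort(clade_idx)
  if (length(clade_idx) < 2L || length(clade_idx) > n - 2L) return(TRUE)
  key <- if (1L %in% clade_idx) {
    paste(setdiff(seq_len(n), clade_idx), collapse = ",")
  } else {
    paste(clade_idx, collapse = ",")
  }
  key %in% strsplit(ut_signature(ut), ";", fixed = TRUE)[[1L]]
}

# rooted Newick with the outgroup as sister to everything else
ut_to_newick <- function(ut, outgroup_idx = 1L) {
  lab <- ut$tip_label
  if (ut$n_tip == 2L) {
    return(paste0("(", lab[outgroup_idx], ",",
                  lab[-outgroup_idx][1L], ");"))
  }
  sub <- function(v, from) {
    if (v <= ut$n_tip) return(lab[v])
    kids <- ut$nbr[[v]][ut$nbr[[v]] != from]
    paste0("(", paste(vapply(kids, sub, "", from = v), collapse = ","), ")")
  }
  w <- ut$nbr[[outgroup_idx]][1L]
  paste0("(", lab[outgroup_idx], ",", sub(w, outgroup_idx), ");")
}

ut_from_phylo <- function(phy) {
  u <- ape::unroot(phy)
  taxa <- u$tip.label
  ut <- ut_new(taxa)
  # node ids already conform: tips 1..n, internals n+1..
  for (k in seq_len(nrow(u$edge))) {
    a <- u$edge[k, 1L]
    b <- u$edge[k, 2L]
    ut$nbr[[a]] <- c(ut$nbr[[a]], b)
    ut$nbr[[b]] <- c(ut$nbr[[b]], a)
  }
  ut
}

# ---- search configuration -------------------------------------------------

#' Configure a heuristic parsimony search
#'
#' @param n_replicates random-addition-sequence starts.
#' @param hold maximum equally parsimonious trees retained per replicate.
#' @param swapper branch-swapping move set: `"TBR"` (bisection and
#'   reconnection over all edge pairs), `"SPR"` or `"NNI"`.
#' @param seed integer seed making the search deterministic.
#' @param slack retain trees up to `slack` steps above the best length
#'   (used by Bremer searches).
#' @param collapse rule deciding which branches count for tree identity:
#'   `"no-unambiguous-support"` (default; a branch is kept only when some
#'   character changes on it in every most-parsimonious reconstruction --
#'   `"min-length-zero"` is accepted as an alias), `"strict"` (collapse only
#'   branches that change in no reconstruction) or `"none"`.
#' @return a `search_config` list.
#' @export
search_config <- function(n_replicates = 10L, hold = 10L,
                          swapper = c("TBR", "SPR", "NNI"), seed = 1L,
                          slack = 0L,
                          collapse = c("no-unambiguous-support",
                                       "min-length-zero", "strict", "none")) {
  swapper <- match.arg(swapper)
  collapse <- match.arg(collapse)
  if (collapse == "min-length-zero") collapse <- "no-unambiguous-support"
  stopifnot(n_replicates >= 1L, hold >= 1L, slack >= 0L)
  structure(list(n_replicates = as.integer(n_replicates),
                 hold = as.integer(hold), swapper = swapper,
                 seed = as.integer(seed), slack = as.integer(slack),
                 collapse = collapse),
            class = "search_config")
}

# bitmask rows for every taxon of a matrix; ? and - mask all ten states
matrix_masks <- function(matrix) {
  st <- .state_int(matrix$cells)
  m <- matrix(bitwShiftL(1L, 10L) - 1L, nrow(st), ncol(st))
  obs <- which(!is.na(st))
  m[obs] <- bitwShiftL(1L, st[obs])
  rownames(m) <- matrix$taxa
  m
}

# one pass of branch swapping; returns first strictly better tree found, or
# the set of distinct equal-score neighbours (up to `hold`)
.swap_step <- function(ut, masks, cur, swapper, hold, objective) {
  equals <- list()
  keys <- character(0)
  ed <- ut_edges(ut)
  for (k in seq_len(nrow(ed))) {
    a <- ed[k, 1L]
    b <- ed[k, 2L]
    compA <- ut_component(ut, a, a, b)
    compB <- ut_component(ut, b, b, a)
    cand <- .reconnections(ut, a, b, compA, compB, swapper)
    for (nt in cand) {
      val <- objective(nt)
      if (val < cur) return(list(better = nt, value = val))
      if (val == cur && length(equals) < hold) {
        key <- ut_signature(nt)
        if (!(key %in% keys)) {
          keys <- c(keys, key)
          equals[[length(equals) + 1L]] <- nt
        }
      }
    }
  }
  list(better = NULL, equals = equals)
}

# candidate trees from cutting edge (a, b) and reconnecting the two pieces
.reconnections <- function(ut, a, b, compA, compB, swapper) {
  if (swapper == "NNI") return(.nni_moves(ut, a, b))
  out <- list()
  sidesA <- .cut_side(ut, a, b, compA)
  sidesB <- .cut_side(ut, b, a, compB)
  for (sa in sidesA$sites) {
    for (sb in sidesB$sites) {
      if (swapper == "SPR" && !sa$original && !sb$original) next
      nt <- .rebuild(ut, a, b, sidesA, sidesB, sa, sb)
      if (!is.null(nt)) out[[length(out) + 1L]] <- nt
    }
  }
  out
}

# describe one side of a bisection: the edges available for reconnection
# after suppressing the cut-end node (when internal)
.cut_side <- function(ut, end, other, comp) {
  if (end <= ut$n_tip) {
    return(list(kind = "tip", end = end,
                sites = list(list(node = end, original = TRUE))))
  }
  rest <- ut$nbr[[end]][ut$nbr[[end]] != other]  # the two merged neighbours
  sites <- list()
  # edges of the component after suppressing `end`
  for (v in comp) {
    if (v == end) next
    for (w in ut$nbr[[v]]) {
      if (w == end || !(w %in% comp) || w < v) next
      sites[[length(sites) + 1L]] <- list(edge = c(v, w), original = FALSE)
    }
  }
  # the merged edge (rest[1], rest[2]) replaces the two edges through `end`
  sites[[length(sites) + 1L]] <- list(edge = sort(rest), original = TRUE)
  list(kind = "internal", end = end, rest = rest, sites = sites)
}

.rebuild <- function(ut, a, b, sidesA, sidesB, sa, sb) {
  nt <- ut
  # dissolve the cut ends
  if (sidesA$kind == "internal") {
    r <- sidesA$rest
    nt <- .swap_nbr(nt, r[1L], a, r[2L])
    nt <- .swap_nbr(nt, r[2L], a, r[1L])
    nt$nbr[[a]] <- integer(0)
  }
  if (sidesB$kind == "internal") {
    r <- sidesB$rest
    nt <- .swap_nbr(nt, r[1L], b, r[2L])
    nt <- .swap_nbr(nt, r[2L], b, r[1L])
    nt$nbr[[b]] <- integer(0)
  }
  pa <- if (!is.null(sa$node)) {
    sa$node
  } else {
    e <- sa$edge
    nt <- .swap_nbr(nt, e[1L], e[2L], a)
    nt <- .swap_nbr(nt, e[2L], e[1L], a)
    nt$nbr[[a]] <- e
    a
  }
  pb <- if (!is.null(sb$node)) {
    sb$node
  } else {
    e <- sb$edge
    nt <- .swap_nbr(nt, e[1L], e[2L], b)
    nt <- .swap_nbr(nt, e[2L], e[1L], b)
    nt$nbr[[b]] <- e
    b
  }
  nt$nbr[[pa]] <- c(nt$nbr[[pa]], pb)
  nt$nbr[[pb]] <- c(nt$nbr[[pb]], pa)
  if (length(nt$nbr[[pa]]) > if (pa <= nt$n_tip) 1L else 3L) return(NULL)
  if (length(nt$nbr[[pb]]) > if (pb <= nt$n_tip) 1L else 3L) return(NULL)
  nt
}

.nni_moves <- function(ut, a, b) {
  if (a <= ut$n_tip || b <= ut$n_tip) return(list())
  xs <- ut$nbr[[a]][ut$nbr[[a]] != b]
  ys <- ut$nbr[[b]][ut$nbr[[b]] != a]
  out <- list()
  for (y in ys[1:2]) {
    x <- xs[1L]
    nt <- ut
    nt <- .swap_nbr(nt, a, x, y)
    nt <- .swap_nbr(nt, b, y, x)
    nt <- .swap_nbr(nt, x, a, b)
    nt <- .swap_nbr(nt, y, b, a)
    out[[length(out) + 1L]] <- nt
  }
  out
}

# ---- heuristic search -----------------------------------------------------

#' Heuristic search for most parsimonious trees
#'
#' Random-addition-sequence starts followed by branch swapping
#' (first-improvement hill climbing to a local optimum). Searches operate on
#' unrooted topologies; results are reported rooted on the declared
#' outgroup, with branches collapsed according to `config$collapse` before
#' topologies are compared for distinctness.
#'
#' @param matrix a [character_matrix()].
#' @param config a [search_config()].
#' @param outgroup taxon used to root the reported trees.
#' @param constraint optional clade (character vector of taxa).
#' @param converse when `TRUE`, only trees NOT containing `constraint` are
#'   retained (the converse-constraint search used for Bremer support).
#' @return a `tree_set`: `trees` (list of rooted [ape::phylo]), `lengths`,
#'   `best_length`, `replicate_log` (best length per replicate), `config`.
#' @export
heuristic_search <- function(matrix, config = search_config(),
                             outgroup = matrix$taxa[1L],
                             constraint = NULL, converse = FALSE) {
  stopifnot(inherits(matrix, "character_matrix"))
  taxa <- matrix$taxa
  if (length(taxa) < 4L) stop("need at least 4 taxa", call. = FALSE)
  outgroup <- normalize_taxon(outgroup)
  if (!outgroup %in% taxa) stop("outgroup not in matrix", call. = FALSE)
  cons_idx <- NULL
  if (!is.null(constraint)) {
    constraint <- normalize_taxon(constraint)
    if (!all(constraint %in% taxa)) {
      stop("constraint clade is not a subset of the matrix taxa",
           call. = FALSE)
    }
    cons_idx <- match(constraint, taxa)
  }
  masks <- matrix_masks(matrix)[taxa, , drop = FALSE]
  big <- 1e7
  objective <- function(ut) {
    len <- ut_fitch(ut, masks)
    if (!is.null(cons_idx)) {
      has <- ut_has_clade(ut, cons_idx)
      if ((converse && has) || (!converse && !has)) len <- len + big
    }
    len
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  pool <- list()        # signature -> list(ut, len)
  rep_log <- numeric(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    ord <- sample(length(taxa))
    ut <- .ras_tree(taxa, ord, masks)
    val <- objective(ut)
    repeat {
      step <- .swap_step(ut, masks, val, config$swapper, config$hold,
                         objective)
      if (!is.null(step$better)) {
        ut <- step$better
        val <- step$value
      } else {
        break
      }
    }
    rep_log[r] <- val
    found <- c(list(ut), step$equals)
    for (t in found) {
      v <- objective(t)
      if (v >= big) next
      key <- ut_signature(t)
      if (is.null(pool[[key]]) || pool[[key]]$len > v) {
        pool[[key]] <- list(ut = t, len = v)
      }
    }
  }
  if (!length(pool)) {
    stop("no tree satisfying the constraint was found", call. = FALSE)
  }
  lens <- vapply(pool, `[[`, 0, "len")
  best <- min(lens)
  keep <- pool[lens <= best + config$slack]
  trees <- lapply(keep, function(p) {
    phy <- read_newick_text(ut_to_newick(p$ut, match(outgroup, taxa)))
    collapse_unsupported(phy, matrix, config$collapse)
  })
  # distinctness is judged after collapsing
  sig <- vapply(trees, function(t) paste(sort(clade_keys(t)), collapse = ";"),
                "")
  first <- !duplicated(sig)
  structure(list(trees = unname(trees[first]),
                 lengths = unname(vapply(keep, `[[`, 0, "len")[first]),
                 best_length = best, replicate_log = rep_log,
                 config = config, outgroup = outgroup),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree set: %d distinct topologies, best length %d\n",
              length(x$trees), as.integer(x$best_length)))
  invisible(x)
}

# random addition sequence: taxa inserted in `ord`, each at the placement
# minimizing the Fitch length (first best in canonical edge order)
.ras_tree <- function(taxa, ord, masks) {
  n <- length(taxa)
  ut <- ut_new(taxa)
  w <- n + 1L
  ut$nbr[[w]] <- ord[1:3]
  for (t in ord[1:3]) ut$nbr[[t]] <- w
  next_internal <- n + 2L
  if (n >= 4L) {
    for (t in ord[4:n]) {
      ed <- ut_edges(ut)
      best <- NULL
      best_len <- Inf
      for (k in seq_len(nrow(ed))) {
        cand <- ut_insert(ut, ed[k, 1L], ed[k, 2L], t, next_internal)
        len <- ut_fitch(cand, masks)
        if (len < best_len) {
          best_len <- len
          best <- cand
        }
      }
      ut <- best
      next_internal <- next_internal + 1L
    }
  }
  ut
}

#' Collapse branches lacking character support
#'
#' @param tree rooted [ape::phylo].
#' @param matrix a [character_matrix()].
#' @param rule `"no-unambiguous-support"`, `"strict"` or `"none"` (see
#'   [search_config()]).
#' @return an [ape::phylo], possibly multifurcating.
#' @export
collapse_unsupported <- function(tree, matrix,
                                 rule = "no-unambiguous-support") {
  if (rule == "none") return(tree)
  nt <- length(tree$tip.label)
  bounds <- edge_change_bounds(tree, matrix)
  drop <- if (rule == "strict") {
    apply(bounds$forced_equal, 1L, all)
  } else {
    apply(bounds$free, 1L, all)
  }
  zero_nodes <- bounds$nodes[drop]
  zero_nodes <- zero_nodes[zero_nodes > nt]  # only internal edges collapse
  if (!length(zero_nodes)) return(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[tree$edge[, 2L] %in% zero_nodes] <- 0
  out <- ape::di2multi(tree, tol = 0.5)
  out$edge.length <- NULL
  out
}

#' Bremer (decay) support of a clade
#'
#' Runs a converse-constraint search (best tree NOT containing the clade)
#' and returns the extra steps that tree needs relative to the best length
#' in `best`.
#'
#' @param matrix a [character_matrix()].
#' @param best a `tree_set` from [heuristic_search()].
#' @param clade character vector of taxa.
#' @param config a [search_config()] for the converse search.
#' @return integer decay value (0 when the clade is contradicted by an
#'   equally parsimonious tree).
#' @export
bremer_support <- function(matrix, best, clade, config = best$config) {
  cons <- strict_consensus(best$trees)
  if (is.na(find_clade_node(cons, clade))) {
    stop("clade is not present in the strict consensus of the best trees",
         call. = FALSE)
  }
  config$slack <- 0L
  converse <- heuristic_search(matrix, config, outgroup = best$outgroup,
                               constraint = clade, converse = TRUE)
  as.integer(converse$best_length - best$best_length)
}
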