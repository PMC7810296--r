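.INF <- 1e9
.N_STATES <- 10L

# integer states per cell: 0..9, NA for "?" and "-"
.state_int <- function(cells) {
  s <- suppressWarnings(as.integer(cells))
  dim(s) <- dim(cells)
  dimnames(s) <- dimnames(cells)
  s
}

# children list and traversal orders for a phylo tree
.tree_index <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  kids <- vector("list", nt + nn)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[k, 2L])
  }
  po <- ape::reorder.phylo(phy, "postorder")
  post_parents <- unique(po$edge[, 1L])      # parents in postorder
  root <- nt + 1L
  pre <- rev(post_parents)                   # internal nodes, root first
  parent <- integer(nt + nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  list(n_tip = nt, n_node = nn, root = root, kids = kids,
       postorder = post_parents, preorder = pre, parent = parent)
}

# Unordered (Fitch) parsimony as a unit-cost Sankoff dynamic program.
# Exact on binary trees and on multifurcations (scored as simultaneous
# radiations). Returns per-node conditional cost matrices so ACCTRAN /
# DELTRAN / MPR sets can be derived without rescoring.
.parsimony_dp <- function(phy, cells) {
  idx <- .tree_index(phy)
  tips <- phy$tip.label
  missing <- setdiff(tips, rownames(cells))
  if (length(missing)) {
    stop("tree leaf absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  st <- .state_int(cells[tips, , drop = FALSE])
  n_char <- ncol(st)
  n_nodes <- idx$n_tip + idx$n_node
  down <- vector("list", n_nodes)
  contrib <- vector("list", n_nodes)  # child's min-cost contribution to parent
  for (i in seq_len(idx$n_tip)) {
    m <- matrix(0, .N_STATES, n_char)
    obs <- !is.na(st[i, ])
    if (any(obs)) {
      m[, obs] <- .INF
      m[cbind(st[i, obs] + 1L, which(obs))] <- 0
    }
    down[[i]] <- m
  }
  for (v in idx$postorder) {
    acc <- matrix(0, .N_STATES, n_char)
    for (c in idx$kids[[v]]) {
      mint <- apply(down[[c]], 2L, min)
      contrib[[c]] <- pmin(down[[c]],
                           matrix(mint + 1, .N_STATES, n_char, byrow = TRUE))
      acc <- acc + contrib[[c]]
    }
    down[[v]] <- acc
  }
  len <- apply(down[[idx$root]], 2L, min)
  list(idx = idx, down = down, contrib = contrib, length = len,
       n_char = n_char, states = st)
}

# outside costs: up[[v]][s, j] = min changes outside subtree(v) if v has
# state s; also per-edge "g" matrices for MPR sets and collapse rules
.parsimony_up <- function(dp) {
  idx <- dp$idx
  n_char <- dp$n_char
  up <- vector("list", idx$n_tip + idx$n_node)
  g <- vector("list", idx$n_tip + idx$n_node)  # indexed by child node
  up[[idx$root]] <- matrix(0, .N_STATES, n_char)
  for (u in idx$preorder) {
    for (v in idx$kids[[u]]) {
      down_minus <- dp$down[[u]] - dp$contrib[[v]]
      gv <- up[[u]] + down_minus
      ming <- apply(gv, 2L, min)
      g[[v]] <- gv
      up[[v]] <- pmin(gv, matrix(ming + 1, .N_STATES, n_char, byrow = TRUE))
    }
  }
  list(up = up, g = g)
}

#' Minimum and maximum conceivable steps for one character
#'
#' The minimum is the number of distinct observed states minus one; the
#' maximum is the steps the character needs on a star tree (taxon count with
#' observed states minus the count of the most frequent state). Only taxa in
#' `taxa` (default: all) are counted.
#'
#' @param matrix a [character_matrix()].
#' @param j character index.
#' @param taxa optional taxon subset (e.g. the leaves of a tree).
#' @return integer vector `c(min, max)`.
#' @export
char_min_max <- function(matrix, j, taxa = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  cells <- matrix$cells
  if (!is.null(taxa)) cells <- cells[normalize_taxon(taxa), , drop = FALSE]
  tok <- cells[, j]
  obs <- tok[tok %in% as.character(0:9)]
  if (!length(obs)) stop("character ", j, " has no observed state among the ",
                         "requested taxa", call. = FALSE)
  counts <- table(obs)
  c(min = length(counts) - 1L, max = length(obs) - max(counts))
}

#' Parsimony tree length and ensemble fit indices
#'
#' Scores every character of `matrix` on `tree` under equal-weights
#' unordered parsimony. Unknown (`?`) and inapplicable (`-`) tokens are both
#' treated as full ambiguity. Polytomies are scored exactly as simultaneous
#' multifurcations (unit-cost dynamic program, which reduces to the Fitch
#' algorithm on binary trees).
#'
#' @param tree an [ape::phylo] tree whose leaves are a subset of the matrix
#'   taxa.
#' @param matrix a [character_matrix()].
#' @return a `parsimony_scores` object: `total_length`, `per_char_length`,
#'   `per_char_min`, `per_char_max`, `ci`, `ri` (raw ratios; round to 2
#'   decimals to compare with conventional reports). The dynamic-program
#'   tables are attached for reuse by [optimize_states()].
#' @export
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  dp <- .parsimony_dp(tree, matrix$cells)
  mm <- vapply(seq_len(matrix$n_char), function(j) {
    char_min_max(matrix, j, taxa = tree$tip.label)
  }, c(min = 0L, max = 0L))
  len <- dp$length
  minv <- as.numeric(mm["min", ])
  maxv <- as.numeric(mm["max", ])
  ci <- if (sum(len) > 0) sum(minv) / sum(len) else 1
  informative <- maxv > minv
  ri <- if (any(informative)) {
    sum((maxv - len)[informative]) / sum((maxv - minv)[informative])
  } else {
    NA_real_
  }
  structure(list(total_length = sum(len), per_char_length = len,
                 per_char_min = minv, per_char_max = maxv,
                 ci = ci, ri = ri, dp = dp, tree = tree),
            class = "parsimony_scores")
}

#' @export
print.parsimony_scores <- function(x, ...) {
  cat(sprintf("parsimony scores: length %d, ci %.2f, ri %s (%d characters)\n",
              as.integer(x$total_length), x$ci,
              if (is.na(x$ri)) "NA" else sprintf("%.2f", x$ri),
              length(x$per_char_length)))
  invisible(x)
}

#' Optimize character states on a fixed topology
#'
#' Produces one most-parsimonious assignment of states to every node for
#' every character, under either accelerated (`ACCTRAN`: ambiguous changes
#' placed as close to the root as possible) or delayed (`DELTRAN`: changes
#' placed as close to the tips as possible) transformation. Ties among
#' states are broken toward the lowest state label. The number of implied
#' changes per character equals that character's parsimony length under
#' both flavors.
#'
#' @param tree an [ape::phylo] tree.
#' @param matrix a [character_matrix()].
#' @param flavor `"DELTRAN"` (default) or `"ACCTRAN"`.
#' @param scores optional precomputed [fitch_length()] result for the same
#'   tree and matrix.
#' @return a `state_reconstruction`: `states` (node x character integer
#'   matrix), `changes` (data.frame: `char`, `node`, `label`, `from`, `to`),
#'   `flavor`, `per_char_changes`.
#' @export
optimize_states <- function(tree, matrix, flavor = c("DELTRAN", "ACCTRAN"),
                            scores = NULL) {
  flavor <- match.arg(flavor)
  if (is.null(scores)) scores <- fitch_length(tree, matrix)
  dp <- scores$dp
  idx <- dp$idx
  n_char <- dp$n_char
  n_nodes <- idx$n_tip + idx$n_node
  states <- matrix(NA_integer_, n_nodes, n_char)
  root_costs <- dp$down[[idx$root]]
  # root: lowest state attaining the minimum subtree cost
  states[idx$root, ] <- apply(root_costs, 2L, which.min) - 1L
  order_nodes <- idx$preorder
  for (u in order_nodes) {
    su <- states[u, ]
    for (v in idx$kids[[u]]) {
      dv <- dp$down[[v]]
      mins <- apply(dv, 2L, min)
      keep_cost <- dv[cbind(su + 1L, seq_len(n_char))]
      if (flavor == "ACCTRAN") {
        # keep the parent state when it is in the downpass (argmin) set,
        # otherwise change here, to the lowest argmin state
        keep <- keep_cost == mins
      } else {
        # DELTRAN: keep the parent state whenever doing so still attains the
        # conditional optimum (cost <= min + 1), i.e. delay the change
        keep <- keep_cost <= mins + 1
      }
      sv <- ifelse(keep, su, apply(dv, 2L, which.min) - 1L)
      states[v, ] <- sv
    }
  }
  labels <- c(tree$tip.label, paste0("node", seq_len(idx$n_node) + idx$n_tip))
  par_safe <- idx$parent
  par_safe[idx$root] <- idx$root  # root row compares with itself: no change
  ch <- which(states[par_safe, , drop = FALSE] != states, arr.ind = TRUE)
  changes <- data.frame(char = ch[, 2L], node = ch[, 1L],
                        label = labels[ch[, 1L]],
                        from = states[cbind(idx$parent[ch[, 1L]], ch[, 2L])],
                        to = states[cbind(ch[, 1L], ch[, 2L])])
  changes <- changes[order(changes$char, changes$node), , drop = FALSE]
  rownames(changes) <- NULL
  per_char <- tabulate(changes$char, nbins = n_char)
  structure(list(states = states, changes = changes, flavor = flavor,
                 per_char_changes = per_char, tree = tree),
            class = "state_reconstruction")
}

#' @export
print.state_reconstruction <- function(x, ...) {
  cat(sprintf("state reconstruction (%s): %d changes over %d characters\n",
              x$flavor, nrow(x$changes), length(x$per_char_changes)))
  invisible(x)
}

#' Export a change list as TSV
#'
#' @param reconstruction a [optimize_states()] result.
#' @param scores matching [fitch_length()] result (for the exclusive flag).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_changes <- function(reconstruction, scores, path) {
  ch <- reconstruction$changes
  excl <- scores$per_char_length[ch$char] == scores$per_char_min[ch$char]
  out <- data.frame(character = ch$char, branch = ch$label, from = ch$from,
                    to = ch$to, flavor = reconstruction$flavor,
                    exclusive = excl)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify the character changes supporting a clade
#'
#' Reads the changes placed on the clade's stem branch in `reconstruction`
#' and labels each one `exclusive` when its character changes the minimum
#' conceivable number of times on the whole tree (character consistency
#' index of 1), otherwise `homoplastic`.
#'
#' @param tree an [ape::phylo] tree.
#' @param matrix a [character_matrix()].
#' @param reconstruction a [optimize_states()] result on the same tree.
#' @param clade character vector of leaf labels forming a clade of `tree`.
#' @return list with data.frames `exclusive` and `homoplastic` (columns
#'   `char`, `from`, `to`).
#' @export
classify_synapomorphies <- function(tree, matrix, reconstruction, clade) {
  node <- find_clade_node(tree, clade)
  if (is.na(node)) {
    stop("clade {", paste(clade, collapse = ", "),
         "} is not a node of the tree", call. = FALSE)
  }
  scores <- fitch_length(tree, matrix)
  ch <- reconstruction$changes
  stem <- ch[ch$node == node, , drop = FALSE]
  excl <- scores$per_char_length[stem$char] == scores$per_char_min[stem$char]
  keep <- c("char", "from", "to")
  list(exclusive = stem[excl, keep, drop = FALSE],
       homoplastic = stem[!excl, keep, drop = FALSE])
}

# per-edge change bounds used by the tree-search collapse rules:
# for every non-root node v (the edge parent(v) -> v) and every character,
# `free` says the edge can be change-free in some most-parsimonious
# reconstruction, `forced_equal` says it is change-free in all of them
edge_change_bounds <- function(tree, matrix) {
  dp <- .parsimony_dp(tree, matrix$cells)
  upg <- .parsimony_up(dp)
  idx <- dp$idx
  n_char <- dp$n_char
  L <- matrix(dp$length, .N_STATES, n_char, byrow = TRUE)
  nodes <- setdiff(seq_len(idx$n_tip + idx$n_node), idx$root)
  free <- matrix(NA, length(nodes), n_char)
  forced <- matrix(NA, length(nodes), n_char)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    tot_same <- upg$g[[v]] + dp$down[[v]]      # u = v = s
    free[i, ] <- colSums(tot_same == L) > 0
    # can the edge change in some optimal reconstruction?
    # min over s != t of g[t] + 1 + down[v][s]
    gv <- upg$g[[v]]
    dv <- dp$down[[v]]
    m2 <- vapply(seq_len(n_char), function(j) {
      gj <- gv[, j]
      dj <- dv[, j]
      best <- .INF
      for (s in seq_len(.N_STATES)) {
        alt <- min(gj[-s])
        best <- min(best, dj[s] + alt + 1)
      }
      best
    }, 0)
    forced[i, ] <- m2 > dp$length
  }
  list(nodes = nodes, free = free, forced_equal = forced)
}
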