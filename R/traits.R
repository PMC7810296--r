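#' Body-size class from length in millimetres
#'
#' Six contiguous 3 mm classes, lower-inclusive: class 0 below 12 mm,
#' class 1 in \[12, 15), 2 in \[15, 18), 3 in \[18, 21), 4 in \[21, 24) and
#' class 5 at 24 mm or more.
#'
#' @param length_mm positive body length(s) in mm.
#' @return integer class(es) 0-5.
#' @examples
#' classify_size(c(11, 12, 16, 25))
#' @export
classify_size <- function(length_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("body length must be positive", call. = FALSE)
  }
  cls <- floor((length_mm - 12) / 3) + 1
  as.integer(pmin(pmax(cls, 0), 5))
}

# single-character Sankoff over an arbitrary state-to-state cost matrix;
# exact on multifurcations. Returns conditional cost tables.
.trait_dp <- function(phy, leaf_state, cost) {
  idx <- .tree_index(phy)
  k <- nrow(cost)
  n_nodes <- idx$n_tip + idx$n_node
  down <- matrix(0, n_nodes, k)
  for (i in seq_len(idx$n_tip)) {
    s <- leaf_state[phy$tip.label[i]]
    down[i, ] <- .INF
    down[i, s] <- 0
  }
  for (v in idx$postorder) {
    acc <- numeric(k)
    for (c in idx$kids[[v]]) {
      # min over child state t of down[c, t] + cost[s, t], for every s
      acc <- acc + apply(cost + rep(down[c, ], each = k), 1L, min)
    }
    down[v, ] <- acc
  }
  list(idx = idx, down = down, k = k, cost = cost)
}

#' Parsimony ancestral-state reconstruction of a categorical trait
#'
#' Optimizes one categorical trait on a fixed topology under parsimony.
#' States are unordered by default (any change costs one step); an ordered
#' (Wagner) mode charging the absolute state-index difference is available
#' for ordinal traits but is not the default. Every leaf of the tree must
#' carry a state. The total number of steps equals the parsimony length of
#' the trait treated as a single character.
#'
#' @param tree an [ape::phylo] tree (e.g. an ingroup subtree).
#' @param trait a [trait_table()].
#' @param ordered charge `|i - j|` per change instead of 1.
#' @return a `trait_reconstruction`: `trait`, `steps`, `root_states`
#'   (labels; a singleton is the inferred ancestral state), `node_states`
#'   (list of most-parsimonious state sets per node), `changes` (data.frame
#'   of branch changes under delayed optimization), `states` (one optimal
#'   label per node).
#' @export
reconstruct_trait <- function(tree, trait, ordered = FALSE) {
  stopifnot(inherits(trait, "trait_table"))
  missing <- setdiff(tree$tip.label, names(trait$index))
  if (length(missing)) {
    stop("no trait state for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- length(trait$states)
  cost <- if (ordered) {
    abs(outer(seq_len(k), seq_len(k), "-"))
  } else {
    1 - diag(k)
  }
  dp <- .trait_dp(tree, trait$index, cost)
  idx <- dp$idx
  root_cost <- dp$down[idx$root, ]
  steps <- min(root_cost)
  # outside costs for exact per-node MPR sets
  n_nodes <- idx$n_tip + idx$n_node
  up <- matrix(0, n_nodes, k)
  for (u in idx$preorder) {
    for (v in idx$kids[[u]]) {
      # cost outside subtree(v) per state of v
      sib <- numeric(k)
      for (w in idx$kids[[u]]) {
        if (w != v) {
          sib <- sib + apply(cost + rep(dp$down[w, ], each = k), 1L, min)
        }
      }
      g <- up[u, ] + sib
      # up[v, s] = min over parent state t of g[t] + cost[t, s]
      up[v, ] <- apply(cost + rep(g, k), 2L, min)
    }
  }
  total <- dp$down + up
  node_states <- lapply(seq_len(n_nodes), function(v) {
    trait$states[which(total[v, ] <= min(total[v, ]) + 1e-9)]
  })
  # one optimal assignment, delaying changes (conditional DP, keep parent
  # state among minimizers)
  assign <- integer(n_nodes)
  assign[idx$root] <- which.min(root_cost)
  for (u in idx$preorder) {
    for (v in idx$kids[[u]]) {
      cond <- dp$down[v, ] + cost[assign[u], ]
      m <- min(cond)
      assign[v] <- if (cond[assign[u]] <= m) assign[u] else which.min(cond)
    }
  }
  labels <- c(tree$tip.label, paste0("node", seq_len(idx$n_node) + idx$n_tip))
  chg <- which(assign[ifelse(seq_len(n_nodes) == idx$root, idx$root,
                             idx$parent[seq_len(n_nodes)])] != assign)
  changes <- data.frame(node = chg, label = labels[chg],
                        from = trait$states[assign[idx$parent[chg]]],
                        to = trait$states[assign[chg]])
  rownames(changes) <- NULL
  structure(list(trait = trait$trait, steps = as.integer(round(steps)),
                 root_states = node_states[[idx$root]],
                 node_states = node_states,
                 states = trait$states[assign],
                 changes = changes, tree = tree, ordered = ordered),
            class = "trait_reconstruction")
}

#' @export
print.trait_reconstruction <- function(x, ...) {
  cat(sprintf("trait '%s': %d steps, root state%s {%s}\n", x$trait, x$steps,
              if (length(x$root_states) > 1L) "s" else "",
              paste(x$root_states, collapse = ", ")))
  invisible(x)
}

#' Write a per-node state table and annotated Newick for a reconstruction
#'
#' @param x a [reconstruct_trait()] result.
#' @param path_table TSV destination for the per-node table.
#' @param path_tree optional Newick destination with `[&state=...]` node
#'   comments.
#' @return `path_table`, invisibly.
#' @export
write_trait_reconstruction <- function(x, path_table, path_tree = NULL) {
  n <- length(x$states)
  tab <- data.frame(node = seq_len(n),
                    label = c(x$tree$tip.label,
                              paste0("node", seq_len(n -
                                length(x$tree$tip.label)) +
                                length(x$tree$tip.label))),
                    state = x$states,
                    mpr_set = vapply(x$node_states, paste, "",
                                     collapse = "|"))
  utils::write.table(tab, path_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_tree)) {
    phy <- x$tree
    nt <- length(phy$tip.label)
    phy$node.label <- x$states[(nt + 1L):n]
    writeLines(ape::write.tree(phy), path_tree)
  }
  invisible(path_table)
}
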