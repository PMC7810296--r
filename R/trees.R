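#' Read a rooted tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that normalizes taxon labels
#' (spaces to underscores) and validates leaf-label uniqueness. `[&...]`
#' comment blocks are tolerated and stripped.
#'
#' @param path file containing one Newick tree.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_text(txt)
}

#' @rdname read_newick
#' @param text Newick string.
#' @export
read_newick_text <- function(text) {
  text <- gsub("\\[&[^]]*\\]", "", text)
  # normalize before parsing: strip whitespace around structure, then map
  # remaining in-label spaces to underscores
  text <- gsub("\\s*([(),;:])\\s*", "\\1", text)
  text <- gsub("\\s+", "_", trimws(text))
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes) {
    # report the offset of the first character where the balance goes wrong
    chars <- strsplit(text, "")[[1L]]
    bal <- cumsum((chars == "(") - (chars == ")"))
    off <- if (any(bal < 0)) which(bal < 0)[1L] else length(chars)
    stop(sprintf("unbalanced parentheses in Newick near character %d", off),
         call. = FALSE)
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick string", call. = FALSE)
  phy$tip.label <- normalize_taxon(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  phy
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read trees in the event-model "trees" tab dialect
#'
#' One Newick string per line; lines starting with `#` are skipped.
#'
#' @param path file to read.
#' @return a list of [ape::phylo] trees.
#' @export
read_gem_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no trees in ", path, call. = FALSE)
  lapply(lines, read_newick_text)
}

# ---- tree utilities shared across modules --------------------------------

# tips (as labels) descending from every node; index = node id
node_tip_sets <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    c <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

# node id whose descendant tip set equals `clade`, or NA
find_clade_node <- function(phy, clade) {
  clade <- sort(normalize_taxon(clade))
  sets <- node_tip_sets(phy)
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) == length(clade) &&
        identical(sort(sets[[i]]), clade)) {
      return(i)
    }
  }
  NA_integer_
}

# non-trivial rooted clades of a tree as a character vector of keys
# (sorted tip labels joined by "|"); excludes the root clade and leaves
clade_keys <- function(phy) {
  nt <- length(phy$tip.label)
  sets <- node_tip_sets(phy)
  root <- nt + 1L
  ids <- setdiff(seq(nt + 1L, nt + phy$Nnode), root)
  vapply(sets[ids], function(s) paste(sort(s), collapse = "|"), "")
}

# unrooted bipartition keys: for every internal edge, the sorted tip set on
# the side NOT containing the alphabetically first tip
bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  anchor <- tips[1L]
  sets <- node_tip_sets(phy)
  nt <- length(phy$tip.label)
  keys <- character(0)
  for (i in seq(nt + 1L, nt + phy$Nnode)) {
    s <- sets[[i]]
    side <- if (anchor %in% s) setdiff(tips, s) else s
    if (length(side) >= 2L && length(side) <= nt - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Test whether a tree contains a clade
#'
#' A clade is given as a set of leaf labels; containment is tested in the
#' unrooted (bipartition) sense, so the answer does not depend on where the
#' tree is rooted as long as the clade does not span the root.
#'
#' @param tree an [ape::phylo] tree.
#' @param clade character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
has_clade <- function(tree, clade) {
  clade <- sort(normalize_taxon(clade))
  tips <- sort(tree$tip.label)
  if (!all(clade %in% tips)) {
    stop("clade contains leaves absent from the tree: ",
         paste(setdiff(clade, tips), collapse = ", "), call. = FALSE)
  }
  if (length(clade) < 2L || length(clade) > length(tips) - 2L) return(TRUE)
  anchor <- tips[1L]
  key <- if (anchor %in% clade) {
    paste(setdiff(tips, clade), collapse = "|")
  } else {
    paste(clade, collapse = "|")
  }
  key %in% bipartition_keys(tree)
}

#' Strict consensus of a set of trees
#'
#' Returns the rooted tree containing exactly the clades present in every
#' input tree. All trees must share one leaf set and one root split
#' orientation (root them on the same outgroup first).
#'
#' @param trees a list of [ape::phylo] trees or a `tree_set` from
#'   [heuristic_search()].
#' @return an [ape::phylo] tree, possibly with polytomies.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  stopifnot(length(trees) >= 1L)
  tips <- sort(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), tips)) {
      stop("trees have mismatched leaf sets", call. = FALSE)
    }
  }
  shared <- Reduce(intersect, lapply(trees, clade_keys))
  build_from_clades(tips, shared)
}

# build a rooted tree from a laminar family of clade keys
build_from_clades <- function(tips, keys) {
  clades <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  clades <- clades[order(lengths(clades))]
  nest <- function(members) {
    # largest proper sub-clades of `members` partition the nesting
    sub <- clades[vapply(clades, function(cl) {
      length(cl) < length(members) && all(cl %in% members)
    }, TRUE)]
    taken <- character(0)
    parts <- list()
    for (cl in rev(sub)) {   # biggest first
      if (!any(cl %in% taken)) {
        parts <- c(parts, list(cl))
        taken <- c(taken, cl)
      }
    }
    single <- setdiff(members, taken)
    kids <- c(lapply(parts, nest), as.list(single))
    paste0("(", paste(unlist(kids), collapse = ","), ")")
  }
  txt <- paste0(nest(tips), ";")
  read_newick_text(txt)
}
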