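# Generators with known ground truth so every pipeline stage can be tested
# without real specimen or locality data. All generators are pure functions
# of their arguments plus the seed.

.with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a rooted binary tree
#'
#' @param n_taxa number of leaves (>= 2).
#' @param shape `"random"` (random joins, Yule-like) or `"pectinate"`
#'   (fully unbalanced comb).
#' @param seed integer seed.
#' @param labels optional leaf labels (default `t1`, `t2`, ...).
#' @return an [ape::phylo] rooted binary tree.
#' @export
simulate_tree <- function(n_taxa, shape = c("random", "pectinate"),
                          seed = 1L, labels = NULL) {
  shape <- match.arg(shape)
  stopifnot(n_taxa >= 2L)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  .with_seed(seed, {
    if (shape == "pectinate") {
      txt <- labels[n_taxa]
      for (i in rev(seq_len(n_taxa - 1L))) {
        txt <- paste0("(", labels[i], ",", txt, ")")
      }
      read_newick_text(paste0(txt, ";"))
    } else {
      parts <- as.list(labels)
      while (length(parts) > 1L) {
        pick <- sample.int(length(parts), 2L)
        merged <- paste0("(", parts[[pick[1L]]], ",", parts[[pick[2L]]], ")")
        parts <- c(parts[-pick], merged)
      }
      read_newick_text(paste0(parts[[1L]], ";"))
    }
  })
}

#' Recipe for simulating a character matrix on a tree
#'
#' @param n_taxa leaves of the simulated tree.
#' @param n_char characters to evolve.
#' @param n_states states per character (2-10).
#' @param rate expected number of state changes per branch and character
#'   (Poisson).
#' @param tree_shape passed to [simulate_tree()].
#' @param seed integer seed.
#' @return a `simulation_recipe` list.
#' @export
simulation_recipe <- function(n_taxa = 10L, n_char = 50L, n_states = 2L,
                              rate = 0.1, tree_shape = "random", seed = 1L) {
  stopifnot(n_taxa >= 4L, n_char >= 1L, n_states >= 2L, n_states <= 10L,
            rate >= 0)
  structure(list(n_taxa = as.integer(n_taxa), n_char = as.integer(n_char),
                 n_states = as.integer(n_states), rate = rate,
                 tree_shape = tree_shape, seed = as.integer(seed)),
            class = "simulation_recipe")
}

#' Evolve a character matrix on a known tree
#'
#' Characters evolve independently: the root state is uniform, each branch
#' carries a Poisson(`rate`) number of change events, and each event moves
#' to a uniformly chosen different state. The realized number of changes is
#' returned, so tests can assert the parsimony bound (tree length on the
#' true tree never exceeds the true change count).
#'
#' @param recipe a [simulation_recipe()].
#' @return list `tree` ([ape::phylo]), `matrix` ([character_matrix()]),
#'   `true_changes` (total realized change events).
#' @export
simulate_matrix <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  tree <- simulate_tree(recipe$n_taxa, recipe$tree_shape, recipe$seed)
  idx <- .tree_index(tree)
  .with_seed(recipe$seed + 1L, {
    n_nodes <- idx$n_tip + idx$n_node
    cells <- matrix("", recipe$n_taxa, recipe$n_char)
    total <- 0L
    for (j in seq_len(recipe$n_char)) {
      st <- integer(n_nodes)
      st[idx$root] <- sample.int(recipe$n_states, 1L) - 1L
      for (u in idx$preorder) {
        for (v in idx$kids[[u]]) {
          s <- st[u]
          k <- stats::rpois(1L, recipe$rate)
          if (k > 0L) {
            for (i in seq_len(k)) {
              s <- sample(setdiff(seq_len(recipe$n_states) - 1L, s), 1L)
            }
            total <- total + k
          }
          st[v] <- s
        }
      }
      cells[, j] <- as.character(st[seq_len(recipe$n_taxa)])
    }
    rownames(cells) <- tree$tip.label
    list(tree = tree, matrix = character_matrix(cells), true_changes = total)
  })
}

#' Simulate a range history from an event script
#'
#' Propagates pixel ranges from the root to the tips applying one ideal
#' event per internal node: `vicariance` splits the range in two non-empty
#' disjoint parts, `sympatry` copies it to both children, `founder` copies
#' it to one child and gives the other a single fresh pixel outside it, and
#' `point_sympatry` copies it to one child and gives the other a single
#' pixel inside it. Every ideal event costs exactly its base cost, so the
#' true reconstruction cost of a noiseless history equals the number of
#' internal nodes under unit costs.
#'
#' @param tree rooted binary [ape::phylo].
#' @param events either a single event name recycled to all internal nodes
#'   or a character vector indexed by internal node number minus `Ntip`
#'   (element 1 = root). `"random"` picks uniformly per node.
#' @param root_range integer pixel vector for the root (see
#'   [pixel_encode()]); sizes above `z` are rejected.
#' @param z maximum ancestral range size.
#' @param seed integer seed.
#' @param noise per-tip probability of adding or dropping one pixel.
#' @return list `terminal_ranges`, `true_ranges` (internal), `true_events`,
#'   `true_cost` (under unit costs).
#' @export
simulate_range_history <- function(tree, events = "random",
                                   root_range = pixel_encode(0:3, 0L),
                                   z = 10L, seed = 1L, noise = 0) {
  idx <- .tree_index(tree)
  nt <- idx$n_tip
  if (length(root_range) > z) stop("root range exceeds Z", call. = FALSE)
  ev_names <- c("vicariance", "sympatry", "founder", "point_sympatry")
  if (length(events) == 1L && events != "random") {
    events <- rep(events, idx$n_node)
  }
  .with_seed(seed, {
    random_events <- identical(events, "random")
    if (random_events) events <- character(idx$n_node)
    stopifnot(length(events) == idx$n_node,
              random_events || all(events %in% ev_names))
    # minimum pixels a subtree needs so every scripted vicariance below it
    # stays splittable (vicariance consumes pixels; the other events copy)
    need <- rep(1L, nt + idx$n_node)
    if (!random_events) {
      for (v in idx$postorder) {
        kids <- idx$kids[[v]]
        need[v] <- switch(events[v - nt],
                          vicariance = need[kids[1L]] + need[kids[2L]],
                          sympatry = max(need[kids[1L]], need[kids[2L]]),
                          need[kids[1L]])   # founder/point keep child 1
      }
      if (length(root_range) < need[idx$root]) {
        stop("root range too small for the scripted vicariances (needs ",
             need[idx$root], " pixels)", call. = FALSE)
      }
    }
    ranges <- vector("list", nt + idx$n_node)
    ranges[[idx$root]] <- sort(unique(as.integer(root_range)))
    fresh <- max(ranges[[idx$root]])
    for (u in idx$preorder) {
      kids <- idx$kids[[u]]
      if (length(kids) != 2L) stop("tree must be binary", call. = FALSE)
      A <- ranges[[u]]
      if (random_events) {
        # vicariance is only feasible on a splittable range
        feasible <- if (length(A) >= 2L) ev_names else ev_names[-1L]
        events[u - nt] <- feasible[sample.int(length(feasible), 1L)]
      }
      ev <- events[u - nt]
      if (ev == "vicariance") {
        if (length(A) < 2L) {
          stop("vicariance requested on a single-pixel range at node ", u,
               call. = FALSE)
        }
        lo <- need[kids[1L]]
        hi <- length(A) - need[kids[2L]]
        if (hi < lo) {           # random script painted into a corner
          lo <- 1L
          hi <- length(A) - 1L
        }
        cut <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
        pick <- sample(A)
        d1 <- sort(pick[seq_len(cut)])
        d2 <- sort(pick[-seq_len(cut)])
      } else if (ev == "sympatry") {
        d1 <- A
        d2 <- A
      } else if (ev == "founder") {
        d1 <- A
        fresh <- fresh + 1L
        d2 <- fresh
      } else {
        d1 <- A
        d2 <- if (length(A) == 1L) A else sample(A, 1L)
      }
      ranges[[kids[1L]]] <- d1
      ranges[[kids[2L]]] <- d2
    }
    terminal <- ranges[seq_len(nt)]
    names(terminal) <- tree$tip.label
    if (noise > 0) {
      universe <- sort(unique(unlist(terminal)))
      for (i in seq_len(nt)) {
        if (stats::runif(1) < noise) {
          r <- terminal[[i]]
          if (stats::runif(1) < 0.5 && length(r) > 1L) {
            terminal[[i]] <- sort(sample(r, length(r) - 1L))
          } else {
            extra <- setdiff(universe, r)
            if (length(extra)) {
              terminal[[i]] <- sort(c(r, sample(extra, 1L)))
            }
          }
        }
      }
    }
    list(terminal_ranges = terminal,
         true_ranges = ranges[(nt + 1L):(nt + idx$n_node)],
         true_events = events,
         true_cost = idx$n_node)
  })
}

#' Plant a known number of changes of a categorical trait on a tree
#'
#' Chooses `n_changes` distinct branches and plants one state change on
#' each, every change introducing a state not seen on the path above it, so
#' the parsimony reconstruction of the resulting leaf states needs exactly
#' `n_changes` steps whenever the chosen branches are non-nested (and never
#' more than `n_changes` in general).
#'
#' @param tree rooted binary [ape::phylo].
#' @param n_states number of available states (>= 2).
#' @param n_changes changes to plant (at most the number of branches; with
#'   `distinct_targets = TRUE` also at most `n_states - 1`).
#' @param seed integer seed.
#' @param distinct_targets give every change its own new target state
#'   (guarantees recoverability on non-nested branches).
#' @return list `trait` ([trait_table()] with states `s0`, `s1`, ...),
#'   `placements` (data.frame `node`, `from`, `to`), `nested` (TRUE when
#'   any planted branch is an ancestor of another).
#' @export
simulate_trait <- function(tree, n_states, n_changes, seed = 1L,
                           distinct_targets = TRUE) {
  idx <- .tree_index(tree)
  nt <- idx$n_tip
  n_branches <- nrow(tree$edge)
  if (n_changes > n_branches) {
    stop("n_changes exceeds the number of branches", call. = FALSE)
  }
  if (distinct_targets && n_changes > n_states - 1L) {
    stop("need n_states > n_changes for distinct target states",
         call. = FALSE)
  }
  .with_seed(seed, {
    picked <- if (n_changes > 0L) {
      sort(sample(tree$edge[, 2L], n_changes))
    } else {
      integer(0)
    }
    st <- integer(nt + idx$n_node)
    st[idx$root] <- 0L
    next_target <- 1L
    placements <- list()
    for (u in idx$preorder) {
      for (v in idx$kids[[u]]) {
        s <- st[u]
        if (v %in% picked) {
          to <- if (distinct_targets) {
            t <- next_target
            next_target <- next_target + 1L
            t
          } else {
            sample(setdiff(seq_len(n_states) - 1L, s), 1L)
          }
          placements[[length(placements) + 1L]] <-
            data.frame(node = v, from = s, to = to)
          s <- to
        }
        st[v] <- s
      }
    }
    # interaction check: a change on an ancestor branch of another, or
    # changes covering every child branch of the root (which frees the
    # root state), can be reconstructed with fewer steps
    anc <- function(v) {
      out <- integer(0)
      while (idx$parent[v] != 0L) {
        v <- idx$parent[v]
        out <- c(out, v)
      }
      out
    }
    nested <- any(vapply(picked, function(v) any(anc(v) %in% picked), TRUE))
    if (length(picked) && all(idx$kids[[idx$root]] %in% picked)) {
      nested <- TRUE
    }
    states <- paste0("s", seq_len(n_states) - 1L)
    vals <- states[st[seq_len(nt)] + 1L]
    names(vals) <- tree$tip.label
    list(trait = trait_table("simulated", states, vals),
         placements = if (length(placements)) {
           do.call(rbind, placements)
         } else {
           data.frame(node = integer(0), from = integer(0), to = integer(0))
         },
         nested = nested)
  })
}
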