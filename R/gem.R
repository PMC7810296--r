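# Pixel ranges are sets of integer-encoded grid cells. The encoding packs
# (column, row) indices into one integer so set operations stay cheap.
.PX_OFF <- 20000L
.PX_MOD <- 40001L

#' Pixel grid for rasterizing occurrence records
#'
#' Cells are indexed by `floor(lon / pixel)` and `floor(lat / pixel)`; a
#' record on a cell boundary maps by floor. `fill = 1` puts each record in
#' its own cell only; larger fills expand every record to a `fill x fill`
#' block of cells around it.
#'
#' @param pixel cell size in decimal degrees.
#' @param fill neighbourhood width in cells.
#' @return a `raster_grid` list.
#' @export
raster_grid <- function(pixel = 1, fill = 1L) {
  stopifnot(pixel > 0, fill >= 1L)
  structure(list(pixel = pixel, fill = as.integer(fill)),
            class = "raster_grid")
}

#' Encode and decode grid-cell indices
#'
#' Pixel ranges are stored as integer codes packing the (column, row) cell
#' indices `floor(lon / pixel)` and `floor(lat / pixel)`.
#'
#' @param ix,iy integer cell indices.
#' @return `pixel_encode`: integer codes; `pixel_decode`: a two-column
#'   matrix of indices.
#' @export
pixel_encode <- function(ix, iy) {
  as.integer((ix + .PX_OFF) * .PX_MOD + (iy + .PX_OFF))
}

#' @rdname pixel_encode
#' @param code integer pixel codes.
#' @export
pixel_decode <- function(code) {
  ix <- code %/% .PX_MOD - .PX_OFF
  iy <- code %% .PX_MOD - .PX_OFF
  cbind(ix = ix, iy = iy)
}

#' Rasterize occurrence records to per-taxon pixel ranges
#'
#' @param records an `occurrence_table` (see [read_records()]).
#' @param grid a [raster_grid()].
#' @param taxa optional taxa that must all have at least one record (e.g.
#'   the leaves of the tree to be analysed).
#' @return named list: taxon -> sorted integer vector of occupied pixels.
#' @export
rasterize <- function(records, grid = raster_grid(), taxa = NULL) {
  ix <- as.integer(floor(records$lon / grid$pixel))
  iy <- as.integer(floor(records$lat / grid$pixel))
  if (grid$fill > 1L) {
    lo <- -((grid$fill - 1L) %/% 2L)
    offs <- expand.grid(dx = lo:(lo + grid$fill - 1L),
                        dy = lo:(lo + grid$fill - 1L))
    ix <- rep(ix, each = nrow(offs)) + offs$dx
    iy <- rep(iy, each = nrow(offs)) + offs$dy
    taxon <- rep(records$taxon, each = nrow(offs))
  } else {
    taxon <- records$taxon
  }
  ranges <- split(pixel_encode(ix, iy), taxon)
  ranges <- lapply(ranges, function(p) sort(unique(as.integer(p))))
  if (!is.null(taxa)) {
    taxa <- normalize_taxon(taxa)
    missing <- setdiff(taxa, names(ranges))
    if (length(missing)) {
      stop("no occurrence record for leaf: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ranges <- ranges[taxa]
  }
  ranges
}

#' Configuration of the geographically-explicit event model
#'
#' @param costs named event costs (`vicariance`, `sympatry`,
#'   `point_sympatry`, `founder`), all 1 by default.
#' @param z maximum ancestral range size in pixels (hard cap by default).
#' @param soft_z when `TRUE`, ranges larger than `z` are admissible at a
#'   penalty of one step per extra pixel instead of being forbidden.
#' @param runs independent runs of the flipping search.
#' @param replicates restarts per run.
#' @param seed integer seed.
#' @param slack also report reconstructions within `slack` of the best cost.
#' @param change_mode how range changes along branches enter the score:
#'   `"embodied"` (default; the per-event formulas already count gained and
#'   lost pixels) or `"separate"` (events cost only their base cost and the
#'   symmetric difference between each node range and its two child ranges
#'   is added as an explicit branch-change term).
#' @return a `gem_config` list.
#' @export
gem_config <- function(costs = c(vicariance = 1, sympatry = 1,
                                 point_sympatry = 1, founder = 1),
                       z = 10L, soft_z = FALSE, runs = 10L,
                       replicates = 10000L, seed = 1L, slack = 0L,
                       change_mode = c("embodied", "separate")) {
  change_mode <- match.arg(change_mode)
  need <- c("vicariance", "sympatry", "point_sympatry", "founder")
  if (!all(need %in% names(costs))) {
    stop("costs must name all four events", call. = FALSE)
  }
  stopifnot(all(costs >= 0), z >= 1L, runs >= 1L, replicates >= 1L,
            slack >= 0L)
  structure(list(costs = costs[need], z = as.integer(z), soft_z = soft_z,
                 runs = as.integer(runs), replicates = as.integer(replicates),
                 seed = as.integer(seed), slack = as.integer(slack),
                 change_mode = change_mode),
            class = "gem_config")
}

.set_int <- function(a, b) a[a %in% b]
.set_diff <- function(a, b) a[!(a %in% b)]
.sym_diff_n <- function(a, b) length(a) + length(b) - 2L * sum(a %in% b)

#' Cost of assigning one event to a node
#'
#' Implements the four assignment rules of the event model. `A` is the
#' ancestral (node) range, `D1` and `D2` the two descendant ranges. For the
#' asymmetric events (`founder`, `point_sympatry`) the descendant named
#' second plays the founder/point role; [node_assignment()] evaluates both
#' orientations and keeps the cheaper.
#'
#' * vicariance: descendant overlap + pixels gained or lost between `A` and
#'   `D1 U D2` + base cost (an ideal range split costs exactly the base).
#' * sympatry: pixels gained or lost by each descendant relative to `A` +
#'   base cost.
#' * point sympatry (`D2` the point): `|D1 n D2| - 1` (or a one-step penalty
#'   when the descendants do not overlap) + descendant pixels outside `A` +
#'   ancestral pixels lost by `D1` + base cost.
#' * founder (`D2` the founder): `|D2| - 1` + founder pixels inside `A` +
#'   pixels gained or lost between `A` and `D1` + base cost.
#'
#' @param event one of `"vicariance"`, `"sympatry"`, `"point_sympatry"`,
#'   `"founder"`.
#' @param A,D1,D2 integer pixel vectors; descendants must be non-empty.
#' @param config a [gem_config()].
#' @return numeric cost.
#' @export
event_cost <- function(event, A, D1, D2, config = gem_config()) {
  if (!length(D1) || !length(D2)) {
    stop("descendant range is empty", call. = FALSE)
  }
  base <- config$costs[[event]]
  if (config$change_mode == "separate") {
    return(base + .sym_diff_n(A, D1) + .sym_diff_n(A, D2))
  }
  U <- unique(c(D1, D2))
  switch(event,
    vicariance = length(.set_int(D1, D2)) + .sym_diff_n(A, U) + base,
    sympatry = .sym_diff_n(A, D1) + .sym_diff_n(A, D2) + base,
    point_sympatry = {
      ov <- length(.set_int(D1, D2))
      (if (ov >= 1L) ov - 1L else 1L) +
        length(.set_diff(U, A)) + length(.set_diff(A, D1)) + base
    },
    founder = {
      (length(D2) - 1L) + length(.set_int(D2, A)) + .sym_diff_n(A, D1) + base
    },
    stop("unknown event: ", event, call. = FALSE))
}

.EVENTS <- c("vicariance", "sympatry", "founder", "point_sympatry")

#' Cheapest event for a node
#'
#' Evaluates all four events (both descendant orientations for the
#' asymmetric ones) and returns the argmin; ties are broken in the order
#' vicariance, sympatry, founder, point sympatry.
#'
#' @inheritParams event_cost
#' @return list `event`, `cost`, `orientation` (1 if `D2` plays the
#'   founder/point role, 2 if `D1` does, `NA` for symmetric events).
#' @export
node_assignment <- function(A, D1, D2, config = gem_config()) {
  over_z <- length(A) - config$z
  zpen <- 0
  if (over_z > 0L) {
    if (!config$soft_z) {
      stop("ancestral range exceeds Z = ", config$z, call. = FALSE)
    }
    zpen <- over_z
  }
  best <- NULL
  for (ev in .EVENTS) {
    if (ev %in% c("founder", "point_sympatry")) {
      c1 <- event_cost(ev, A, D1, D2, config)
      c2 <- event_cost(ev, A, D2, D1, config)
      cost <- min(c1, c2)
      orient <- if (c1 <= c2) 1L else 2L
    } else {
      cost <- event_cost(ev, A, D1, D2, config)
      orient <- NA_integer_
    }
    if (is.null(best) || cost < best$cost) {
      best <- list(event = ev, cost = cost, orientation = orient)
    }
  }
  best$cost <- best$cost + zpen
  best
}

# internal-node candidate range check
.range_ok <- function(r, config) {
  length(r) >= 1L && (config$soft_z || length(r) <= config$z)
}

#' Score a full reconstruction
#'
#' Given ranges for every internal node, assigns each node its cheapest
#' event and totals the cost.
#'
#' @param tree rooted binary [ape::phylo].
#' @param terminal_ranges named list of pixel vectors for every leaf.
#' @param internal_ranges list of pixel vectors indexed by internal node id
#'   minus `Ntip` (i.e. element 1 is the root).
#' @param config a [gem_config()].
#' @return a `gem_reconstruction`: `total_cost`, `events` (data.frame with
#'   `node`, `event`, `cost`, `orientation`, `range_size`), `census` (named
#'   counts per event type), `ranges`.
#' @export
reconstruction_cost <- function(tree, terminal_ranges, internal_ranges,
                                config = gem_config()) {
  idx <- .tree_index(tree)
  nt <- idx$n_tip
  get_range <- function(v) {
    if (v <= nt) terminal_ranges[[tree$tip.label[v]]] else
      internal_ranges[[v - nt]]
  }
  nodes <- idx$postorder
  rows <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    kids <- idx$kids[[v]]
    if (length(kids) != 2L) {
      stop("event assignment requires a binary tree", call. = FALSE)
    }
    A <- get_range(v)
    if (!.range_ok(A, config)) {
      stop("internal node ", v, " has an inadmissible range (empty or > Z)",
           call. = FALSE)
    }
    asg <- node_assignment(A, get_range(kids[1L]), get_range(kids[2L]),
                           config)
    rows[[i]] <- data.frame(node = v, event = asg$event, cost = asg$cost,
                            orientation = asg$orientation,
                            range_size = length(A))
  }
  events <- do.call(rbind, rows)
  census <- vapply(.EVENTS, function(e) sum(events$event == e), 0L)
  structure(list(total_cost = sum(events$cost), events = events,
                 census = census, ranges = internal_ranges, tree = tree),
            class = "gem_reconstruction")
}

#' @export
print.gem_reconstruction <- function(x, ...) {
  cat(sprintf("event reconstruction: cost %g; %s\n", x$total_cost,
              paste(sprintf("%d %s", x$census, names(x$census)),
                    collapse = ", ")))
  invisible(x)
}

# initial internal ranges for one restart (children-driven heuristics)
.gem_init <- function(tree, terminal_ranges, config, universe) {
  idx <- .tree_index(tree)
  nt <- idx$n_tip
  ranges <- vector("list", idx$n_node)
  get_range <- function(v) {
    if (v <= nt) terminal_ranges[[tree$tip.label[v]]] else ranges[[v - nt]]
  }
  for (v in idx$postorder) {
    kids <- idx$kids[[v]]
    r1 <- get_range(kids[1L])
    r2 <- get_range(kids[2L])
    u <- unique(c(r1, r2))
    r <- switch(sample.int(3L, 1L),
                {
                  i <- .set_int(r1, r2)
                  if (length(i)) i else u
                },
                u[sample.int(length(u),
                             sample.int(min(length(u), config$z), 1L))],
                if (stats::runif(1) < 0.5) r1 else r2)
    if (length(r) > config$z) r <- sort(sample(r, config$z))
    ranges[[v - nt]] <- sort(unique(r))
  }
  ranges
}

#' Minimize reconstruction cost by a flipping search
#'
#' Restarted local search: each replicate initializes every internal range
#' from its children (intersection, truncated union, or a copied child,
#' chosen at random), then repeatedly flips single-pixel membership at
#' single internal nodes, accepting strict improvements, until no flip
#' helps. All distinct reconstructions at the best cost found (plus those
#' within `config$slack`) are returned.
#'
#' @param tree rooted binary [ape::phylo].
#' @param terminal_ranges named list of pixel vectors for every leaf.
#' @param config a [gem_config()]; `runs * replicates` restarts are
#'   performed.
#' @return list with `best_cost`, `reconstructions` (list of
#'   `gem_reconstruction` at `best_cost`), `within_slack` (including those
#'   up to `best_cost + slack`).
#' @export
flip_search <- function(tree, terminal_ranges, config = gem_config()) {
  idx <- .tree_index(tree)
  nt <- idx$n_tip
  missing <- setdiff(tree$tip.label, names(terminal_ranges))
  if (length(missing)) {
    stop("no range for leaf: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  universe <- sort(unique(unlist(terminal_ranges[tree$tip.label])))
  internal <- (nt + 1L):(nt + idx$n_node)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  node_cost <- function(ranges, v) {
    kids <- idx$kids[[v]]
    gr <- function(w) {
      if (w <= nt) terminal_ranges[[tree$tip.label[w]]] else ranges[[w - nt]]
    }
    node_assignment(ranges[[v - nt]], gr(kids[1L]), gr(kids[2L]), config)$cost
  }
  total_cost <- function(ranges) sum(vapply(internal, node_cost, 0,
                                            ranges = ranges))

  pool <- list()
  best <- Inf
  n_restart <- config$runs * config$replicates
  for (rep_i in seq_len(n_restart)) {
    ranges <- .gem_init(tree, terminal_ranges, config, universe)
    per_node <- vapply(internal, node_cost, 0, ranges = ranges)
    names(per_node) <- internal
    cur <- sum(per_node)
    repeat {
      improved <- FALSE
      for (v in internal[sample.int(length(internal))]) {
        for (p in universe) {
          r <- ranges[[v - nt]]
          r2 <- if (p %in% r) r[r != p] else sort(c(r, p))
          if (!.range_ok(r2, config)) next
          touched <- c(v, idx$parent[v])
          touched <- touched[touched > nt & touched != 0L]
          old <- sum(per_node[as.character(touched)])
          ranges[[v - nt]] <- r2
          newv <- vapply(touched, node_cost, 0, ranges = ranges)
          if (sum(newv) < old) {
            per_node[as.character(touched)] <- newv
            cur <- cur - old + sum(newv)
            improved <- TRUE
          } else {
            ranges[[v - nt]] <- r
          }
        }
      }
      if (!improved) break
    }
    if (cur <= best + config$slack) {
      key <- paste(vapply(ranges, paste, "", collapse = ","), collapse = ";")
      if (is.null(pool[[key]])) {
        pool[[key]] <- list(ranges = ranges, cost = cur)
      }
      if (cur < best) {
        best <- cur
        keep <- vapply(pool, `[[`, 0, "cost") <= best + config$slack
        pool <- pool[keep]
      }
    }
  }
  recs <- lapply(pool, function(p) {
    reconstruction_cost(tree, terminal_ranges, p$ranges, config)
  })
  costs <- vapply(recs, `[[`, 0, "total_cost")
  recs <- recs[order(costs)]
  costs <- sort(costs)
  list(best_cost = best,
       reconstructions = unname(recs[costs == best]),
       within_slack = unname(recs))
}

#' Permutation test for phylogenetic structure in the ranges
#'
#' Shuffles the taxon-to-range mapping and re-runs the flipping search at
#' reduced effort for each permutation. A real phylogeny/geography signal
#' shows as an observed cost below the permuted distribution.
#'
#' @param tree rooted binary [ape::phylo].
#' @param terminal_ranges named list of pixel vectors.
#' @param config a [gem_config()].
#' @param n_perm number of permutations.
#' @param perm_effort restarts used per permutation (and for the observed
#'   cost).
#' @return list `observed`, `permuted` (numeric vector of length `n_perm`).
#' @export
permutation_test <- function(tree, terminal_ranges, config = gem_config(),
                             n_perm = 10L, perm_effort = 50L) {
  stopifnot(n_perm >= 1L)
  small <- config
  small$runs <- 1L
  small$replicates <- as.integer(perm_effort)
  observed <- flip_search(tree, terminal_ranges, small)$best_cost
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed + 1L)
  permuted <- vapply(seq_len(n_perm), function(i) {
    shuffled <- terminal_ranges
    names(shuffled) <- sample(names(terminal_ranges))
    cfg <- small
    cfg$seed <- config$seed + i
    flip_search(tree, shuffled, cfg)$best_cost
  }, 0)
  list(observed = observed, permuted = permuted)
}

#' Export the event table of a reconstruction as TSV
#'
#' @param x a `gem_reconstruction`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gem_events <- function(x, path) {
  ev <- x$events
  ev$range <- vapply(ev$node, function(v) {
    nt <- length(x$tree$tip.label)
    px <- pixel_decode(x$ranges[[v - nt]])
    paste(sprintf("(%d,%d)", px[, 1L], px[, 2L]), collapse = " ")
  }, "")
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
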