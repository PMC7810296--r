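#' Configure an end-to-end analysis run
#'
#' Bundles the inputs of the three stages: parsimony search (matrix +
#' outgroup), trait reconstruction (trait tables + the topology to paint
#' them on) and the event-model biogeography (occurrence records + grid).
#' Every element can be an in-memory object or a path to the matching
#' on-disk format.
#'
#' @param matrix a [character_matrix()] or path to a TSV matrix.
#' @param outgroup taxon used to root reported trees.
#' @param search a [search_config()].
#' @param gem a [gem_config()].
#' @param grid a [raster_grid()].
#' @param traits list of [trait_table()] objects (or paths).
#' @param records an `occurrence_table` (or path); `NULL` skips the
#'   biogeography stage.
#' @param asr_tree fixed topology for trait reconstruction and the event
#'   model (or path to a Newick file); default: the first best tree found
#'   by the search, restricted to the taxa with trait states / records.
#' @param clades named list of character vectors: clades to report Bremer
#'   support and stem synapomorphies for.
#' @param n_perm permutations for the biogeography permutation test
#'   (0 skips it).
#' @param out_dir output directory (created if needed); `NULL` writes no
#'   files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(matrix, outgroup, search = search_config(),
                            gem = gem_config(), grid = raster_grid(),
                            traits = list(), records = NULL,
                            asr_tree = NULL, clades = list(), n_perm = 0L,
                            out_dir = NULL) {
  if (is.character(matrix)) matrix <- read_matrix(matrix)
  traits <- lapply(traits, function(t) {
    if (is.character(t)) read_trait_table(t) else t
  })
  if (is.character(records)) records <- read_records(records)
  if (is.character(asr_tree)) asr_tree <- read_newick(asr_tree)
  structure(list(matrix = matrix, outgroup = normalize_taxon(outgroup),
                 search = search, gem = gem, grid = grid, traits = traits,
                 records = records, asr_tree = asr_tree, clades = clades,
                 n_perm = as.integer(n_perm), out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes search, strict consensus, Bremer support, synapomorphy
#' classification, trait ancestral-state reconstruction, the event-model
#' range reconstruction and its permutation test, and collects every
#' headline quantity into a flat summary. Reruns with the same
#' configuration (seeds included) produce identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: `summary` (flat named list),
#'   `trees` (tree_set), `consensus`, `scores`, `traits` (list of
#'   reconstructions), `gem` (flip-search result or `NULL`),
#'   `permutation` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  summary <- list()
  ts <- .stage("search", heuristic_search(config$matrix, config$search,
                                          config$outgroup))
  summary$best_length <- as.integer(ts$best_length)
  summary$n_mpt <- length(ts$trees)
  cons <- .stage("consensus", strict_consensus(ts))
  first <- ts$trees[[1L]]
  scores <- .stage("scores", fitch_length(first, config$matrix))
  summary$ci <- round(scores$ci, 2)
  summary$ri <- round(scores$ri, 2)
  recon <- .stage("optimization",
                  optimize_states(first, config$matrix, scores = scores))
  for (nm in names(config$clades)) {
    clade <- config$clades[[nm]]
    summary[[paste0("bremer_", nm)]] <-
      .stage(paste0("bremer:", nm),
             bremer_support(config$matrix, ts, clade, config$search))
    syn <- .stage(paste0("synapomorphies:", nm),
                  classify_synapomorphies(first, config$matrix, recon, clade))
    summary[[paste0("exclusive_", nm)]] <- nrow(syn$exclusive)
    summary[[paste0("homoplastic_", nm)]] <- nrow(syn$homoplastic)
  }
  asr_tree <- config$asr_tree
  trait_res <- list()
  for (tr in config$traits) {
    base <- if (is.null(asr_tree)) first else asr_tree
    keep <- intersect(base$tip.label, names(tr$index))
    sub <- if (length(keep) < length(base$tip.label)) {
      ape::keep.tip(base, keep)
    } else {
      base
    }
    res <- .stage(paste0("asr:", tr$trait), reconstruct_trait(sub, tr))
    trait_res[[tr$trait]] <- res
    summary[[paste0("steps_", tr$trait)]] <- res$steps
    summary[[paste0("root_", tr$trait)]] <-
      paste(res$root_states, collapse = "|")
  }
  gem_res <- NULL
  perm <- NULL
  if (!is.null(config$records)) {
    gtree <- if (is.null(asr_tree)) first else asr_tree
    ranges <- .stage("rasterize",
                     rasterize(config$records, config$grid,
                               taxa = gtree$tip.label))
    gem_res <- .stage("gem", flip_search(gtree, ranges, config$gem))
    best <- gem_res$reconstructions[[1L]]
    summary$gem_cost <- gem_res$best_cost
    for (ev in names(best$census)) {
      summary[[paste0("gem_", ev)]] <- unname(best$census[[ev]])
    }
    if (config$n_perm > 0L) {
      perm <- .stage("permutation",
                     permutation_test(gtree, ranges, config$gem,
                                      n_perm = config$n_perm))
      summary$gem_perm_observed <- perm$observed
      summary$gem_perm_median <- stats::median(perm$permuted)
    }
  }
  report <- structure(list(summary = summary, trees = ts, consensus = cons,
                           scores = scores, reconstruction = recon,
                           traits = trait_res, gem = gem_res,
                           permutation = perm),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(vapply(ts$trees, write_newick, ""),
               file.path(config$out_dir, "trees.nwk"))
    writeLines(write_newick(cons), file.path(config$out_dir,
                                             "consensus.nwk"))
    write_changes(recon, scores, file.path(config$out_dir, "changes.tsv"))
    write_summary(report, file.path(config$out_dir, "summary.txt"))
  }
  report
}

#' Write the flat machine-readable summary of a run
#'
#' One `key<TAB>value` line per quantity, in a stable order.
#'
#' @param report a [run_pipeline()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(report, path) {
  s <- report$summary
  writeLines(paste0(names(s), "\t",
                    vapply(s, function(v) paste(format(v), collapse = ","),
                           "")),
             path)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x$summary[[nm]], collapse = ",")))
  }
  invisible(x)
}
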