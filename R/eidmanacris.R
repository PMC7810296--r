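# Bundled case-study data: ecological trait states for the 28 species of
# the Neotropical cricket genus Eidmanacris (habitat, body-size class,
# extent of the bristle field on the male metanotal gland), together with a
# working ingroup topology. The topology file is labelled synthetic: it was
# reconstructed from the published clade structure (clade membership table
# plus the clade relationships described in the results), not taken from a
# machine-readable tree file, and is the stand-in used by the tests.

#' Eidmanacris trait tables
#'
#' Habitat (straminicolous `str`, mixed `str/cav`, cavicolous `cav`),
#' body-size class (six 3 mm classes, see [classify_size()]) and metanotal
#' bristle extent (`anterior` vs `entire`) for the 28 ingroup species,
#' with the clade and biome columns carried as metadata.
#'
#' @return list with elements `habitat`, `size`, `bristles` (each a
#'   [trait_table()]) and `table` (the underlying data.frame, including
#'   biome occupancy and clade labels).
#' @export
eidmanacris_traits <- function() {
  path <- system.file("extdata", "table1_traits.tsv", package = "phylogem")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  mk <- function(col, name, states) {
    vals <- as.character(tab[[col]])
    names(vals) <- tab$species
    trait_table(name, states, vals)
  }
  list(habitat = mk("habitat", "habitat", c("str", "str/cav", "cav")),
       size = mk("size_class", "size", as.character(0:5)),
       bristles = mk("bristles", "bristles", c("anterior", "entire")),
       table = tab)
}

#' Eidmanacris ingroup topology (synthetic stand-in)
#'
#' The 28-species ingroup topology reconstructed from the published clade
#' structure. It reproduces the published ancestral-state step counts and
#' is the fixed tree used for trait reconstruction examples and tests; it
#' is not the original analysis output file.
#'
#' @return an [ape::phylo] rooted binary tree with 28 leaves.
#' @export
eidmanacris_tree <- function() {
  read_newick(system.file("extdata",
                          "eidmanacris_ingroup_topology_synthetic.nwk",
                          package = "phylogem"))
}

#' Eidmanacris clade memberships
#'
#' Leaf sets of the named clades (A, C, E, G, I, K, M, N1, N2 from the
#' membership table, plus the composite clades N = N1 + N2 and
#' B = everything outside A).
#'
#' @return named list of character vectors.
#' @export
eidmanacris_clades <- function() {
  tab <- eidmanacris_traits()$table
  out <- split(tab$species, tab$clade)
  out$N <- c(out$N1, out$N2)
  out$B <- setdiff(tab$species, out$A)
  out$Eidmanacris <- tab$species
  out
}
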