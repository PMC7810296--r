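test_that("TSV matrix reading maps tokens and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t010", "B\t0?-"), path)
  m <- read_matrix(path, "tsv")
  expect_equal(m$taxa, c("A", "B"))
  expect_equal(m$n_char, 3L)
  expect_equal(unname(m$cells["B", 2L]), "?")
  expect_equal(unname(m$cells["B", 3L]), "-")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, out)
  m2 <- read_matrix(out, "tsv")
  expect_identical(m$cells, m2$cells)
  # byte-identical canonical round trip
  write_matrix(m2, path)
  expect_identical(readLines(path), readLines(out))
})

test_that("matrix validation rejects malformed input with named offenders", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t010", "B\t01"), path)
  expect_error(read_matrix(path), "B")
  writeLines(c("A\t01x", "B\t010"), path)
  expect_error(read_matrix(path), "character 3")
  writeLines(c("A\t0?-", "B\t0--"), path)   # char 2 has no observed state
  expect_error(read_matrix(path), "character 2")
  expect_error(character_matrix(rbind(A = "0", A = "1")), "duplicate")
})

test_that("TNT and NEXUS dialects agree with the TSV reading", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Taxon_a\t0101", "Taxon_b\t01?1", "Taxon_c\t1110"), tsv)
  ref <- read_matrix(tsv)

  tnt <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c("xread", "'a tiny matrix'", "4 3", "Taxon_a 0101",
               "Taxon_b 01?1", "Taxon_c 1110", ";"), tnt)
  expect_identical(read_matrix(tnt, "tnt")$cells, ref$cells)

  nex <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN CHARACTERS;",
               "DIMENSIONS NTAX=3 NCHAR=4;", "MATRIX",
               "Taxon_a 0101", "Taxon_b 01?1", "Taxon_c 1110", ";",
               "END;"), nex)
  expect_identical(read_matrix(nex, "nexus")$cells, ref$cells)

  # TNT round trip through write_matrix
  out <- withr::local_tempfile(fileext = ".tnt")
  write_matrix(ref, out, "tnt")
  expect_identical(read_matrix(out, "tnt")$cells, ref$cells)
})

test_that("taxon names are normalized uniformly at read time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Genus species\t01", path)
  expect_equal(read_matrix(path)$taxa, "Genus_species")
  phy <- read_newick_text("((Genus species,b),c);")
  expect_true("Genus_species" %in% phy$tip.label)
})

test_that("Newick reading round-trips and reports parse errors", {
  phy <- read_newick_text("((a,b),(c,d));")
  expect_equal(sort(phy$tip.label), c("a", "b", "c", "d"))
  expect_equal(phy$Nnode, 3L)

  txt <- write_newick(phy)
  phy2 <- read_newick_text(txt)
  expect_setequal(phylogem:::bipartition_keys(phy),
                  phylogem:::bipartition_keys(phy2))

  expect_error(read_newick_text("((a,b),(c,d);"), "unbalanced")
})

test_that("the trees tab dialect reads one Newick per line, skipping comments", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("# comment", "((a,b),c);", "((a,c),b);"), path)
  trees <- read_gem_trees(path)
  expect_length(trees, 2L)
  expect_equal(sort(trees[[2L]]$tip.label), c("a", "b", "c"))
})

test_that("record reading validates coordinates and keeps duplicates", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("E_caipira  -47.5  -22.4", "E_caipira\t-47.5\t-22.4",
               "# note", "E_gigas -48.1 -21.0"), path)
  rec <- read_records(path)
  expect_equal(nrow(rec), 3L)           # duplicates retained here
  expect_equal(sum(rec$taxon == "E_caipira"), 2L)

  writeLines("E_x -47.5 -95.0", path)
  expect_error(read_records(path), "latitude")
  writeLines("E_x -200 -20", path)
  expect_error(read_records(path), "longitude")
  expect_error(occurrence_table(c("a", ""), c(0, 0), c(0, 0)), "empty taxon")
})

test_that("trait tables read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#trait habitat", "#states str str/cav cav",
               "sp1\tstr", "sp2\tcav"), path)
  tt <- read_trait_table(path)
  expect_equal(tt$trait, "habitat")
  expect_equal(unname(tt$index[c("sp1", "sp2")]), c(1L, 3L))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(tt, out)
  expect_equal(read_trait_table(out)$index, tt$index)

  writeLines(c("#trait h", "#states a b", "sp1\tc"), path)
  expect_error(read_trait_table(path), "declared set")
  writeLines(character(0), path)
  expect_error(read_trait_table(path), "empty")
})

test_that("bundled case-study tables have the published shape", {
  tt <- eidmanacris_traits()
  expect_length(tt$habitat$index, 28L)
  expect_equal(tt$habitat$states, c("str", "str/cav", "cav"))
  expect_equal(tt$bristles$states, c("anterior", "entire"))
  cl <- eidmanacris_clades()
  # every species of clade N carries the entire-metanotum state
  expect_true(all(tt$bristles$index[cl$N] == 2L))
  tree <- eidmanacris_tree()
  expect_equal(length(tree$tip.label), 28L)
  expect_true(ape::is.binary(tree))
  expect_setequal(tree$tip.label, names(tt$habitat$index))
})
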