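signal_matrix <- function() {
  cells <- rbind(a = c("0", "0"), b = c("0", "0"),
                 c = c("1", "1"), d = c("1", "1"))
  character_matrix(cells)
}

test_that("a 4-taxon matrix with signal yields its unique best tree", {
  m <- signal_matrix()
  ts <- heuristic_search(m, search_config(n_replicates = 3L, seed = 11L),
                         outgroup = "a")
  expect_equal(ts$best_length, 2)
  expect_length(ts$trees, 1L)
  expect_true(has_clade(ts$trees[[1L]], c("c", "d")))
  # exhaustive 3-topology check: no unrooted 4-taxon tree is shorter
  lens <- vapply(oracle_all_topologies(m$taxa), function(nwk) {
    fitch_length(read_newick_text(nwk), m)$total_length
  }, 0)
  expect_equal(min(lens), 2)
  expect_equal(sum(lens == 2), 1L)
})

test_that("heuristic search matches exhaustive enumeration on small matrices", {
  for (seed in 101:112) {
    case <- random_case(seed, n_taxa = sample(5:6, 1L))
    best_exh <- min(vapply(oracle_all_topologies(case$matrix$taxa),
                           function(nwk) {
                             fitch_length(read_newick_text(nwk),
                                          case$matrix)$total_length
                           }, 0))
    ts <- heuristic_search(case$matrix,
                           search_config(n_replicates = 4L, seed = seed),
                           outgroup = case$matrix$taxa[1L])
    expect_equal(ts$best_length, best_exh, info = paste("seed", seed))
  }
})

test_that("search effort never worsens the result under nested seeds", {
  case <- random_case(200L, n_taxa = 7L, n_char = 6L)
  lens <- vapply(c(1L, 3L, 6L), function(r) {
    heuristic_search(case$matrix, search_config(n_replicates = r, seed = 5L),
                     outgroup = case$matrix$taxa[1L])$best_length
  }, 0)
  expect_true(all(diff(lens) <= 0))
  # determinism: same seed, same result
  a <- heuristic_search(case$matrix, search_config(n_replicates = 2L,
                                                   seed = 9L),
                        outgroup = case$matrix$taxa[1L])
  b <- heuristic_search(case$matrix, search_config(n_replicates = 2L,
                                                   seed = 9L),
                        outgroup = case$matrix$taxa[1L])
  expect_identical(lapply(a$trees, write_newick),
                   lapply(b$trees, write_newick))
})

test_that("all three swappers find the optimum on an easy matrix", {
  case <- random_case(300L, n_taxa = 6L, n_char = 8L, n_states = 2L)
  best <- min(vapply(oracle_all_topologies(case$matrix$taxa),
                     function(nwk) {
                       fitch_length(read_newick_text(nwk),
                                    case$matrix)$total_length
                     }, 0))
  for (sw in c("TBR", "SPR", "NNI")) {
    ts <- heuristic_search(case$matrix,
                           search_config(n_replicates = 6L, seed = 2L,
                                         swapper = sw),
                           outgroup = case$matrix$taxa[1L])
    expect_equal(ts$best_length, best, info = sw)
  }
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- read_newick_text("(o,((a,b),(c,d)));")
  expect_equal(sort(clade_keys <- phylogem:::clade_keys(
    strict_consensus(list(t1, t1)))),
    sort(phylogem:::clade_keys(t1)))
  # conflicting resolutions collapse to a star
  t2 <- read_newick_text("(o,((a,c),(b,d)));")
  cons <- strict_consensus(list(t1, t2))
  expect_equal(phylogem:::clade_keys(cons),
               paste(sort(c("a", "b", "c", "d")), collapse = "|"))
  # idempotent and order-independent
  expect_equal(write_newick(strict_consensus(list(t2, t1))),
               write_newick(cons))
  expect_equal(write_newick(strict_consensus(list(cons))),
               write_newick(cons))
  expect_error(strict_consensus(list(t1, read_newick_text("((a,b),(c,x));"))),
               "mismatched")
})

test_that("Bremer support matches its definition on toy matrices", {
  # one uncontradicted character supporting (c,d): decay 1
  cells <- rbind(o = "0", a = "0", b = "0", c = "1", d = "1")
  m <- character_matrix(cells)
  cfg <- search_config(n_replicates = 4L, seed = 3L)
  ts <- heuristic_search(m, cfg, outgroup = "o")
  expect_equal(bremer_support(m, ts, c("c", "d"), cfg), 1L)

  # two characters supporting (c,d): decay 2
  m2 <- character_matrix(cbind(cells, cells))
  ts2 <- heuristic_search(m2, cfg, outgroup = "o")
  expect_equal(bremer_support(m2, ts2, c("c", "d"), cfg), 2L)

  # a clade absent from the consensus is rejected
  expect_error(bremer_support(m, ts, c("b", "c"), cfg), "consensus")
})

test_that("a clade contradicted at equal parsimony decays to zero", {
  # character 1 supports (c,d), character 2 supports (b,d) equally: both
  # resolutions are most parsimonious, so the decay of (c,d) is 0 and the
  # strict consensus collapses the conflict to a polytomy
  cells <- rbind(o = c("0", "0"), a = c("0", "0"),
                 b = c("0", "1"), c = c("1", "0"), d = c("1", "1"))
  m <- character_matrix(cells)
  cfg <- search_config(n_replicates = 6L, seed = 13L)
  ts <- heuristic_search(m, cfg, outgroup = "o")
  converse <- heuristic_search(m, cfg, outgroup = "o",
                               constraint = c("c", "d"), converse = TRUE)
  expect_equal(converse$best_length - ts$best_length, 0)
  cons <- strict_consensus(ts)
  expect_false(!is.na(phylogem:::find_clade_node(cons, c("c", "d"))))
})

test_that("collapse rules control reported resolution", {
  # b carries no character evidence: the (b,(c,d)) resolution is arbitrary
  cells <- rbind(o = "0", a = "0", b = "?", c = "1", d = "1")
  m <- character_matrix(cells)
  ts_none <- heuristic_search(m, search_config(n_replicates = 4L, seed = 1L,
                                               collapse = "none"),
                              outgroup = "o")
  ts_def <- heuristic_search(m, search_config(n_replicates = 4L, seed = 1L),
                             outgroup = "o")
  # the default rule reports no more distinct topologies than "none"
  expect_lte(length(ts_def$trees), length(ts_none$trees))
  expect_equal(ts_def$best_length, ts_none$best_length)
})
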