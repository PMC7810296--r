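four_taxon <- function(states) {
  cells <- matrix(states, ncol = 1L)
  rownames(cells) <- c("a", "b", "c", "d")
  character_matrix(cells)
}

test_that("tree length matches hand-derived small cases", {
  m <- four_taxon(c("0", "0", "1", "1"))
  expect_equal(fitch_length(read_newick_text("((a,b),(c,d));"),
                            m)$total_length, 1)
  expect_equal(fitch_length(read_newick_text("((a,c),(b,d));"),
                            m)$total_length, 2)
  # constant character: no steps
  expect_equal(fitch_length(read_newick_text("((a,b),(c,d));"),
                            four_taxon(rep("0", 4L)))$total_length, 0)
  # missing leaf is a join error naming the leaf
  expect_error(fitch_length(read_newick_text("((a,b),(c,x));"), m), "x")
})

test_that("tree length equals brute-force enumeration on random cases", {
  for (seed in 1:40) {
    case <- random_case(seed)
    got <- fitch_length(case$tree, case$matrix)$total_length
    want <- oracle_matrix_length(case$tree, case$matrix,
                                 states = 0:(case$n_states - 1L))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("length agrees with phangorn and is invariant under rerooting", {
  skip_if_not_installed("phangorn")
  for (seed in 41:50) {
    case <- random_case(seed)
    pd <- phangorn::phyDat(case$matrix$cells, type = "USER",
                           levels = as.character(0:(case$n_states - 1L)))
    expect_equal(fitch_length(case$tree, case$matrix)$total_length,
                 phangorn::parsimony(case$tree, pd, method = "sankoff"),
                 info = paste("seed", seed))
    rerooted <- ape::root(ape::unroot(case$tree),
                          outgroup = case$tree$tip.label[2L],
                          resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, case$matrix)$total_length,
                 fitch_length(case$tree, case$matrix)$total_length)
  }
})

test_that("per-character min and max follow the star-tree definitions", {
  cells <- rbind(a = c("0", "0", "0", "0"), b = c("0", "1", "0", "?"),
                 c = c("1", "1", "0", "1"), d = c("1", "1", "0", "1"),
                 e = c("1", "2", "0", "1"))
  m <- character_matrix(cells)
  expect_equal(unname(char_min_max(m, 1L)), c(1L, 2L))  # 0,0,1,1,1
  expect_equal(unname(char_min_max(m, 2L)), c(2L, 2L))  # 0,1,1,1,2
  expect_equal(unname(char_min_max(m, 3L)), c(0L, 0L))  # constant
  expect_equal(unname(char_min_max(m, 4L)), c(1L, 1L))  # autapomorphy, ? skipped
})

test_that("ensemble ci and ri behave as homoplasy measures", {
  t4 <- read_newick_text("((a,b),(c,d));")
  clean <- four_taxon(c("0", "0", "1", "1"))
  s <- fitch_length(t4, clean)
  expect_equal(s$ci, 1)
  expect_equal(s$ri, 1)
  # adding a homoplastic character strictly decreases ensemble ci
  noisy <- character_matrix(cbind(clean$cells,
                                  c(a = "0", b = "1", c = "0", d = "1")))
  s2 <- fitch_length(t4, noisy)
  expect_lt(s2$ci, s$ci)
  expect_equal(s2$total_length, sum(s2$per_char_length))
  expect_true(all(s2$per_char_length >= s2$per_char_min))
  expect_true(all(s2$per_char_length <= s2$per_char_max))
})

test_that("unambiguous characters reconstruct identically under both flavors", {
  t4 <- read_newick_text("((a,b),(c,d));")
  m <- four_taxon(c("0", "0", "1", "1"))
  acc <- optimize_states(t4, m, "ACCTRAN")
  del <- optimize_states(t4, m, "DELTRAN")
  expect_identical(acc$states, del$states)
  expect_equal(nrow(acc$changes), 1L)
})

test_that("the textbook ambiguous case splits ACCTRAN and DELTRAN apart", {
  # outgroup 0, then leaves 1, 0, 1 on a pectinate tree: one gain + one loss
  # under ACCTRAN, two independent gains under DELTRAN
  phy <- read_newick_text("(out,(l1,(l2,l3)));")
  cells <- matrix(c("0", "1", "0", "1"), ncol = 1L)
  rownames(cells) <- c("out", "l1", "l2", "l3")
  m <- character_matrix(cells)
  acc <- optimize_states(phy, m, "ACCTRAN")
  del <- optimize_states(phy, m, "DELTRAN")
  expect_equal(nrow(acc$changes), 2L)
  expect_equal(nrow(del$changes), 2L)
  # ACCTRAN: a gain on an internal branch then a loss at leaf l2
  expect_true(any(acc$changes$from == 1L & acc$changes$to == 0L))
  # DELTRAN: both changes are gains at the tips
  expect_true(all(del$changes$from == 0L & del$changes$to == 1L))
  expect_setequal(del$changes$label, c("l1", "l3"))
})

test_that("change counts equal the parsimony length under both flavors", {
  for (seed in 51:70) {
    case <- random_case(seed)
    s <- fitch_length(case$tree, case$matrix)
    for (fl in c("ACCTRAN", "DELTRAN")) {
      rec <- optimize_states(case$tree, case$matrix, fl, scores = s)
      expect_equal(rec$per_char_changes, unname(s$per_char_length),
                   info = paste(fl, "seed", seed))
    }
  }
})

test_that("stem changes classify into exclusive and homoplastic", {
  # char 1 changes once (on the (c,d) stem): exclusive;
  # char 2 changes twice, once on the stem: homoplastic
  phy <- read_newick_text("(o,(a,(b,(c,d))));")
  cells <- rbind(o = c("0", "0"), a = c("0", "1"), b = c("0", "0"),
                 c = c("1", "1"), d = c("1", "1"))
  m <- character_matrix(cells)
  rec <- optimize_states(phy, m, "DELTRAN")
  syn <- classify_synapomorphies(phy, m, rec, c("c", "d"))
  expect_equal(syn$exclusive$char, 1L)
  expect_equal(syn$homoplastic$char, 2L)
  expect_error(classify_synapomorphies(phy, m, rec, c("a", "c")),
               "not a node")
})
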