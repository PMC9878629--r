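test_that("Bemis-Murcko scaffolds match hand-derived references", {
  # a bare ring is its own scaffold
  expect_equal(compute_scaffold("c1ccccc1", "GNB"), "c1ccccc1")
  # side chains are pruned
  expect_equal(compute_scaffold("Cc1ccccc1", "GNB"), "c1ccccc1")
  # acyclic molecules share the pseudo-scaffold at every level
  for (lv in c("GNB", "GN", "GRAPH")) {
    expect_equal(compute_scaffold("CCO", lv), ACYCLIC_TOKEN)
  }
  # graph level anonymizes pyridine to the saturated all-carbon six-ring
  cyclohexane <- compute_scaffold("C1CCCCC1", "GRAPH")
  expect_equal(compute_scaffold("c1ccncc1", "GRAPH"), cyclohexane)
  # GN keeps the nitrogen but collapses bond orders
  expect_equal(compute_scaffold("c1ccncc1", "GN"),
               compute_scaffold("C1CCNCC1", "GN"))
  # linkers between rings are part of the scaffold
  expect_equal(compute_scaffold("c1ccc(-c2ccccc2)cc1", "GNB"),
               compute_scaffold("Cc1ccc(-c2ccccc2)cc1", "GNB"))
  expect_error(compute_scaffold("xx)yy"), "unparseable")
})

test_that("exocyclic multiple-bond atoms are retained at GNB only", {
  gnb <- compute_scaffold("CC1CCCCC1=O", "GNB")
  expect_equal(gnb, compute_scaffold("O=C1CCCCC1", "GNB"))
  expect_true(grepl("O", gnb))
  # at GN/GRAPH bond collapse makes the carbonyl oxygen a prunable chain
  expect_equal(compute_scaffold("O=C1CCCCC1", "GN"),
               compute_scaffold("C1CCCCC1", "GN"))
  expect_equal(compute_scaffold("O=C1CCCCC1", "GRAPH"),
               compute_scaffold("C1CCCCC1", "GRAPH"))
})

test_that("scaffold keys are canonical at their level (idempotence)", {
  set.seed(42)
  vocab <- sample(scaffold_vocabulary(), 25)
  for (lv in c("GNB", "GN", "GRAPH")) {
    keys <- compute_scaffold(vocab, lv)
    keys <- keys[keys != ACYCLIC_TOKEN]
    expect_identical(compute_scaffold(keys, lv), keys)
  }
})

test_that("levels coarsen: distinct GRAPH <= GN <= GNB keys; GRAPH commutes with GNB", {
  gen <- generate_library(synthetic_spec(M = 40, n_scaffolds = 15,
                                         acyclic_fraction = 0, seed = 5))
  smi <- gen$library$records$smiles
  gnb <- compute_scaffold(smi, "GNB")
  gn <- compute_scaffold(smi, "GN")
  graph <- compute_scaffold(smi, "GRAPH")
  expect_lte(length(unique(graph)), length(unique(gn)))
  expect_lte(length(unique(gn)), length(unique(gnb)))
  expect_identical(compute_scaffold(gnb, "GRAPH"), graph)
})

test_that("a GNB scaffold never has more heavy atoms than its parent", {
  gen <- generate_library(synthetic_spec(M = 30, n_scaffolds = 10,
                                         acyclic_fraction = 0, seed = 9))
  smi <- gen$library$records$smiles
  keys <- compute_scaffold(smi, "GNB")
  heavy <- function(s) {
    sdf <- ChemmineR::smiles2sdf(stats::setNames(s, seq_along(s)))
    vapply(seq_along(s), function(i) {
      ab <- ChemmineR::atomblock(sdf[[i]])
      sum(sub("_.*", "", rownames(ab)) != "H")
    }, integer(1))
  }
  expect_true(all(heavy(keys) <= heavy(smi)))
})

test_that("scaffold counts aggregate with a shared pseudo-scaffold", {
  lib <- chem_library("mix", c("b", "t", "e"),
                      c("c1ccccc1", "Cc1ccccc1", "CCO"))
  sc <- scaffold_counts(lib, "GNB")
  expect_equal(sc$M, 3L)
  expect_equal(sc$N, 2L)
  expect_equal(sc$N_sing, 1L)
  expect_equal(unname(sc$counts["c1ccccc1"]), 2L)
  expect_equal(unname(sc$counts[ACYCLIC_TOKEN]), 1L)

  # all-acyclic library: one scaffold, no singletons
  acy <- chem_library("acy", paste0("a", 1:5),
                      c("CCO", "CCC", "CCN", "CCCC", "COC"))
  sca <- scaffold_counts(acy)
  expect_equal(sca$N, 1L)
  expect_equal(sca$N_sing, 0L)

  # single-scaffold library
  benz <- chem_library("benz", paste0("b", 1:3),
                       c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1"))
  scb <- scaffold_counts(benz)
  expect_equal(scb$N, 1L)
  expect_equal(scb$N_sing, 0L)

  # invariants
  expect_equal(sum(sc$counts), sc$M)
  expect_equal(length(sc$counts), sc$N)
  expect_lte(sc$N, sc$M)
})

test_that("scaffold tables serialize sorted by frequency", {
  lib <- chem_library("mix", c("b", "t", "e"),
                      c("c1ccccc1", "Cc1ccccc1", "CCO"))
  path <- tempfile(fileext = ".tsv")
  write_scaffold_table(scaffold_counts(lib), path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$scaffold_key, c("c1ccccc1", "ACYCLIC"))
  expect_equal(tab$count, c(2L, 1L))
  expect_equal(tab$is_singleton, c(FALSE, TRUE))
})
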