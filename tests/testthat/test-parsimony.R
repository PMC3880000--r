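study_tree <- function() load_study()$tree

test_that("known character patterns give the expected Fitch minima", {
  tree <- study_tree()
  # present in all three nectar feeders: one gain below the root
  f <- fitch_parsimony(tree, c(GSO = 1, ACU = 1, LCO = 1, MCA = 0),
                       root_state = 0L)
  expect_equal(f$changes, 1L)
  # constant character: no changes
  expect_equal(fitch_parsimony(tree, c(GSO = 1, ACU = 1, LCO = 1,
                                       MCA = 1))$changes, 0L)
  # ACU+LCO but not GSO: two changes, and the reconstruction is not unique
  f2 <- fitch_parsimony(tree, c(GSO = 0, ACU = 1, LCO = 1, MCA = 0),
                        root_state = 0L)
  expect_equal(f2$changes, 2L)
  e2 <- enumerate_mprs(tree, c(GSO = 0, ACU = 1, LCO = 1, MCA = 0),
                       root_state = 0L)
  expect_equal(e2$changes, 2L)
  expect_gte(e2$count, 2L)
})

test_that("the single-gain reconstruction for the three-species character is unique", {
  tree <- study_tree()
  e <- enumerate_mprs(tree, c(GSO = 1, ACU = 1, LCO = 1, MCA = 0),
                      root_state = 0L)
  expect_equal(e$count, 1L)
  # the gain sits on the branch to the nectar-feeder ancestor: that node
  # is state 1, the root state 0
  rec <- e$reconstructions[[1]]
  root <- as.character(ape::Ntip(tree) + 1L)
  ingroup_mrca <- as.character(mrca_node(tree, c("GSO", "ACU", "LCO")))
  expect_equal(rec[[root]], 0L)
  expect_equal(rec[[ingroup_mrca]], 1L)
})

test_that("a constant character has exactly one reconstruction", {
  tree <- study_tree()
  e <- enumerate_mprs(tree, c(GSO = 0, ACU = 0, LCO = 0, MCA = 0),
                      root_state = 0L)
  expect_equal(e$changes, 0L)
  expect_equal(e$count, 1L)
})

test_that("the DP engine equals exhaustive enumeration on random trees", {
  set.seed(2024)
  for (i in seq_len(60)) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    states <- stats::setNames(sample(0:1, n, replace = TRUE),
                              tree$tip.label)
    for (rs in list(NULL, 0L, 1L)) {
      f <- fitch_parsimony(tree, states, root_state = rs)
      e <- enumerate_mprs(tree, states, root_state = rs)
      expect_identical(f$changes, e$changes)
      # per-node MPR state sets agree with the union over enumerated MPRs
      ntip <- ape::Ntip(tree)
      for (v in ntip + seq_len(tree$Nnode)) {
        seen <- sort(unique(vapply(e$reconstructions,
                                   function(r) r[[as.character(v)]], 0L)))
        expect_identical(unname(which(f$node_states[v, ])) - 1L, seen)
      }
    }
  }
})

test_that("unconstrained minima agree with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in seq_len(40)) {
    n <- sample(4:10, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    states <- stats::setNames(sample(0:1, n, replace = TRUE),
                              tree$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(states),
                                   ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_parsimony(tree, states)$changes,
                 as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("the size guard rejects oversized enumeration requests", {
  tree <- ape::rtree(20, rooted = TRUE)
  states <- stats::setNames(sample(0:1, 20, replace = TRUE),
                            tree$tip.label)
  expect_error(enumerate_mprs(tree, states), "size guard")
})

test_that("a leaf without a state is rejected", {
  tree <- study_tree()
  expect_error(fitch_parsimony(tree, c(GSO = 1, ACU = 1, LCO = 1)),
               "leaf without a state.*MCA")
})

test_that("the character matrix encodes the published presence pattern", {
  study <- load_study()
  cmat <- build_character_matrix(study$profiles, outgroup = "MCA")
  expect_true("13/3" %in% colnames(cmat))
  expect_equal(unname(cmat[c("GSO", "ACU", "LCO", "MCA"), "13/3"]),
               c(1L, 1L, 1L, 0L))
  expect_equal(unname(cmat[c("GSO", "ACU", "LCO", "MCA"), "16/19"]),
               c(0L, 1L, 1L, 0L))
  # outgroup all-zero; no all-zero characters
  expect_true(all(cmat["MCA", ] == 0L))
  expect_true(all(colSums(cmat) > 0L))
  # the study provides at least nine usable cladistic characters
  expect_gte(ncol(cmat), 9L)
  ann <- attr(cmat, "annotations")
  expect_equal(unname(ann[["13/3"]]), "assumed-acrocentric-ancestor")
  expect_true(all(c("9/17", "18/5") %in% names(ann)))
  expect_false("16/19" %in% names(ann))
})

test_that("a single taxon with no associations gives an empty matrix", {
  empty <- structure(list(species = "T", associations = character(),
                          ambiguous = character(), intact = character(),
                          pairs = NULL), class = "association_profile")
  cmat <- build_character_matrix(list(empty), outgroup = "T")
  expect_equal(ncol(cmat), 0L)
  expect_error(build_character_matrix(list(empty), outgroup = "ZZ"),
               "missing taxon profile")
})

test_that("placement follows the outgroup-polarized convention", {
  study <- load_study()
  cmat <- build_character_matrix(study$profiles, outgroup = "MCA")
  rep <- place_rearrangements(study$tree, cmat)
  row <- function(ch) rep[rep$character == ch, ]
  r <- row("13/3")
  expect_equal(r$placement_type, "ancestral")
  expect_equal(r$nodes, "MRCA(ACU,GSO,LCO)")
  expect_true(r$unique_mpr)
  for (ch in c("9/17", "18/5")) {
    r <- row(ch)
    expect_equal(r$placement_type, "clade_synapomorphy")
    expect_equal(r$nodes, "MRCA(ACU,GSO)")
    expect_equal(r$fitch_min, 1L)
  }
  r <- row("16/19")
  expect_equal(r$placement_type, "convergent_terminal")
  expect_equal(r$nodes, "ACU|LCO")
  expect_equal(r$implied_changes, 2L)
  expect_equal(r$fitch_min, 2L)
  expect_equal(r$mpr_count, 2L)
  expect_false(r$unique_mpr)
})

test_that("placement change counts never beat the Fitch minimum", {
  study <- load_study()
  cmat <- build_character_matrix(study$profiles, outgroup = "MCA")
  rep <- place_rearrangements(study$tree, cmat)
  expect_true(all(rep$implied_changes >= rep$fitch_min))
  mono <- rep$placement_type %in% c("ancestral", "clade_synapomorphy",
                                    "terminal_autapomorphy")
  expect_true(all(rep$implied_changes[mono] == rep$fitch_min[mono]))
  # synapomorphies are exactly the characters whose presence set is a
  # proper multi-taxon clade of the ingroup
  expect_setequal(rep$character[rep$placement_type == "clade_synapomorphy"],
                  c("9/17", "18/5"))
})

test_that("the annotated newick lists gained characters at nodes", {
  study <- load_study()
  cmat <- build_character_matrix(study$profiles, outgroup = "MCA")
  rep <- place_rearrangements(study$tree, cmat)
  f <- tempfile(fileext = ".nwk")
  write_annotated_tree(rep, f)
  txt <- readLines(f)
  expect_match(txt, "13_3", fixed = TRUE)
  expect_no_error(ape::read.tree(f))
})
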