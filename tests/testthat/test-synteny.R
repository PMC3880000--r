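test_that("conserved-region counts match the published totals", {
  study <- load_study()
  expect_equal(count_conserved_regions(study$maps$GSO, study$probes), 24L)
  expect_equal(count_conserved_regions(study$maps$ACU, study$probes), 29L)
  expect_equal(count_conserved_regions(study$maps$LCO, study$probes), 26L)
})

test_that("an identity map has exactly one region per probe", {
  study <- load_study()
  idm <- identity_homology_map(study$karyos$MCA)
  expect_equal(count_conserved_regions(idm, study$probes), 19L)
  expect_equal(count_conserved_regions(idm), 19L)  # default autosomal probes
})

test_that("region counting equals an independent run-length scan, including on simulated maps", {
  study <- load_study()
  for (sp in names(study$maps)) {
    expect_equal(count_conserved_regions(study$maps[[sp]], study$probes),
                 oracle_region_count(study$maps[[sp]], study$probes))
  }
  for (seed in 1:10) {
    h <- simulate_history(default_recovery_tree(),
                          rates = c(rb_fusion = 1, rb_fission = 0.3,
                                    tandem_fusion = 0.3), seed = seed)
    probes <- setdiff(vapply(h$root$chroms, `[[`, "", "id"), "X")
    for (tip in names(h$tip_karyotypes)) {
      m <- project_painting(h, tip)
      expect_equal(count_conserved_regions(m, probes),
                   oracle_region_count(m, probes))
    }
  }
})

test_that("intact chromosomes match the published per-species sets", {
  study <- load_study()
  p <- study$profiles
  expect_equal(setdiff(p$GSO$intact, "X"),
               c("4", "6", "7", "8", "15", "16"))
  expect_equal(setdiff(p$ACU$intact, "X"), c("7", "8", "10", "11"))
  expect_equal(setdiff(p$LCO$intact, "X"), c("8", "9"))
  # the X chromosome is a single conserved block in every species
  for (sp in c("GSO", "ACU", "LCO")) {
    expect_true("X" %in% p[[sp]]$intact)
  }
  # only one autosome is conserved across all three lineages
  common <- Reduce(intersect, lapply(p[c("GSO", "ACU", "LCO")],
                                     function(x) setdiff(x$intact, "X")))
  expect_equal(common, "8")
})

test_that("an identity map leaves every autosome intact", {
  study <- load_study()
  idm <- identity_homology_map(study$karyos$MCA)
  expect_setequal(intact_source_chromosomes(idm),
                  c(study$probes, "X"))
})

test_that("a forced fusion removes exactly its operands from the intact set", {
  h0 <- simulate_history(default_recovery_tree(), rates = c(rb_fusion = 0),
                         seed = 1)
  kar <- apply_event(h0$tip_karyotypes$A,
                     list(kind = "rb_fusion", chroms = c("9", "10")))
  h0$tip_karyotypes$A <- kar
  m <- project_painting(h0, "A")
  intact <- setdiff(intact_source_chromosomes(m), "X")
  all_auto <- setdiff(vapply(h0$root$chroms, `[[`, "", "id"), "X")
  expect_setequal(intact, setdiff(all_auto, c("9", "10")))
})

test_that("associations: per-species sets contain the published characters", {
  study <- load_study()
  p <- study$profiles
  expect_true("13/3" %in% p$GSO$associations)
  expect_true("9/17" %in% p$GSO$associations)
  expect_true("18/5" %in% p$GSO$associations)
  expect_true("13/3" %in% p$ACU$associations)
  expect_true("16/19" %in% p$ACU$associations)
  expect_true("16/19" %in% p$LCO$associations)
  # intact chromosomes never appear inside an association of the same profile
  for (sp in names(p)) {
    members <- unique(unlist(strsplit(p[[sp]]$associations, "/")))
    expect_length(intersect(members, p[[sp]]$intact), 0)
  }
})

test_that("a map with one source per target yields no associations", {
  study <- load_study()
  idm <- identity_homology_map(study$karyos$MCA)
  expect_length(extract_syntenic_associations(idm)$associations, 0)
})

test_that("shared associations reproduce the published taxon-subset sets", {
  study <- load_study()
  p <- study$profiles[c("GSO", "ACU", "LCO")]
  expect_equal(shared_associations(p, c("GSO", "ACU", "LCO")), "13/3")
  expect_setequal(shared_associations(p, c("GSO", "ACU"),
                                      excluded = "LCO"),
                  c("9/17", "18/5"))
  expect_equal(shared_associations(p, c("ACU", "LCO"), excluded = "GSO"),
               "16/19")
  expect_error(shared_associations(p, c("GSO", "ZZZ")), "unknown taxon")
})

test_that("shared associations on identical profiles return the full set", {
  study <- load_study()
  p <- study$profiles$GSO
  p2 <- p; p2$species <- "GSO2"
  expect_equal(shared_associations(list(p, p2), c("GSO", "GSO2")),
               sort(p$associations))
})

test_that("shared_associations is monotone: more required taxa, never more results", {
  study <- load_study()
  p <- study$profiles[c("GSO", "ACU", "LCO")]
  subsets <- list("GSO", "ACU", "LCO", c("GSO", "ACU"), c("GSO", "LCO"),
                  c("ACU", "LCO"), c("GSO", "ACU", "LCO"))
  for (small in subsets) {
    for (big in subsets) {
      if (!all(small %in% big)) next
      expect_true(all(shared_associations(p, big) %in%
                        shared_associations(p, small)))
    }
  }
})

test_that("chromosome-level ambiguous blocks are excluded from shared associations", {
  # synthetic map where the 2/3 adjacency rests on an 'or' between two
  # different source chromosomes
  tab <- data.frame(target_species = "T", target_chrom = "1",
                    order_index = c(1, 2), target_region = c("1p", "1q"),
                    source_species = "S", source_region = c("2", "3"),
                    alternatives = c("", "4"), flags = "")
  m <- homology_map("T", "S", tab[, -1])
  prof <- extract_syntenic_associations(m)
  expect_length(prof$associations, 0)
  expect_equal(prof$ambiguous, "2/3")
})

test_that("plesiomorphic chromosomes are those intact in the outgroup and one ingroup taxon", {
  study <- load_study()
  plesio <- infer_plesiomorphic_chromosomes(study$profiles, "MCA")
  expect_equal(plesio,
               c("4", "6", "7", "8", "9", "10", "11", "15", "16"))
  expect_length(plesio, 9)
  expect_true("8" %in% plesio)
  # empty ingroup: nothing can be corroborated
  expect_length(infer_plesiomorphic_chromosomes(
    study$profiles["MCA"], "MCA"), 0)
})

test_that("canonical association names keep the conventional orderings", {
  expect_equal(canonical_association("3", "13"), "13/3")
  expect_equal(canonical_association("17", "9"), "9/17")
  expect_equal(canonical_association("5", "18"), "18/5")
  expect_equal(canonical_association("19", "16"), "16/19")
  expect_equal(canonical_association("7", "2"), "2/7")
  expect_equal(canonical_association("2", "7"), "2/7")
})
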