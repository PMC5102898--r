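test_that("the synthetic panel has the right shape and embedded motifs", {
  panel <- small_panel()
  expect_length(panel$panel, 36)
  expect_length(panel$markers, 3)
  lens <- nchar(panel$profile_panel)
  expect_true(all(lens >= 60 & lens <= 1200))
  hits <- scan_motifs(substr(panel$panel[["TraI"]], 1, 300))
  expect_setequal(unique(hits$motif), c("(D/E)NYY", "D(L/F)TF"))
  # markers mutually dissimilar, as verified by the aligner
  mk <- panel$markers
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_lt(global_identity(mk[[pair[1]]], mk[[pair[2]]]), 0.25)
  }
})

test_that("panels are seed-deterministic with seed-dependent sequences", {
  p1 <- make_reference_panel(5)
  p2 <- make_reference_panel(5)
  p3 <- make_reference_panel(6)
  expect_identical(p1$profile_panel, p2$profile_panel)
  expect_identical(names(p1$profile_panel), names(p3$profile_panel))
  expect_false(identical(p1$profile_panel, p3$profile_panel))
})

test_that("evolution hits its identity target as measured by the aligner", {
  panel <- small_panel()
  base <- panel$panel[["TraI"]]   # 300-mer
  expect_identical(as.character(evolve(base, 1.0, seed = 1)), base)
  for (target in c(0.40, 0.60, 0.85)) {
    out <- evolve(base, target, seed = 51)
    realized <- global_identity(base, out)
    expect_gte(realized, target - 0.03)
    expect_lte(realized, target + 0.03)
    expect_equal(attr(out, "realized_identity"), realized)
  }
  expect_identical(as.character(evolve(base, 0.5, seed = 9)),
                   as.character(evolve(base, 0.5, seed = 9)))
  expect_false(identical(as.character(evolve(base, 0.5, seed = 9)),
                         as.character(evolve(base, 0.5, seed = 10))))
})

test_that("protected intervals survive evolution; impossible targets error", {
  panel <- small_panel()
  base <- panel$panel[["TraI"]]
  prot <- unlist(panel$motif_positions)
  out <- as.character(evolve(base, 0.4, seed = 52, protected = prot))
  expect_identical(substr(out, 96, 99), substr(base, 96, 99))
  expect_identical(substr(out, 151, 154), substr(base, 151, 154))
  expect_error(evolve("DNYYDLTF", 0.2, seed = 1, protected = 1:8),
               "unattainable")
})

test_that("archetype complements respect the group-defining rules", {
  arch <- group_archetypes()
  genes <- lapply(arch, fplasmid:::archetype_genes)
  expect_true(all(c("TraM", "TraJ", "FinO") %in% genes$A))
  expect_true("FinO" %in% genes$B)
  expect_false(any(c("TraM", "TraJ") %in% genes$B))
  expect_true("TraJ_V" %in% genes$C)
  expect_false(any(c("TraJ", "FinO") %in% genes$C))
  expect_true("EntFR" %in% genes$D)
  expect_false(any(c("TraJ", "FinO") %in% genes$D))
  expect_true("SphTR" %in% genes$E)
  expect_false(any(c("TraM", "TraJ", "TraY", "FinO") %in% genes$E))
  # every complement is drawn from the known panel + markers
  all_names <- c(panel_gene_names(), marker_gene_names())
  for (g in genes) expect_true(all(g %in% all_names))
})

test_that("group E places sphTR immediately upstream of traD", {
  ds <- small_dataset()
  recE <- ds$records[[which(ds$truths$group == "E")[1]]]
  labels <- vapply(recE$features, `[[`, "", "label")
  i_sph <- which(labels == "SphTR")
  i_trad <- which(labels == "traD")
  expect_length(i_sph, 1)
  # minus strand: upstream means genomically after traD, adjacent
  expect_identical(recE$features[[i_sph]]$strand, "-")
  expect_equal(i_sph, i_trad + 1)
})

test_that("dataset generation is deterministic down to the emitted bytes", {
  ds1 <- make_dataset(n_per_group = 1, seed = 17)
  ds2 <- make_dataset(n_per_group = 1, seed = 17)
  f1 <- tempfile(); f2 <- tempfile()
  write_genbank(ds1$records, f1)
  write_genbank(ds2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(ds1$truths, ds2$truths)
  expect_identical(ds1$typing_panel, ds2$typing_panel)
})

test_that("dataset counts and ablation bookkeeping are as configured", {
  ds <- make_dataset(n_per_group = 2, seed = 23, n_decoys = 1)
  expect_length(ds$records, 11)
  expect_equal(sum(ds$truths$group == "decoy"), 1)
  expect_equal(unname(table(ds$truths$group)[c("A", "B", "C", "D", "E")]),
               rep(2L, 5), ignore_attr = TRUE)
  # one derepressed and one deletion derivative, both in group A
  expect_equal(sum(grepl("derepressed", ds$truths$expected_flags)), 1)
  expect_equal(sum(ds$truths$ablations == "shigella"), 1)
  sh <- ds$truths[ds$truths$ablations == "shigella", ]
  expect_identical(sh$expected_group, "unassigned")
  # the reduced record carries only the signature genes
  rec <- ds$records[[match(sh$plasmid_id, ds$truths$plasmid_id)]]
  expect_setequal(vapply(rec$features, `[[`, "", "label"),
                  c("traI", "traX", "finO"))
})

test_that("contradictory ablations are rejected", {
  ds <- small_dataset()
  arch <- group_archetypes()
  seqs <- setNames(
    lapply(fplasmid:::archetype_genes(arch$E), function(g)
      ds$panel_obj$profile_panel[[g]]),
    fplasmid:::archetype_genes(arch$E))
  expect_error(make_plasmid(arch$E, unlist(seqs), "pBad", 1,
                            list(shigella = TRUE)), "requires")
  expect_error(make_plasmid(arch$E, unlist(seqs), "pBad", 1,
                            list(drop = "FinO")), "absent from the archetype")
})
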