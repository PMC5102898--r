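test_that("generator layouts infer their archetype architectures", {
  ds <- small_dataset()
  cls <- small_classification()
  want <- c(A = "single_operon", B = "bipartite_divergent",
            C = "single_operon", D = "single_operon",
            E = "split_convergent")
  for (i in seq_len(nrow(ds$truths))) {
    g <- ds$truths$group[i]
    if (g == "decoy") next
    if (ds$truths$ablations[i] == "shigella") next
    expect_identical(cls$assignments$architecture[i], unname(want[g]),
                     label = paste("architecture of", ds$truths$plasmid_id[i]))
  }
})

test_that("too few located genes gives a fragmentary call", {
  ds <- small_dataset()
  rec <- ds$records[[1]]
  prov <- small_classification()$matrix$provenance
  row <- small_classification()$matrix$matrix[rec$plasmid_id, ]
  frag <- infer_architecture(rec, row, prov, min_genes = 100)
  expect_identical(frag$class, "fragmentary")
  none <- infer_architecture(rec, row, prov[0, ], min_genes = 4)
  expect_identical(none$class, "fragmentary")
})

test_that("regulator profile copies presence calls cellwise", {
  row <- setNames(rep(1L, 39), names(small_panel()$profile_panel))
  prof <- regulator_profile(row)
  expect_true(all(unlist(prof)))

  row2 <- setNames(rep(0L, 39), names(small_panel()$profile_panel))
  row2["FinO"] <- 1L
  prof2 <- regulator_profile(row2)
  expect_true(prof2[["finO"]])
  expect_false(prof2[["traM"]])
  expect_false(prof2[["traJ"]])

  # traJ and TraJ_V are distinct calls
  row3 <- row2; row3["TraJ_V"] <- 1L
  prof3 <- regulator_profile(row3)
  expect_true(prof3[["traJ_V"]])
  expect_false(prof3[["traJ"]])

  # markers missing from the panel are unknown, not false
  prof4 <- regulator_profile(row2[panel_gene_names()])
  expect_true(is.na(prof4[["traJ_V"]]))
  expect_true(is.na(prof4[["sphTR"]]))
})

make_profile <- function(...) {
  base <- setNames(rep(0L, 39), names(small_panel()$profile_panel))
  on <- c(...)
  base[on] <- 1L
  regulator_profile(base)
}

arch_of <- function(cls) structure(list(class = cls, clusters = list()),
                                   class = "architecture_class")

test_that("group rules assign A-E and fall through to unassigned", {
  # classical group A: traM+ traJ+ finO+
  a <- classify_group(make_profile("TraM", "TraJ", "FinO", "TraC"),
                      arch_of("single_operon"))
  expect_identical(a$group, "A")
  expect_length(a$flags, 0)

  # the F-plasmid exception: finO- group A is flagged derepressed
  a2 <- classify_group(make_profile("TraM", "TraJ", "TraC"),
                       arch_of("single_operon"))
  expect_identical(a2$group, "A")
  expect_identical(a2$flags, "derepressed_finO_minus")

  b <- classify_group(make_profile("FinO", "TraC"),
                      arch_of("bipartite_divergent"))
  expect_identical(b$group, "B")
  # same regulators without the bipartite layout are not group B
  expect_identical(classify_group(make_profile("FinO", "TraC"),
                                  arch_of("single_operon"))$group,
                   "unassigned")

  cc <- classify_group(make_profile("TraJ_V", "TraC"),
                       arch_of("single_operon"))
  expect_identical(cc$group, "C")

  d <- classify_group(make_profile("EntFR", "TraC"),
                      arch_of("single_operon"))
  expect_identical(d$group, "D")

  e <- classify_group(make_profile("SphTR", "TraC"),
                      arch_of("split_convergent"))
  expect_identical(e$group, "E")

  expect_identical(classify_group(make_profile("TraC"),
                                  arch_of("single_operon"))$group,
                   "unassigned")
})

test_that("removing traM and traJ from a group-A profile never gives A", {
  variants <- list(c("FinO", "TraC"), c("FinO"), c("TraC"), character())
  for (v in variants) {
    res <- classify_group(do.call(make_profile, as.list(v)),
                          arch_of("single_operon"))
    expect_false(res$group == "A")
  }
})

test_that("completeness reports missing essentials and the deletion signature", {
  full <- setNames(rep(1L, 39), names(small_panel()$profile_panel))
  rep1 <- completeness(full)
  expect_true(rep1$complete)
  expect_length(rep1$missing, 0)

  no_c <- full; no_c["TraC"] <- 0L
  rep2 <- completeness(no_c)
  expect_false(rep2$complete)
  expect_identical(rep2$missing, "TraC")

  # Shigella-type deletion derivative: only traI, traX, finO remain
  sig <- setNames(rep(0L, 39), names(small_panel()$profile_panel))
  sig[c("TraI", "TraX", "FinO")] <- 1L
  rep3 <- completeness(sig)
  expect_true(rep3$deletion_derivative)
  expect_false(rep3$complete)
  cls3 <- classify_group(regulator_profile(sig), arch_of("fragmentary"), rep3)
  expect_identical(cls3$group, "unassigned")
  expect_true("deletion_derivative" %in% cls3$flags)

  expect_error(completeness(full, essential_set = c("TraC", "NotAGene")),
               "absent")
})
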