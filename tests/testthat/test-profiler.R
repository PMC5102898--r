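test_that("the default reference panel has the 36 genes plus 3 markers", {
  expect_length(panel_gene_names(), 36)
  expect_false(anyDuplicated(panel_gene_names()) > 0)
  expect_length(marker_gene_names(), 3)
  panel <- small_panel()
  expect_length(panel$panel, 36)
  expect_length(panel$profile_panel, 39)
  expect_setequal(names(panel$panel), panel_gene_names())
})

test_that("a record carrying a reference protein is called present", {
  panel <- small_panel()
  traD <- panel$panel[["TraD"]]
  rec <- plasmid_record("pHit", list(
    gene_feature("traD", 100, 100 + 3 * nchar(traD) + 3, "+", traD)))
  call <- detect_presence(traD, rec)
  expect_equal(call$present, 1L)
  expect_lt(call$evalue, 1e-3)
  expect_equal(call$identity, 1)
  expect_identical(call$protein_id, "traD")
})

test_that("unrelated random proteins are called absent", {
  set.seed(110)
  panel <- small_panel()
  feats <- lapply(1:5, function(k) {
    p <- paste(sample(aa20, 250, TRUE), collapse = "")
    gene_feature(sprintf("orf%d", k), 100 + 1000 * k,
                 100 + 1000 * k + 3 * 250 + 3, "+", p)
  })
  rec <- plasmid_record("pRand", feats)
  expect_equal(detect_presence(panel$panel[["TraD"]], rec)$present, 0L)
  empty <- plasmid_record("pEmpty", list(), length_bp = 100)
  call <- detect_presence(panel$panel[["TraD"]], empty)
  expect_equal(call$present, 0L)
  expect_identical(call$note, "no proteins")
})

test_that("matrix rows reproduce generator complements, including ablations", {
  ds <- small_dataset()
  cls <- small_classification()
  m <- cls$matrix$matrix
  expect_identical(rownames(m), vapply(ds$records, `[[`, "", "plasmid_id"))
  expect_identical(colnames(m), names(ds$panel_obj$profile_panel))
  arch <- group_archetypes()
  keys <- fplasmid:::gene_key(colnames(m))
  for (i in seq_along(ds$records)) {
    g <- ds$truths$group[i]
    if (g == "decoy") next
    genes <- fplasmid:::gene_key(fplasmid:::archetype_genes(arch[[g]]))
    if (ds$truths$ablations[i] == "drop") genes <- setdiff(genes, "fino")
    expected <- as.integer(keys %in% genes)
    # allow a rare spurious E-value hit, but require near-exact agreement
    expect_gte(mean(m[i, ] == expected), 0.97)
  }
  expect_error(build_matrix(list(ds$records[[1]], ds$records[[1]]),
                            ds$panel_obj$profile_panel), "duplicate")
})

test_that("conservation reports column means as descending percentages", {
  m <- matrix(c(1, 1, 1, 1,
                1, 0, 1, 0,
                0, 0, 0, 0), 4, 3,
              dimnames = list(paste0("p", 1:4), c("traA", "traB", "traC")))
  cons <- conservation(m)
  expect_equal(cons$percent[cons$gene == "traA"], 100)
  expect_equal(cons$percent[cons$gene == "traB"], 50)
  expect_equal(cons$percent[cons$gene == "traC"], 0)
  expect_true(all(diff(cons$percent) <= 0))
  # recount oracle: brute-force column sums on random matrices
  set.seed(111)
  for (i in 1:10) {
    r <- matrix(rbinom(60, 1, 0.4), 10, 6,
                dimnames = list(paste0("p", 1:10), paste0("g", 1:6)))
    cons_r <- conservation(r)
    for (j in seq_len(ncol(r))) {
      manual <- 0
      for (k in seq_len(nrow(r))) manual <- manual + r[k, j]
      expect_equal(cons_r$percent[cons_r$gene == colnames(r)[j]],
                   100 * manual / nrow(r))
    }
  }
})

test_that("co-occurrence equals N minus the Hamming distance", {
  m <- matrix(c(1, 1, 0, 0,
                1, 0, 1, 0), 4, 2,
              dimnames = list(paste0("p", 1:4), c("g1", "g2")))
  cc <- cooccurrence(m)
  expect_equal(cc$matrix["g1", "g2"], 2L)   # Hamming 2 of N = 4
  expect_equal(diag(cc$matrix), setNames(c(4L, 4L), c("g1", "g2")))
  comp <- matrix(c(1, 1, 0, 0,
                   0, 0, 1, 1), 4, 2,
                 dimnames = list(paste0("p", 1:4), c("a", "b")))
  expect_equal(cooccurrence(comp)$matrix["a", "b"], 0L)
  expect_error(cooccurrence(matrix(integer(), 0, 2)), "empty")
})

test_that("C(i,j) + Hamming(i,j) = N on random matrices, and C is symmetric", {
  set.seed(112)
  for (trial in 1:10) {
    n <- sample(3:30, 1); g <- sample(2:10, 1)
    m <- matrix(rbinom(n * g, 1, runif(1, 0.2, 0.8)), n, g,
                dimnames = list(paste0("p", 1:n), paste0("g", 1:g)))
    cc <- cooccurrence(m)$matrix
    expect_identical(cc, t(cc))
    for (i in seq_len(g)) for (j in seq_len(g)) {
      expect_equal(cc[i, j] + sum(m[, i] != m[, j]), n)
    }
    # all-ones column: co-occurrence with any gene is that gene's count
    m2 <- cbind(m, all1 = 1L)
    cc2 <- cooccurrence(m2)$matrix
    expect_equal(unname(cc2["all1", seq_len(g)]), unname(colSums(m)))
  }
})

test_that("row permutation permutes the matrix and leaves co-occurrence fixed", {
  ds <- small_dataset()
  sub <- ds$records[1:4]
  panel <- ds$panel_obj$profile_panel[c("TraD", "TraC", "TraM", "FinO")]
  m1 <- build_matrix(sub, panel)
  perm <- c(3, 1, 4, 2)
  m2 <- build_matrix(sub[perm], panel)
  expect_identical(m2$matrix, m1$matrix[perm, ])
  expect_identical(cooccurrence(m2)$matrix, cooccurrence(m1)$matrix)
})
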