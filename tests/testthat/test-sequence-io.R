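test_that("FASTA write/read round-trips and rejects duplicates", {
  path <- tempfile(fileext = ".faa")
  entries <- c(relA = "MKVLAW", relB = paste(rep("ACDEFGHIKL", 20),
                                             collapse = ""))
  write_fasta(entries, path)
  back <- read_fasta(path)
  expect_identical(back, entries)

  one <- tempfile()
  writeLines(c(">a", "MKV"), one)
  expect_equal(read_fasta(one), c(a = "MKV"))
  dup <- tempfile()
  writeLines(c(">a", "MKV", ">a", "MAV"), dup)
  expect_error(read_fasta(dup), "duplicate")
  expect_error(write_fasta(character(), tempfile()), "no entries")
})

test_that("matrix TSV round-trips including the 1x1 case", {
  m1 <- matrix(1L, 1, 1, dimnames = list("p1", "traD"))
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m1, p)
  lines <- readLines(p)
  expect_length(lines, 2)
  expect_identical(read_matrix_tsv(p), m1)

  m <- matrix(rbinom(12, 1, 0.5), 3, 4,
              dimnames = list(paste0("p", 1:3), paste0("g", 1:4)))
  storage.mode(m) <- "integer"
  write_matrix_tsv(m, p)
  expect_identical(read_matrix_tsv(p), m)
})

test_that("Newick output is parseable by an independent tree reader", {
  D <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- neighbor_joining(D)
  p <- tempfile(fileext = ".nwk")
  write_newick(tree, p)
  back <- ape::read.tree(p)
  expect_setequal(back$tip.label, c("x", "y", "z"))
  expect_equal(sort(back$edge.length), sort(tree$edge.length))
})

test_that("GenBank coordinates convert between conventions at the boundary", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       pTest                 500 bp    DNA     circular BCT 01-JAN-2016",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    '                     /organism="Escherichia coli"',
    "     CDS             complement(10..30)",
    '                     /gene="traX"',
    '                     /translation="MKVLAWG"',
    "     CDS             40..60",
    '                     /gene="finO"',
    '                     /translation="MAVHEAG"',
    "//"), gb)
  recs <- read_genbank(gb)
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_identical(rec$plasmid_id, "pTest")
  expect_identical(rec$host_taxon, "Escherichia coli")
  f <- rec$features[[1]]
  expect_equal(c(f$start, f$end), c(9, 30))
  expect_identical(f$strand, "-")
  expect_identical(f$protein, "MKVLAWG")
  # for every feature: genbank_start = start + 1, genbank_end = end
  expect_equal(rec$features[[2]]$start + 1, 40)
  expect_equal(rec$features[[2]]$end, 60)
})

test_that("GenBank parsing fails loudly on malformed input", {
  empty <- tempfile()
  writeLines(character(), empty)
  expect_error(read_genbank(empty), "LOCUS")
  junk <- tempfile()
  writeLines(c("this is not", "a genbank file"), junk)
  expect_error(read_genbank(junk), "LOCUS")
})

test_that("CDS without a translation is skipped with a warning, not fatal", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       pFrag                 300 bp    DNA     circular BCT 01-JAN-2016",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..90",
    '                     /gene="traI"',
    "     CDS             100..130",
    '                     /gene="traX"',
    '                     /translation="MAVHEAGAWG"',
    "//"), gb)
  expect_message(recs <- read_genbank(gb), "skipped")
  expect_length(recs[[1]]$features, 1)
  expect_identical(recs[[1]]$features[[1]]$label, "traX")
})

test_that("generator datasets round-trip through GenBank exactly", {
  ds <- small_dataset()
  gb <- tempfile(fileext = ".gbk")
  write_genbank(ds$records, gb)
  back <- read_genbank(gb)
  expect_length(back, length(ds$records))
  for (i in seq_along(back)) {
    a <- ds$records[[i]]; b <- back[[i]]
    expect_identical(b$plasmid_id, a$plasmid_id)
    expect_identical(b$host_taxon, a$host_taxon)
    expect_identical(b$length_bp, a$length_bp)
    expect_length(b$features, length(a$features))
    for (k in seq_along(a$features)) {
      expect_identical(unclass(b$features[[k]]), unclass(a$features[[k]]))
    }
  }
})

test_that("long translations wrap and re-join across qualifier lines", {
  prot <- paste(rep("MKVLAWGHED", 30), collapse = "")   # 300 aa
  rec <- plasmid_record("pWrap", list(gene_feature("traC", 100, 100 + 903,
                                                   "+", prot)))
  gb <- tempfile(fileext = ".gbk")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_identical(back[[1]]$features[[1]]$protein, prot)
})
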