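test_that("the bundled reference loads, validates and round-trips", {
  path <- system.file("extdata", "synthetic_rCRS.fasta",
                      package = "mitorho")
  ref <- loadReference(path)
  expect_equal(refLength(ref), 16569L)
  expect_identical(refSequence(ref), refSequence(REF))

  out <- file.path(tempdir(), "ref_roundtrip.fasta")
  writeReference(ref, out)
  expect_identical(refSequence(loadReference(out)), refSequence(ref))

  multi <- file.path(tempdir(), "two_records.fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), multi)
  expect_error(loadReference(multi), "exactly one record")

  # IUPAC ambiguity codes are legal FASTA but not accepted in a reference
  bad <- file.path(tempdir(), "bad_chars.fasta")
  writeLines(c(">a", "ACGTR"), bad)
  expect_error(loadReference(bad), "A,C,G,T,N")
})

test_that("samples and metadata are reconciled by id, preserving order", {
  dir <- tempdir()
  fa <- file.path(dir, "samples_io.fasta")
  writeLines(c(">b1", "ACGT", ">a1", "ACGT", ">c1", "ACGT"), fa)
  meta <- file.path(dir, "samples_io.tsv")
  write.table(data.frame(sample_id = c("a1", "b1", "c1"),
                         population = "pop", region_class = "Siberia",
                         source = "test"),
              meta, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readSamples(fa, meta)
  expect_equal(names(got$sequences), c("b1", "a1", "c1"))
  expect_equal(got$samples$sample_id, c("b1", "a1", "c1"))

  writeLines(c(">b1", "ACGT", ">zz", "ACGT"), fa)
  expect_error(readSamples(fa, meta), "zz")

  writeLines(character(), fa)
  empty <- readSamples(fa, meta)
  expect_length(empty$sequences, 0)
})

test_that("variant labels parse with kinds derived from the reference", {
  v <- parseVariantLabel("16189", REF)
  expect_equal(v$kind, "transition")
  expect_equal(v$position, 16189L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "C")

  ins <- parseVariantLabel("315.1C", REF)
  expect_equal(ins[, c("kind", "position", "insert_index", "alt")],
               data.frame(kind = "insertion", position = 315L,
                          insert_index = 1L, alt = "C"))

  # 16182 is A in the reference, so a C there is a transversion
  tv <- parseVariantLabel("16182C", REF)
  expect_equal(tv$kind, "transversion")

  del <- parseVariantLabel("523d", REF)
  expect_equal(del$kind, "deletion")
  expect_equal(del$label, "523d")

  # case-insensitive suffixes
  expect_equal(parseVariantLabel("16182c", REF)$label, "16182C")

  expect_error(parseVariantLabel("abc", REF), "unparseable")
  expect_error(parseVariantLabel("99999", REF), "out of range")
})

test_that("canonical labels are stable under parse-format round trips", {
  set.seed(11)
  n <- 1000
  kinds <- sample(c("transition", "transversion", "insertion", "deletion"),
                  n, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  refChars <- strsplit(refSequence(REF), "")[[1]]
  labels <- vapply(seq_len(n), function(i) {
    pos <- sample(refLength(REF), 1)
    rb <- refChars[pos]
    switch(kinds[i],
      transition = as.character(pos),
      transversion = paste0(pos, sample(setdiff(
        setdiff(c("A", "C", "G", "T"), rb),
        mitorho:::transitionPartner(rb)), 1)),
      insertion = paste0(pos, ".", sample(3, 1),
                         sample(c("A", "C", "G", "T"), 1)),
      deletion = paste0(pos, "d"))
  }, "")
  parsed <- parseVariantLabel(labels, REF)
  expect_setequal(parsed$label, unique(labels))
  # formatting the parsed variants reproduces the canonical labels
  expect_equal(formatVariantLabel(parsed), parsed$label)
  # and a second parse is the identity
  reparsed <- parseVariantLabel(parsed$label, REF)
  expect_identical(reparsed, parsed)
})

test_that("positions 1 and 16569 are representable", {
  both <- parseVariantLabel(c("1", "16569"), REF)
  expect_equal(both$position, c(1L, 16569L))
})

test_that("report writers are deterministic and header-complete", {
  profs <- list(profileFrom("s1", c("8473", "263"), region = "Siberia"),
                profileFrom("s2", character(), region = "Europe"))
  tree <- buildMPTree(profs, emptyRootProfile())
  d1 <- file.path(tempdir(), "out_a")
  d2 <- file.path(tempdir(), "out_b")
  writeOutputs(profs, list(complete = tree), outDir = d1)
  writeOutputs(profs, list(complete = tree), outDir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # empty profile list: header-only table
  d3 <- file.path(tempdir(), "out_c")
  writeOutputs(list(), outDir = d3)
  expect_equal(readLines(file.path(d3, "profiles.tsv")),
               "sample_id\tpopulation\tregion_class\tmask\tvariants")
})

test_that("Newick output has the right leaves and re-reads through ape", {
  profs <- list(profileFrom("a", "1000"), profileFrom("b", "2000"),
                profileFrom("c", c("1000", "3000")))
  tree <- buildMPTree(profs, emptyRootProfile())
  d <- file.path(tempdir(), "out_nwk")
  writeOutputs(profs, list(complete = tree), outDir = d)
  ph <- ape::read.tree(file.path(d, "tree_complete.nwk"))
  expect_setequal(ph$tip.label, c("a", "b", "c"))
  expect_equal(sum(ph$edge.length), treeLength(tree))
  ann <- readLines(file.path(d, "tree_complete_annotated.nwk"))
  expect_match(ann, "&mut=", fixed = TRUE)
})
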