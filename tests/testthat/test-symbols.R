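test_that("symbol table matches the checked-in transcription fixture", {
  tab <- wln_symbol_table()
  ref <- read.delim(fixture("wln_symbols.tsv"), stringsAsFactors = FALSE)
  # the space character round-trips awkwardly through TSV; compare by key
  ref$char[is.na(ref$char)] <- " "
  rownames(ref) <- ref$char
  expect_setequal(tab$char, c(LETTERS, as.character(0:9), "&", "-", " ", "/"))
  expect_equal(nrow(tab), 40L)
  for (col in c("meaning", "max_branches", "terminating", "locant_capable",
                "implied_charge", "implied_fill", "must_unsaturate")) {
    expect_equal(tab[tab$char, col], ref[tab$char, col],
                 info = paste("column", col))
  }
})

test_that("per-symbol semantics follow the acyclic definitions", {
  e <- lookup_symbol("E")
  expect_equal(e$meaning, "bromine")
  expect_equal(e$max_branches, 1L)
  expect_true(e$terminating)
  expect_true(e$locant_capable)

  x <- lookup_symbol("X")
  expect_equal(x$max_branches, 4L)
  expect_false(x$terminating)
  expect_equal(x$implied_fill, "methyl")

  j <- lookup_symbol("J")
  expect_equal(j$meaning, "ring closure")
  expect_equal(j$max_branches, 0L)
  expect_true(j$terminating)

  # the C carbon demands an unsaturated bond, making explicit U adjacent to
  # it redundant and disallowed
  expect_true(lookup_symbol("C")$must_unsaturate)

  # terminating symbols never allow more than one branch
  tab <- wln_symbol_table()
  expect_true(all(tab$max_branches[tab$terminating] <= 1L))

  expect_error(lookup_symbol("a"), class = "UnknownSymbol")
  expect_error(lookup_symbol("!", pos = 3L), class = "UnknownSymbol")
})

test_that("locant arithmetic indexes past X with '&' extensions", {
  expect_equal(locant_to_index("A"), 1L)
  expect_equal(locant_to_index("X"), 24L)
  expect_equal(locant_to_index("A&"), 25L)
  expect_equal(locant_to_index("B&&"), 50L)
  for (i in 1:200) expect_equal(locant_to_index(index_to_locant(i)), i)
  expect_error(locant_to_index("Y"), class = "MalformedLocant")
  expect_error(locant_to_index(""), class = "MalformedLocant")
  expect_error(locant_to_index("&A"), class = "MalformedLocant")
})
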