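test_that("stereo stripping flattens references without changing the molecule", {
  expect_equal(strip_stereo("N[C@@H](C)C(=O)O"), canon("NC(C)C(=O)O"))
  expect_equal(strip_stereo("CCO"), canon("CCO"))
  expect_equal(strip_stereo("F/C=C/F"), canon("FC=CF"))
})

test_that("canonical comparison is a strict string equality after stripping", {
  expect_true(compare_canonical(convert_quiet("SCN"), "SC#N"))
  expect_true(compare_canonical("OCC(Cl)(Cl)CCC(CO)CN",
                                "OCC(Cl)(Cl)CCC(CO)CN"))
  # OO denotes dioxygen, not the peroxide dianion
  expect_false(compare_canonical(convert_quiet("OO"), "[O-][O-]"))
  expect_error(canonical_smiles("not-a-smiles(("), class = "RecordError")
})

test_that("Tanimoto similarity over FP2 fingerprints is well-behaved", {
  expect_equal(smiles_similarity("CCO", "CCO"), 1)
  expect_equal(smiles_similarity("C", "O"), 0)   # no paths, empty bit sets
  s <- smiles_similarity("CCO", "CCCO")
  expect_gt(s, 0); expect_lt(s, 1)
  # equals the direct |A&B| / |A|B| computation on the generated bit sets
  mols <- ChemmineOB::forEachMol("SMILES", "CCO\nCCCO", identity)
  bits <- ChemmineOB::fingerprint_OB(mols, "FP2") > 0
  expect_equal(s, sum(bits[1, ] & bits[2, ]) / sum(bits[1, ] | bits[2, ]))
})

test_that("triage implements the four-step pipeline", {
  r <- suppressMessages(triage("SCN", "SC#N"))
  expect_equal(r$status, "exact_pass")

  r <- suppressMessages(triage("Z2Z & GH", "NCCN.Cl"))
  expect_equal(r$status, "partial")
  expect_equal(r$substrings, c("Z2Z", "GH"))
  expect_match(r$note, "recoverable by skipping")

  r <- suppressMessages(triage("mixture of things", "CCO"))
  expect_equal(r$status, "rejected")

  r <- suppressMessages(triage("Q2 &&beta form", "CCO"))
  expect_equal(r$status, "exact_pass")
  expect_match(r$note, "suffix")

  # syntactically valid but chemically wrong: similarity scores the miss
  r <- suppressMessages(triage("Q2", "CCCCCCCC"))
  expect_equal(r$status, "exact_fail")
  expect_true(r$similarity >= 0 && r$similarity < 1)

  # statuses partition all outcomes
  for (case in list(c("SCN", "SC#N"), c("Z2Z & GH", "NCCN.Cl"),
                    c("junk lowercase", "CCO"), c("Q2", "CCCCCCCC"))) {
    r <- suppressMessages(triage(case[1], case[2]))
    expect_true(r$status %in% c("exact_pass", "exact_fail", "partial", "rejected"))
  }
})

test_that("benchmark summaries count matches and conversions", {
  two <- data.frame(wln = c("SCN", "mixture of things"),
                    reference = c("SC#N", "CCO"), stringsAsFactors = FALSE)
  s <- suppressMessages(run_benchmark(two))
  expect_equal(s$set_size, 2L)
  expect_equal(s$exact_matches, 1L)
  expect_equal(s$conversions_correct, 1L)
  expect_equal(as.integer(s$status_counts[c("exact_pass", "rejected")]), c(1L, 1L))

  # row order never changes the counts
  s2 <- suppressMessages(run_benchmark(two[2:1, ]))
  for (f in c("set_size", "exact_matches", "greedy_matches",
              "conversions_correct"))
    expect_equal(s2[[f]], s[[f]], info = f)

  expect_gte(s$greedy_matches, s$exact_matches)
})

test_that("benchmark reports serialize to JSON and TSV", {
  tmp_json <- tempfile(fileext = ".json")
  tmp_tsv <- tempfile(fileext = ".tsv")
  s <- suppressMessages(run_benchmark(fixture("synthetic_triage.tsv")))
  write_benchmark_report(s, report = tmp_json, failures = tmp_tsv)
  j <- jsonlite::read_json(tmp_json)
  expect_equal(j$set_size, s$set_size)
  expect_equal(j$conversions_correct, s$conversions_correct)
  bad <- read.delim(tmp_tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(bad), s$set_size - s$conversions_correct)
})
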