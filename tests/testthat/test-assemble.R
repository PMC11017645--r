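test_that("shorthand expansion materializes implied groups", {
  expect_equal(convert_quiet("QQ"), canon("OO"))          # hydrogen peroxide
  expect_equal(convert_quiet("1V1"), canon("CC(C)=O"))    # V = carbonyl
  expect_equal(convert_quiet("1NW"), canon("C[N](=O)=O")) # W = dioxo on N
  expect_equal(convert_quiet("WN1"), canon("C[N](=O)=O")) # W before its target
  expect_equal(convert_quiet("QX"), canon("CC(C)(C)O"))   # X methyl fill
  expect_equal(convert_quiet("QY"), canon("CC(C)O"))      # Y methyl fill
  expect_equal(convert_quiet("K"), canon("C[N+](C)(C)C")) # K: N+, methyl fill
  expect_equal(convert_quiet("HVQ"), canon("OC=O"))       # explicit H folds in
  # W on an already-bonded carbon cannot host two more double bonds
  expect_error(convert_quiet("2W"), class = "ValenceError")
})

test_that("implied double bonds follow the historical conventions", {
  expect_equal(convert_quiet("OO"), canon("O=O"))
  expect_equal(convert_quiet("SCN"), canon("SC#N"))
  expect_equal(convert_quiet("1CN"), canon("CC#N"))
  # flag off: single bonds; bare O reads as the anionic species
  expect_equal(convert_quiet("OO", implied_double = FALSE),
               canon("[O-][O-]"))
  # a 'C' whose deficit cannot be placed is a valence error
  expect_error(convert_quiet("GCG"), class = "ValenceError")
})

test_that("disabling implied double bonds never increases a bond order", {
  for (w in c("OO", "SCN", "1CN", "2U2", "1UU1", "Q1XGG2Y1Q1Z")) {
    g_on <- apply_implied_unsaturation(expand_shorthand(parse_wln(w)), TRUE)
    g_off <- apply_implied_unsaturation(expand_shorthand(parse_wln(w)), FALSE)
    expect_true(all(g_off$bond_order <= g_on$bond_order), info = w)
  }
})

test_that("maximum matching agrees with brute force on random graphs", {
  set.seed(11)
  for (k in 1:60) {
    n <- sample(2:10, 1)
    maxe <- n * (n - 1) / 2
    all_pairs <- t(combn(n, 2))
    ne <- sample(seq_len(maxe), 1)
    edges <- all_pairs[sample(maxe, ne), , drop = FALSE]
    mt <- max_matching(n, edges)
    expect_equal(sum(mt > 0) / 2, wlntools:::.matching_bruteforce(n, edges),
                 info = sprintf("case %d (n=%d, e=%d)", k, n, ne))
  }
})

test_that("kekulization places the maximum number of double bonds", {
  # benzene: perfect matching of size 3 with alternating double bonds
  g <- kekulize(apply_implied_unsaturation(expand_shorthand(parse_wln("L6J")), TRUE))
  expect_equal(sum(g$bond_order == 2L), 3L)
  # pyrrole-type five-ring with N-H: the nitrogen is barred, matching 2
  g <- kekulize(apply_implied_unsaturation(expand_shorthand(parse_wln("T5MJ")), TRUE))
  expect_equal(sum(g$bond_order == 2L), 2L)
  # azulene-type fused 5-7 system: matching of size 5
  g <- kekulize(apply_implied_unsaturation(expand_shorthand(parse_wln("L57J")), TRUE))
  expect_equal(sum(g$bond_order == 2L), 5L)
  # matching size equals the brute-force maximum on small ring systems
  for (w in c("L6J", "T6NJ", "T5MJ", "T5OJ", "L57J", "L66J", "T56 BMJ")) {
    sub <- ring_match_edges(w)
    mt <- max_matching(sub$n, sub$edges)
    expect_equal(sum(mt > 0) / 2, wlntools:::.matching_bruteforce(sub$n, sub$edges),
                 info = w)
  }
})

test_that("canonical output is invariant to matching tie-breaks", {
  for (w in c("L6J", "L66J", "L57J", "T56 BMJ", "L C666J")) {
    base <- convert_quiet(w)
    for (rep in 1:4) {
      set.seed(100 + rep)
      g <- parse_wln(w)
      g <- apply_implied_unsaturation(expand_shorthand(g), TRUE)
      g <- kekulize(g, shuffle = TRUE)
      out <- canonical_smiles(write_smiles(build_connection_table(g)))
      expect_identical(out, base, info = w)
    }
  }
})

test_that("connection tables carry correct atoms, hydrogens and charges", {
  ct <- wln_to_table(parse_wln("Q1XGG2Y1Q1Z"))
  expect_equal(nrow(ct$atoms), 12L)
  expect_equal(nrow(ct$bonds), 11L)
  expect_true(all(ct$bonds$order == 1L))
  expect_true(isTRUE(check_valences(ct)))

  ct <- wln_to_table(parse_wln("GH"))        # hydrogen chloride
  expect_equal(ct$atoms$element, "Cl")
  expect_equal(ct$atoms$hcount, 1L)

  ct <- wln_to_table(parse_wln("K"))
  n <- which(ct$atoms$element == "N")
  expect_equal(ct$atoms$charge[n], 1L)
  expect_equal(ct$atoms$hcount[n], 0L)

  # deterministic atom ordering by source position
  expect_true(!is.unsorted(wln_to_table(parse_wln("Q1XGG2Y1Q1Z"))$atoms$pos))
})

test_that("conversion is a pure function of string and options", {
  expect_identical(convert_quiet("L C666J"), convert_quiet("L C666J"))
  expect_identical(convert_quiet("SCN", format = "inchi"),
                   "InChI=1S/CHNS/c2-1-3/h3H")
})
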