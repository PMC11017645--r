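test_that("acyclic strings build the documented WLN graph", {
  g <- parse_wln("Q1XGG2Y1Q1Z")
  expect_s3_class(g, "wln_graph")
  expect_equal(g$n, 12L)
  expect_equal(sort(table(g$element[1:g$n]), decreasing = TRUE),
               sort(table(c("O", "C", "C", "Cl", "Cl", "C", "C", "C", "C",
                            "O", "C", "N")), decreasing = TRUE))
  expect_equal(length(g$bond_from), 11L)          # a tree: n - 1 edges
  expect_true(all(g$bond_order == 1L))
  # X carries four connections, Y three
  x <- which(g$char[1:g$n] == "X")
  y <- which(g$char[1:g$n] == "Y")
  deg <- function(a) sum(g$bond_from == a) + sum(g$bond_to == a)
  expect_equal(deg(x), 4L)
  expect_equal(deg(y), 3L)
  # every node's connection count respects its branch limit
  expect_true(all(vapply(1:g$n, deg, integer(1)) <= g$capacity[1:g$n]))
})

test_that("unsaturation, element codes and ions parse", {
  g <- parse_wln("1UU1")
  expect_equal(g$n, 2L)
  expect_equal(g$bond_order, 3L)

  g <- parse_wln("-SE-H")
  expect_equal(g$element[1], "Se")

  g <- parse_wln("Z2Z &GH")
  expect_equal(max(g$component[1:g$n]), 2L)
  expect_equal(g$element[g$component[1:g$n] == 2L], c("Cl", "H"))

  expect_error(parse_wln("1UU"), class = "ParseError")    # U without child
  expect_error(parse_wln("U1"), class = "ParseError")     # U without parent
  expect_error(parse_wln("SCUUN"), class = "ParseError")  # explicit U next to C
  expect_error(parse_wln("1UC1"), class = "ParseError")
  expect_error(parse_wln("-ZZ-"), class = "UnknownElement")
  expect_error(parse_wln("0"), class = "ParseError")      # zero-length chain
})

test_that("branch popping and terminators behave", {
  # '&' returns to the last open branching symbol
  expect_equal(convert_quiet("1N1&1"), canon("CN(C)C"))
  # a terminator mid-string closes its branch
  expect_equal(convert_quiet("Q1XGGG"), canon("OCC(Cl)(Cl)Cl"))
  # popping an empty stack with nothing to raise is an error
  expect_error(parse_wln("1&1", strict = TRUE), class = "ParseError")
  # trailing characters after the molecule closed are errors
  expect_error(parse_wln("GH1"), class = "ParseError")
})

test_that("run-time recovery raises M to N and skips impossible spaces", {
  expect_warning_free <- function(x) x
  msgs <- capture_messages(g <- parse_wln("1M1&1"))
  expect_match(paste(msgs, collapse = ""), "raised over-branched 'M'")
  expect_equal(g$char[2], "N")
  expect_equal(suppressMessages(wln_convert("1M1&1")), canon("CN(C)C"))
  expect_error(parse_wln("1M1&1", strict = TRUE), class = "ParseError")

  msgs <- capture_messages(out <- wln_convert("Z2Z & GH"))
  expect_match(paste(msgs, collapse = ""), "skipping space")
  expect_equal(out, canon("NCCN.Cl"))
  expect_error(parse_wln("Z2Z & GH", strict = TRUE), class = "ParseError")
  # nitrogen has no higher-degree counterpart: over-branching is fatal
  expect_error(suppressMessages(parse_wln("1X1&1&1&1&1")), class = "ParseError")
})

test_that("errors carry the offending character position", {
  err <- tryCatch(parse_wln("Z2Z & GH", strict = TRUE),
                  wln_error = function(e) e)
  expect_equal(err$position, 5L)             # the impossible space, 0-based
  err <- tryCatch(parse_wln("1UU"), wln_error = function(e) e)
  expect_equal(err$position, 2L)
  err <- tryCatch(parse_wln("T6N QJ"), wln_error = function(e) e)
  expect_s3_class(err, "RingParseError")
  expect_equal(err$position, 5L)             # ring faults highlight the J
})

test_that("parsing is deterministic", {
  for (w in c("Q1XGG2Y1Q1Z", "T-T665 B6 2AB O KO NUT &TTJ IQ MQ B2N1 &- D6J")) {
    a <- suppressMessages(wln_convert(w))
    b <- suppressMessages(wln_convert(w))
    expect_identical(a, b)
  }
})
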