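test_that("ring blocks parse into citations, heteroatoms and flags", {
  b <- parse_ring_block("L C666J")
  expect_equal(b$opener, "L")
  expect_equal(vapply(b$citations, `[[`, integer(1), "size"), c(6L, 6L, 6L))
  expect_equal(vapply(b$citations, `[[`, integer(1), "loc"), c(3L, 1L, 1L))

  b <- parse_ring_block("L6J")
  expect_equal(length(b$citations), 1L)
  expect_equal(length(b$aromatic), 0L)       # no flags: aromatic by default

  b <- parse_ring_block("T6NJ")
  expect_equal(b$heteros[[1]]$pos, 1L)       # implied first position
  expect_equal(b$heteros[[1]]$char, "N")

  b <- parse_ring_block("L6TJ")
  expect_equal(b$aromatic, FALSE)

  b <- parse_ring_block("T-T665 B6 2AB O KO NUT &TTJ")
  expect_true(b$macro)
  expect_equal(vapply(b$citations, `[[`, integer(1), "size"), c(6L, 6L, 5L, 6L))
  expect_equal(b$multicyclic, c(1L, 2L))
  expect_equal(b$size_locant, 15L)
  expect_equal(b$aromatic, c(FALSE, TRUE, FALSE, FALSE))

  expect_error(parse_ring_block("L2J"), class = "RingParseError")
  expect_error(parse_ring_block("LJ"), class = "RingParseError")
})

test_that("assembly closes each cited ring at its cited size", {
  cases <- list(
    list(wln = "L6J", n = 6L, sizes = 6L),
    list(wln = "L66J", n = 10L, sizes = c(6L, 6L)),
    list(wln = "L C666J", n = 14L, sizes = c(6L, 6L, 6L)),
    list(wln = "L B666J", n = 14L, sizes = c(6L, 6L, 6L)),
    list(wln = "L57J", n = 10L, sizes = c(5L, 7L)),
    list(wln = "T-T665 B6 2AB O KO NUT &TTJ", n = 15L, sizes = c(6L, 6L, 5L, 6L)),
    list(wln = "T B65 H6 F6 F6 3FGH R AO DU GX PN HU- MTT &TTJ",
         n = 18L, sizes = c(6L, 5L, 6L, 6L, 6L)))
  for (cs in cases) {
    a <- assemble_ring_system(parse_ring_block(cs$wln))
    expect_equal(a$n, cs$n, info = cs$wln)
    expect_equal(vapply(a$rings, length, integer(1)), cs$sizes, info = cs$wln)
    # every cited ring is an actual cycle of the assembled bond set
    has_edge <- function(u, v) any((a$edges[, 1] == u & a$edges[, 2] == v) |
                                   (a$edges[, 1] == v & a$edges[, 2] == u))
    for (r in a$rings) {
      cyc <- c(r, r[1])
      for (k in seq_along(r))
        expect_true(has_edge(cyc[k], cyc[k + 1]), info = cs$wln)
    }
  }
})

test_that("multicyclic declarations constrain ring sharing", {
  a <- assemble_ring_system(parse_ring_block("T-T665 B6 2AB O KO NUT &TTJ"))
  share <- integer(a$n)
  for (r in a$rings) share[r] <- share[r] + 1L
  expect_equal(which(share >= 3L), c(1L, 2L))  # exactly the declared A, B
  expect_equal(a$n, 15L)                       # system size locant O
})

test_that("crossed bonds and bridges add the stated bonds", {
  a <- assemble_ring_system(parse_ring_block("L6 6/BEJ"))
  expect_true(any((a$edges[, 1] == 2 & a$edges[, 2] == 5) |
                  (a$edges[, 1] == 5 & a$edges[, 2] == 2)))
  a <- assemble_ring_system(parse_ring_block("L66 CJ"))
  expect_true(any((a$edges[, 1] == 3 & a$edges[, 2] == 10) |
                  (a$edges[, 1] == 10 & a$edges[, 2] == 3)))
})

test_that("locant paths are Hamiltonian with the maximal-share start", {
  for (w in c("L6J", "L66J", "L C666J", "L B666J", "L57J",
              "T-T665 B6 2AB O KO NUT &TTJ")) {
    a <- assemble_ring_system(parse_ring_block(w))
    p <- build_locant_path(a)
    expect_true(p$exhaustive)
    expect_equal(sort(p$path), seq_len(a$n), info = w)   # visits each atom once
    expect_equal(p$share[p$path[1]], max(p$share), info = w)
    # the construction's own numbering is among the locant-sum minimizers
    identity_sum <- sum(which(p$share >= 2L))
    expect_equal(p$locant_sum, identity_sum, info = w)
  }
})

test_that("ring substituents, chained rings and spiro atoms attach", {
  expect_equal(convert_quiet("L6TJ A1"), canon("CC1CCCCC1"))
  expect_equal(convert_quiet("T6NJ B1"), canon("Cc1ccccn1"))
  # hydroxyls at two locants
  expect_equal(convert_quiet("L6TJ AQ BQ"), canon("OC1CCCCC1O"))
  # chained ring bonded at the cited locant of the new ring
  expect_equal(convert_quiet("L6TJ A- AL6TJ"), canon("C1CCCCC1C1CCCCC1"))
  # spiro: one shared atom
  expect_equal(convert_quiet("L5TJ A&- AL5TJ"), canon("C1CCC2(C1)CCCC2"))
  expect_error(suppressMessages(parse_wln("L6TJ H1")), class = "BadLocant")
})

test_that("the two morphine notations give one canonical molecule", {
  m1 <- convert_quiet("T-T665 B6 2AB O KO NUT &TTJ IQ MQ B2N1 &- D6J")
  m2 <- convert_quiet("T B65 H6 F6 F6 3FGH R AO DU GX PN HU- MTT &TTJ CQ JQ P1")
  expect_identical(m1, m2)
  expect_identical(m1, strip_stereo("CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5"))
})
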