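dfa <- build_matcher()

test_that("exact matching accepts documented WLN strings and rejects faults", {
  accepted <- c("L C666J", "SCN", "Q1XGG2Y1Q1Z", "Z1Y1Q2X1QGG", "QQ", "OO",
                "1UU1", "GH", "Z2Z &GH", "-SE-H", "R", "T6NJ", "L6TJ",
                "L66J", "L6TJ A1", "0",
                "T-T665 B6 2AB O KO NUT &TTJ IQ MQ B2N1 &- D6J",
                "T B65 H6 F6 F6 3FGH R AO DU GX PN HU- MTT &TTJ CQ JQ P1",
                "L F6 E6 B666 CV DUTJ A1 HVQ H1 K1 N1 O1 S1 S1 TQ")
  for (s in accepted) expect_true(match_exact(dfa, s), info = s)
  rejected <- c("", "SCUUN", "Z2Z & GH", "Z2Z  GH", " SCN", "SCN ",
                "abc", "Q1&&note")
  for (s in rejected) expect_false(match_exact(dfa, s), info = s)
})

test_that("determinize and minimize preserve the language", {
  nfa <- build_wln_nfa()
  raw <- nfa_determinize(nfa)
  mini <- dfa_minimize(raw)
  expect_lte(mini$n, raw$n)
  set.seed(42)
  for (k in 1:1500) {
    s <- if (k %% 3 == 0) {
      paste(sample(c(LETTERS, 0:9, "&", "-", " ", "/"),
                   sample(1:20, 1), replace = TRUE), collapse = "")
    } else {
      w <- random_accepted(mini)
      if (k %% 3 == 1) w else mutate_string(w)
    }
    a <- nfa_match(nfa, s); b <- dfa_match(raw, s); c <- dfa_match(mini, s)
    expect_true(a == b && b == c, info = s)
  }
})

test_that("no two states of the minimized machine are equivalent", {
  n <- dfa$n
  # table-filling: start from the acceptance split, propagate distinctions
  dist <- outer(dfa$accepts, dfa$accepts, FUN = "!=")
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      if (dist[i, j]) next
      for (ci in seq_len(ncol(dfa$trans))) {
        a <- dfa$trans[i, ci]; b <- dfa$trans[j, ci]
        if ((a == 0L) != (b == 0L) || (a != 0L && a != b && dist[a, b])) {
          dist[i, j] <- dist[j, i] <- TRUE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  pairs <- which(upper.tri(dist) & !dist, arr.ind = TRUE)
  expect_equal(nrow(pairs), 0L)
})

test_that("greedy extraction finds leftmost-longest candidates", {
  m <- match_greedy(dfa, "prepared Q1XGG2Y1Q1Z in two steps")
  expect_equal(nrow(m), 1L)
  expect_equal(m$text, "Q1XGG2Y1Q1Z")
  expect_equal(m$start, 9L)
  expect_equal(m$end, 20L)
  expect_equal(substr("prepared Q1XGG2Y1Q1Z in two steps",
                      m$start + 1L, m$end), m$text)

  # single-letter suppression and the enabling flag
  expect_equal(nrow(match_greedy(dfa, "A")), 0L)
  m1 <- match_greedy(dfa, "A", matcher_config(allow_single_letter = TRUE))
  expect_equal(m1$text, "A")

  # agreement with the naive all-substrings oracle on random texts
  set.seed(7)
  alpha <- c(LETTERS, letters, 0:9, "&", "-", " ", "/", ".", ",")
  for (k in 1:10) {
    txt <- paste(sample(alpha, 60, replace = TRUE), collapse = "")
    expect_equal(match_greedy(dfa, txt)[, c("start", "end", "text")],
                 greedy_oracle(dfa, txt)[, c("start", "end", "text")],
                 info = txt)
  }
})

test_that("annotation suffixes split at the first ' &&' with a valid prefix", {
  r <- strip_annotation_suffix(
    "L F6 E6 B666 CV DUTJ A1 HVQ H1 K1 N1 O1 S1 S1 TQ &&Alpha", dfa)
  expect_equal(r$wln, "L F6 E6 B666 CV DUTJ A1 HVQ H1 K1 N1 O1 S1 S1 TQ")
  expect_equal(r$suffix, "Alpha")
  expect_equal(strip_annotation_suffix("SCN", dfa),
               list(wln = "SCN", suffix = ""))
  expect_equal(strip_annotation_suffix("Q &&beta form", dfa),
               list(wln = "Q", suffix = "beta form"))
})

test_that("wlngrep processes lines independently", {
  lines <- c("the sample Q2 was dissolved", "no notation here.", "SCN")
  hits <- wlngrep(lines)
  expect_equal(hits$text, c("Q2", "SCN"))
  expect_equal(hits$line, c(1L, 3L))
  expect_equal(wlngrep(lines, exact = TRUE), "SCN")
})
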