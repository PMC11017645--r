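# Finite-state machinery: NFA construction from the relaxed WLN grammar,
# subset-construction determinization, Moore minimization, and matching.
#
# The matcher accepts a *relaxation* of WLN: any number of branches after a
# branching symbol and any number of closures anywhere, but token adjacency
# is enforced (terminators, ring open/close pairing, locant clauses, -XX-
# element codes, '/' crossed-bond clauses, space-separated ion and locant
# clauses, and the C+U adjacency ban). Strings it accepts are syntactically
# plausible WLN; semantic validity is the parser's job.

.wln_alphabet <- c(LETTERS, as.character(0:9), "&", "-", " ", "/")

.char_idx <- function(ch) match(ch, .wln_alphabet)

# ---------------------------------------------------------------------------
# NFA ----------------------------------------------------------------------

# An NFA is a list(states, trans, start, accepts) where trans is a list
# indexed [[state]][[char index]] -> integer vector of successor states.

.nfa_new <- function(state_names) {
  n <- length(state_names)
  trans <- vector("list", n)
  for (i in seq_len(n)) trans[[i]] <- vector("list", length(.wln_alphabet))
  list(states = state_names, trans = trans, start = NA_integer_,
       accepts = integer(0))
}

.nfa_add <- function(nfa, from, chars, to) {
  fi <- match(from, nfa$states)
  ti <- match(to, nfa$states)
  stopifnot(!is.na(fi), !is.na(ti))
  for (ch in chars) {
    ci <- .char_idx(ch)
    nfa$trans[[fi]][[ci]] <- sort(unique(c(nfa$trans[[fi]][[ci]], ti)))
  }
  nfa
}

#' Build the NFA for the relaxed WLN token grammar
#'
#' States model the syntactic context (start of a component, after an atom
#' symbol, after the must-unsaturate carbon `C`, after `U`, inside a digit
#' run, after branch punctuation, inside locant / element-code / ring-block
#' clauses). Ring blocks open with `L`, `T` or `D` and close with a `J` that
#' is not in locant position; inside a block letters, digits, spaces, `&`,
#' `-` and `/` follow the cyclic clause structure.
#'
#' @return An NFA object (list with `states`, `trans`, `start`, `accepts`).
#' @export
build_wln_nfa <- function() {
  ATOM  <- c("B", "C", "E", "F", "G", "H", "I", "K", "M", "N", "O", "P",
             "Q", "R", "S", "V", "W", "X", "Y", "Z")
  ATOMnC <- setdiff(ATOM, "C")
  OPEN  <- c("L", "T", "D")
  DIG   <- as.character(0:9)
  LOCL  <- LETTERS[1:24]                        # locant letters A..X
  LET   <- LETTERS

  st <- c("q0", "qlone", "qa", "qc", "qu", "qd", "qam", "qsp", "qion",
          "qloc", "qe1", "qe2", "qe3", "qhysp", "qchain", "qretd",
          "qr0", "qrm", "qri", "qrsp", "qrh1", "qrhd", "qrl1", "qrl2",
          "qx1", "qx2")
  nfa <- .nfa_new(st)
  nfa$start <- match("q0", st)
  nfa$accepts <- match(c("qlone", "qa", "qc", "qd", "qam"), st)

  A <- function(nfa, from, chars, to) .nfa_add(nfa, from, chars, to)

  # component start (fresh string or after an ion separator)
  for (s in c("q0", "qion")) {
    nfa <- A(nfa, s, ATOMnC, "qa")
    nfa <- A(nfa, s, "C", "qc")
    nfa <- A(nfa, s, DIG, "qd")
    nfa <- A(nfa, s, OPEN, "qr0")
    nfa <- A(nfa, s, "-", "qe1")
  }
  nfa <- A(nfa, "q0", "A", "qlone")        # lone locant letter, standalone only
  # after an atom symbol
  for (s in c("qa", "qc")) {
    nfa <- A(nfa, s, ATOMnC, "qa")
    nfa <- A(nfa, s, "C", "qc")
    nfa <- A(nfa, s, DIG, "qd")
    nfa <- A(nfa, s, "&", "qam")
    nfa <- A(nfa, s, " ", "qsp")
    nfa <- A(nfa, s, "-", "qe1")
  }
  nfa <- A(nfa, "qa", "U", "qu")           # C+U adjacency banned: no qc -> U
  # after unsaturation: needs a child atom next
  nfa <- A(nfa, "qu", setdiff(ATOMnC, character(0)), "qa")  # U then C banned too
  nfa <- A(nfa, "qu", "U", "qu")
  nfa <- A(nfa, "qu", DIG, "qd")
  nfa <- A(nfa, "qu", OPEN, "qr0")
  nfa <- A(nfa, "qu", "-", "qe1")
  # digit runs (alkane chain lengths)
  nfa <- A(nfa, "qd", DIG, "qd")
  nfa <- A(nfa, "qd", ATOMnC, "qa")
  nfa <- A(nfa, "qd", "C", "qc")
  nfa <- A(nfa, "qd", "U", "qu")
  nfa <- A(nfa, "qd", "&", "qam")
  nfa <- A(nfa, "qd", " ", "qsp")
  nfa <- A(nfa, "qd", "-", "qe1")
  # after '&' branch/ring pops
  nfa <- A(nfa, "qam", ATOMnC, "qa")
  nfa <- A(nfa, "qam", "C", "qc")
  nfa <- A(nfa, "qam", DIG, "qd")
  nfa <- A(nfa, "qam", "U", "qu")
  nfa <- A(nfa, "qam", "&", "qam")
  nfa <- A(nfa, "qam", " ", "qsp")
  nfa <- A(nfa, "qam", "-", "qe1")
  # space clauses: ion separator or locant clause
  nfa <- A(nfa, "qsp", "&", "qion")
  nfa <- A(nfa, "qsp", LOCL, "qloc")
  nfa <- A(nfa, "qion", "-", "qe1")        # macro-return " &- D6J"
  # locant clause: extensions, then a branch / ring continues
  nfa <- A(nfa, "qloc", "&", "qloc")
  nfa <- A(nfa, "qloc", ATOMnC, "qa")
  nfa <- A(nfa, "qloc", "C", "qc")
  nfa <- A(nfa, "qloc", DIG, "qd")
  nfa <- A(nfa, "qloc", "U", "qu")
  nfa <- A(nfa, "qloc", OPEN, "qr0")
  nfa <- A(nfa, "qloc", "-", "qe1")
  # element codes -X- and -XX-, and the hyphen-space ring chain "- <locant>"
  nfa <- A(nfa, "qe1", LET, "qe2")
  nfa <- A(nfa, "qe1", " ", "qhysp")
  nfa <- A(nfa, "qe2", LET, "qe3")
  nfa <- A(nfa, "qe2", "-", "qa")
  nfa <- A(nfa, "qe3", "-", "qa")
  nfa <- A(nfa, "qhysp", LOCL, "qchain")
  nfa <- A(nfa, "qchain", "&", "qchain")
  nfa <- A(nfa, "qchain", OPEN, "qr0")     # chained / spiro ring block
  nfa <- A(nfa, "qchain", DIG, "qretd")    # macro-return ring size
  nfa <- A(nfa, "qretd", DIG, "qretd")
  nfa <- A(nfa, "qretd", "J", "qa")        # macro-return closure
  # ring block: opener consumed
  nfa <- A(nfa, "qr0", "-", "qrm")
  nfa <- A(nfa, "qr0", DIG, "qri")
  nfa <- A(nfa, "qr0", setdiff(LET, "J"), "qri")
  nfa <- A(nfa, "qr0", " ", "qrsp")
  nfa <- A(nfa, "qrm", OPEN, "qr0")        # embedded macro opener "T-T..."
  nfa <- A(nfa, "qrm", DIG, "qrhd")        # big ring size "-12-"
  nfa <- A(nfa, "qrm", setdiff(LET, OPEN), "qrl1")
  # in-ring body
  nfa <- A(nfa, "qri", setdiff(LET, "J"), "qri")
  nfa <- A(nfa, "qri", "J", "qa")          # block closure
  nfa <- A(nfa, "qri", DIG, "qri")
  nfa <- A(nfa, "qri", " ", "qrsp")
  nfa <- A(nfa, "qri", "&", "qri")
  nfa <- A(nfa, "qri", "-", "qrh1")
  nfa <- A(nfa, "qri", "/", "qx1")
  # in-ring after a space: letters here are locants (including J)
  nfa <- A(nfa, "qrsp", LET, "qri")
  nfa <- A(nfa, "qrsp", DIG, "qri")
  nfa <- A(nfa, "qrsp", "&", "qri")
  nfa <- A(nfa, "qrsp", "-", "qrh1")
  nfa <- A(nfa, "qrsp", "/", "qx1")
  # in-ring hyphen: big ring sizes, element codes, or an explicit-target bond
  nfa <- A(nfa, "qrh1", DIG, "qrhd")
  nfa <- A(nfa, "qrh1", LET, "qrl1")
  nfa <- A(nfa, "qrh1", " ", "qrsp")
  nfa <- A(nfa, "qrhd", DIG, "qrhd")
  nfa <- A(nfa, "qrhd", "-", "qri")
  nfa <- A(nfa, "qrl1", LET, "qrl2")
  nfa <- A(nfa, "qrl1", "-", "qri")
  nfa <- A(nfa, "qrl2", "-", "qri")
  # crossed-bond clause "<size>/AB"
  nfa <- A(nfa, "qx1", LET, "qx2")
  nfa <- A(nfa, "qx2", "&", "qx2")
  nfa <- A(nfa, "qx2", LET, "qri")
  nfa
}

#' Simulate an NFA on a string
#' @param nfa NFA from [build_wln_nfa()].
#' @param line Character scalar.
#' @return TRUE iff the whole string is accepted.
#' @export
nfa_match <- function(nfa, line) {
  cur <- nfa$start
  if (nchar(line) == 0L) return(FALSE)
  for (ch in strsplit(line, "", fixed = TRUE)[[1]]) {
    ci <- .char_idx(ch)
    if (is.na(ci)) return(FALSE)
    nxt <- integer(0)
    for (s in cur) nxt <- c(nxt, nfa$trans[[s]][[ci]])
    cur <- unique(nxt)
    if (length(cur) == 0L) return(FALSE)
  }
  any(cur %in% nfa$accepts)
}

# ---------------------------------------------------------------------------
# DFA ----------------------------------------------------------------------

# A DFA is a list(n, trans, start, accepts): trans is an n x |alphabet|
# integer matrix (0 = no transition), accepts a logical vector.

#' Determinize an NFA by subset construction
#' @param nfa NFA object.
#' @return DFA object.
#' @export
nfa_determinize <- function(nfa) {
  key <- function(set) paste(set, collapse = ",")
  start_set <- sort(nfa$start)
  subsets <- list(start_set)
  ids <- new.env(parent = emptyenv())
  assign(key(start_set), 1L, envir = ids)
  trans_rows <- list()
  i <- 1L
  nchars <- length(.wln_alphabet)
  while (i <= length(subsets)) {
    set <- subsets[[i]]
    row <- integer(nchars)
    for (ci in seq_len(nchars)) {
      nxt <- integer(0)
      for (s in set) nxt <- c(nxt, nfa$trans[[s]][[ci]])
      nxt <- sort(unique(nxt))
      if (length(nxt)) {
        k <- key(nxt)
        id <- if (exists(k, envir = ids, inherits = FALSE))
          get(k, envir = ids) else NA_integer_
        if (is.na(id)) {
          subsets[[length(subsets) + 1L]] <- nxt
          id <- length(subsets)
          assign(k, id, envir = ids)
        }
        row[ci] <- id
      }
    }
    trans_rows[[i]] <- row
    i <- i + 1L
  }
  trans <- do.call(rbind, trans_rows)
  accepts <- vapply(subsets, function(s) any(s %in% nfa$accepts), logical(1))
  list(n = nrow(trans), trans = trans, start = 1L, accepts = accepts)
}

#' Minimize a DFA (Moore partition refinement)
#'
#' Merges Myhill-Nerode-equivalent states and drops unreachable ones; the
#' result accepts the same language with no two distinct equivalent states.
#' @param dfa DFA object.
#' @return Minimal DFA object.
#' @export
dfa_minimize <- function(dfa) {
  n <- dfa$n
  # partition id per state; class 0 reserved for the implicit dead state
  part <- ifelse(dfa$accepts, 2L, 1L)
  repeat {
    sig <- character(n)
    for (s in seq_len(n)) {
      row <- dfa$trans[s, ]
      cls <- ifelse(row == 0L, 0L, part[pmax(row, 1L)])
      sig[s] <- paste(part[s], paste(cls, collapse = " "))
    }
    new_part <- match(sig, unique(sig))
    if (identical(new_part, part)) break
    part <- new_part
  }
  # build quotient machine: classes are numbered 1..m contiguously by match()
  m <- max(part)
  reps <- match(seq_len(m), part)         # one representative per class
  trans <- matrix(0L, m, ncol(dfa$trans))
  for (j in seq_len(m)) {
    row <- dfa$trans[reps[j], ]
    trans[j, ] <- ifelse(row == 0L, 0L, part[pmax(row, 1L)])
  }
  accepts <- dfa$accepts[reps]
  start <- part[dfa$start]
  # drop states unreachable from the start
  seen <- logical(m); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    for (t in setdiff(unique(trans[s, ]), 0L)) {
      if (!seen[t]) { seen[t] <- TRUE; queue <- c(queue, t) }
    }
  }
  keep <- which(seen)
  remap2 <- integer(m); remap2[keep] <- seq_along(keep)
  trans <- trans[keep, , drop = FALSE]
  trans[] <- ifelse(trans == 0L, 0L, remap2[pmax(trans, 1L)])
  list(n = length(keep), trans = trans, start = remap2[start],
       accepts = accepts[keep])
}

#' Run a DFA over a string
#' @param dfa DFA object.
#' @param line Character scalar.
#' @return TRUE iff accepted.
#' @export
dfa_match <- function(dfa, line) {
  if (nchar(line) == 0L) return(FALSE)
  s <- dfa$start
  for (ch in strsplit(line, "", fixed = TRUE)[[1]]) {
    ci <- .char_idx(ch)
    if (is.na(ci)) return(FALSE)
    s <- dfa$trans[s, ci]
    if (s == 0L) return(FALSE)
  }
  dfa$accepts[s]
}

#' Number of states and edges of a DFA
#' @param dfa DFA object.
#' @return Named numeric vector with `states` and `edges`.
#' @export
dfa_size <- function(dfa) {
  c(states = dfa$n, edges = sum(dfa$trans != 0L))
}
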