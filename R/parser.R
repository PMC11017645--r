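# Character-by-character WLN parsing: builds the WLN graph (nodes, bonds,
# branch stack, ion components), delegating ring blocks to the rings module
# and leaving shorthand expansion to the assembler.

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

.terminators <- c("E", "F", "G", "H", "I", "Q", "Z")
.plain_atoms <- c("B", "C", "K", "M", "N", "O", "P", "S", "V", "X", "Y", "Z",
                  "E", "F", "G", "H", "I", "Q")

# per-symbol element / capacity used when a node is created
.acyclic_atom_info <- function(ch) {
  spec <- lookup_symbol(ch)
  cap <- spec$max_branches
  if (spec$terminating) cap <- 1L           # one connection (parent or child)
  list(element = .wln_core_element[[ch]], capacity = cap,
       charge = spec$implied_charge, fill = spec$implied_fill,
       must_unsat = spec$must_unsaturate, terminating = spec$terminating)
}

.perr <- function(P, class, msg, pos = P$i - 1L) {
  stop(wln_error(class, sprintf("position %d: %s", pos, msg), position = pos))
}

.pwarn <- function(P, msg, pos = P$i - 1L) {
  w <- sprintf("position %d: %s", pos, msg)
  P$mol$warnings <- c(P$mol$warnings, w)
  message(w)
}

# recovery: re-type the most recent saturated 'M' in this component as 'N'
# (same element, one more branch) and make it the attachment point
.raise_m <- function(P, pos) {
  if (P$strict) return(FALSE)
  m <- P$mol
  cand <- which(m$char[seq_len(m$n)] == "M" & m$component[seq_len(m$n)] == P$component &
                m$used[seq_len(m$n)] >= m$capacity[seq_len(m$n)])
  if (!length(cand)) return(FALSE)
  a <- cand[length(cand)]
  m$char[a] <- "N"
  m$capacity[a] <- 3L
  .pwarn(P, sprintf("raised over-branched 'M' at position %d to 'N'", m$pos[a]), pos)
  P$stack <- c(P$stack, a)
  P$cur <- a
  P$at_branch <- TRUE
  TRUE
}

# return to the most recent branching symbol that can still take children
.pop_to_open <- function(P) {
  m <- P$mol
  while (length(P$stack)) {
    top <- P$stack[length(P$stack)]
    if (!m$closed[top] && m$used[top] < m$capacity[top]) {
      P$cur <- top
      P$at_branch <- TRUE
      return(invisible())
    }
    P$stack <- P$stack[-length(P$stack)]
  }
  P$cur <- NA_integer_
  P$at_branch <- TRUE
  invisible()
}

# attach a new atom node to the current attachment point
.attach_atom <- function(P, ch, info, pos) {
  m <- P$mol
  ord <- 1L + P$pending_u
  if (!is.na(P$cur)) {
    if (m$closed[P$cur] || m$used[P$cur] >= m$capacity[P$cur]) {
      # run-time recovery: raise the symbol where the table offers a
      # same-element higher-degree counterpart (M -> N)
      raised <- FALSE
      if (!P$strict && m$char[P$cur] == "M") {
        m$char[P$cur] <- "N"
        m$capacity[P$cur] <- 3L
        .pwarn(P, sprintf("raised over-branched 'M' at position %d to 'N'", m$pos[P$cur]), pos)
        raised <- TRUE
      }
      if (!raised)
        .perr(P, "ParseError",
              sprintf("symbol '%s' allows %d branches; cannot attach '%s'",
                      m$char[P$cur], m$capacity[P$cur], ch), pos)
    }
  } else if (P$pending_u > 0L) {
    .perr(P, "ParseError", "unsaturation 'U' has no parent atom", pos)
  }
  if (is.na(P$cur) && !P$allow_new_root) {
    # a closed branch leaves nothing to attach to; recovery may raise a
    # filled 'M' into a branch-capable 'N' and continue from it
    if (!.raise_m(P, pos))
      .perr(P, "ParseError",
            sprintf("terminator closed the molecule; '%s' has nothing to attach to", ch),
            pos)
  }
  id <- .mol_add_atom(m, ch, pos, info$element, info$capacity,
                      charge = info$charge, fill = info$fill,
                      must_unsat = info$must_unsat, component = P$component)
  if (!is.na(P$cur)) .mol_add_bond(m, P$cur, id, ord)
  else P$allow_new_root <- FALSE
  P$pending_u <- 0L
  if (!is.na(P$w_next)) {                   # W written before its target
    m$pending_dioxo[id] <- m$pending_dioxo[id] + 1L
    P$w_next <- NA_integer_
  }
  if (info$terminating && !is.na(P$cur)) {
    .pop_to_open(P)
  } else {
    P$cur <- id
    P$at_branch <- FALSE
    if (info$capacity >= 3L) P$stack <- c(P$stack, id)
  }
  id
}

# create and register a ring system in the molecule; returns its index
.register_ring_system <- function(P, rs, pos0) {
  m <- P$mol
  ids <- integer(rs$n)
  elem <- rep("C", rs$n)
  chars <- rep("ring", rs$n)
  caps <- rep(4L, rs$n)
  charges <- rep(0L, rs$n)
  nod <- rep(FALSE, rs$n)                   # barred from kekulized doubles
  carbonyl <- rep(FALSE, rs$n)
  for (h in rs$heteros) {
    p <- h$pos
    if (p > rs$n)
      stop(wln_error("RingParseError",
                     sprintf("heteroatom locant %s is off the %d-atom path (ring closed at J, position %d)",
                             index_to_locant(p), rs$n, pos0 + rs$jpos),
                     position = pos0 + rs$jpos))
    if (!is.na(h$element)) {                # -XX- code
      elem[p] <- h$element
      caps[p] <- max(.std_valences[[h$element]] %||% 6L)
      chars[p] <- h$char
      next
    }
    chars[p] <- h$char
    switch(h$char,
      "N" = { elem[p] <- "N"; caps[p] <- 3L },
      "M" = { elem[p] <- "N"; caps[p] <- 2L; nod[p] <- TRUE },
      "K" = { elem[p] <- "N"; caps[p] <- 4L; charges[p] <- 1L },
      "O" = { elem[p] <- "O"; caps[p] <- 2L; nod[p] <- TRUE },
      "S" = { elem[p] <- "S"; caps[p] <- 6L; nod[p] <- TRUE },
      "P" = { elem[p] <- "P"; caps[p] <- 5L },
      "B" = { elem[p] <- "B"; caps[p] <- 3L },
      "V" = { elem[p] <- "C"; nod[p] <- TRUE; carbonyl[p] <- TRUE },
      "X" = { nod[p] <- TRUE },
      "Y" = { nod[p] <- TRUE; caps[p] <- 3L },
      "H" = { nod[p] <- TRUE },             # indicated hydrogen
      "C" = { },
      stop(wln_error("RingParseError",
                     sprintf("symbol '%s' cannot be a ring heteroatom", h$char))))
  }
  for (k in seq_len(rs$n)) {
    ids[k] <- .mol_add_atom(m, chars[k], pos0, elem[k], caps[k],
                            charge = charges[k], ring_member = TRUE,
                            component = P$component)
    if (carbonyl[k]) m$carbonyl[ids[k]] <- TRUE
  }
  for (p in rs$dioxo) m$pending_dioxo[ids[p]] <- m$pending_dioxo[ids[p]] + 1L
  m$no_double[ids] <- nod
  orders <- rep(1L, nrow(rs$edges))
  for (u in rs$unsats) {
    from <- u$from
    to <- u$to %||% (u$from + 1L)
    if (from > rs$n || to > rs$n)
      stop(wln_error("RingParseError", "unsaturation locant off the path",
                     position = pos0 + rs$jpos))
    k <- which((rs$edges[, 1] == from & rs$edges[, 2] == to) |
               (rs$edges[, 1] == to & rs$edges[, 2] == from))
    if (!length(k))
      stop(wln_error("RingParseError",
                     sprintf("no ring bond between locants %s and %s",
                             index_to_locant(from), index_to_locant(to)),
                     position = pos0 + rs$jpos))
    orders[k[1]] <- orders[k[1]] + u$order_add
    m$no_double[ids[c(from, to)]] <- TRUE   # explicit unsaturation fixes these
  }
  for (k in seq_len(nrow(rs$edges)))
    .mol_add_bond(m, ids[rs$edges[k, 1]], ids[rs$edges[k, 2]], orders[k])
  sys <- list(path = ids, rings = lapply(rs$rings, function(r) ids[r]),
              aromatic = rs$aromatic, opener = rs$opener,
              chelate = identical(rs$opener, "D"))
  m$ring_systems[[length(m$ring_systems) + 1L]] <- sys
  length(m$ring_systems)
}

# locate the J that closes a ring block opened at position i (1-based);
# inside a block a J directly after a space is a locant, not the closure
.find_block_close <- function(chars, i) {
  j <- i + 1L
  while (j <= length(chars)) {
    if (chars[j] == "J" && chars[j - 1L] != " ") return(j)
    j <- j + 1L
  }
  NA_integer_
}

# parse a ring block starting at P$i; returns its ring-system index
.parse_block_at <- function(P) {
  jj <- .find_block_close(P$chars, P$i)
  if (is.na(jj))
    .perr(P, "RingParseError", "ring block is never closed by 'J'", P$i - 1L)
  text <- paste(P$chars[P$i:jj], collapse = "")
  block <- parse_ring_block(text)
  block$jpos <- jj - 1L - (P$i - 1L)        # J offset within the block
  rs <- assemble_ring_system(block)
  rs$jpos <- block$jpos
  idx <- .register_ring_system(P, rs, P$i - 1L)
  P$i <- jj + 1L
  idx
}

#' Parse a WLN string into a WLN graph
#'
#' Reads the string character by character, building nodes and bonds for
#' the acyclic notation and splicing in ring systems parsed from `L`/`T`/`D`
#' ... `J` blocks. Canonical (Rule 2) symbol ordering is not enforced.
#'
#' By default run-time error recovery is on: over-branched symbols with a
#' higher-degree same-element counterpart are raised (`M` to `N`) and
#' semantically impossible spaces (a frequent OCR fault) are skipped, each
#' with a diagnostic on standard error. `strict = TRUE` turns every
#' recovery into a `ParseError`.
#'
#' @param wln WLN string.
#' @param strict Disable run-time error recovery.
#' @return An object of class `wln_graph`: the node/edge environment plus
#'   parse metadata. Use [wln_to_table()] / [wln_convert()] downstream.
#' @examples
#' g <- parse_wln("Q1XGG2Y1Q1Z")
#' g$n  # 12 heavy-atom nodes
#' @export
parse_wln <- function(wln, strict = FALSE) {
  stopifnot(is.character(wln), length(wln) == 1L)
  P <- new.env(parent = emptyenv())
  P$mol <- .wln_new_mol()
  P$chars <- strsplit(wln, "", fixed = TRUE)[[1]]
  P$i <- 1L
  P$cur <- NA_integer_
  P$pending_u <- 0L
  P$stack <- integer(0)
  P$at_branch <- FALSE
  P$component <- 1L
  P$w_next <- NA_integer_
  P$ring_stack <- integer(0)               # entered ring systems, for '&' pops
  P$allow_new_root <- TRUE                 # start of string / ion component
  P$strict <- strict
  n <- length(P$chars)
  if (n == 0L) .perr(P, "ParseError", "empty WLN string", 0L)

  while (P$i <= n) {
    ch <- P$chars[P$i]
    nxt <- if (P$i < n) P$chars[P$i + 1L] else NA_character_

    if (ch %in% c("L", "T", "D") && is.na(P$cur) && P$pending_u == 0L) {
      if (!P$allow_new_root)
        .perr(P, "ParseError", "ring block cannot start after a closed branch")
      idx <- .parse_block_at(P)
      P$ring_stack <- c(P$ring_stack, idx)
      P$stack <- integer(0)
      P$at_branch <- FALSE
      P$allow_new_root <- FALSE
      next
    }
    if (ch == "R") {
      .attach_benzene(P)
      P$i <- P$i + 1L
      next
    }
    if (ch %in% .plain_atoms) {
      if (ch == "C" && P$pending_u > 0L)
        .perr(P, "ParseError",
              "'C' implies its own unsaturation; an adjacent explicit 'U' is disallowed")
      info <- .acyclic_atom_info(ch)
      id <- .attach_atom(P, ch, info, P$i - 1L)
      if (ch == "V") P$mol$carbonyl[id] <- TRUE
      P$i <- P$i + 1L
      next
    }
    if (ch == "W") {
      if (P$pending_u > 0L)
        .perr(P, "ParseError", "'W' cannot follow a dangling unsaturation")
      if (!is.na(P$cur))
        P$mol$pending_dioxo[P$cur] <- P$mol$pending_dioxo[P$cur] + 1L
      else P$w_next <- 1L                   # applies to the following atom
      P$i <- P$i + 1L
      next
    }
    if (ch == "U") {
      if (is.na(P$cur))
        .perr(P, "ParseError", "unsaturation 'U' has no parent atom")
      if (P$mol$char[P$cur] == "C" && P$pending_u == 0L)
        .perr(P, "ParseError",
              "'C' implies its own unsaturation; an adjacent explicit 'U' is disallowed")
      P$pending_u <- P$pending_u + 1L
      if (P$pending_u > 2L)
        .perr(P, "ParseError", "more than two consecutive 'U' (bond order above 3)")
      P$i <- P$i + 1L
      next
    }
    if (ch %in% as.character(0:9)) {
      run <- regmatches(x <- paste(P$chars[P$i:n], collapse = ""),
                        regexpr("^[0-9]+", x))
      len <- as.integer(run)
      if (len == 0L)
        .perr(P, "ParseError", "zero-length alkane chain '0' is not a compound")
      for (k in seq_len(len))
        .attach_atom(P, substr(run, 1L, 1L),
                     list(element = "C", capacity = 2L, charge = 0L,
                          fill = "hydrogen", must_unsat = FALSE,
                          terminating = FALSE),
                     P$i - 1L)
      P$i <- P$i + nchar(run)
      next
    }
    if (ch == "&") {
      .handle_amp(P)
      P$i <- P$i + 1L
      next
    }
    if (ch == " ") {
      .handle_space(P)
      next
    }
    if (ch == "-") {
      .handle_hyphen(P)
      next
    }
    if (ch == "J" || ch == "A")
      .perr(P, "ParseError",
            sprintf("'%s' is not valid in an acyclic context", ch))
    .perr(P, "UnknownSymbol", sprintf("unknown WLN character '%s'", ch))
  }

  if (P$pending_u > 0L)
    .perr(P, "ParseError", "unsaturation 'U' has no child atom", n - 1L)
  g <- P$mol
  g$source <- wln
  class(g) <- c("wln_graph", "environment")
  g
}

# '&' outside a space clause: pop one branching level, or pop back a ring
.handle_amp <- function(P) {
  if (P$pending_u > 0L)
    .perr(P, "ParseError", "'&' cannot follow a dangling unsaturation")
  if (P$at_branch && length(P$stack)) {
    top <- P$stack[length(P$stack)]
    P$mol$closed[top] <- TRUE
    P$stack <- P$stack[-length(P$stack)]
    .pop_to_open(P)
    return(invisible())
  }
  if (length(P$stack)) {
    .pop_to_open(P)
    return(invisible())
  }
  if (length(P$ring_stack) > 1L) {          # pop back to an earlier ring
    P$ring_stack <- P$ring_stack[-length(P$ring_stack)]
    P$cur <- NA_integer_
    P$at_branch <- FALSE
    return(invisible())
  }
  if (.raise_m(P, P$i - 1L)) return(invisible())
  .perr(P, "ParseError", "'&' pops an empty branch stack")
}

# benzene shorthand: a six-membered aromatic ring attached at position A
.attach_benzene <- function(P) {
  m <- P$mol
  pos <- P$i - 1L
  ord <- 1L + P$pending_u
  parent <- P$cur
  if (!is.na(parent) && (m$closed[parent] || m$used[parent] >= m$capacity[parent]))
    .perr(P, "ParseError", "cannot attach benzene ring 'R' here")
  ids <- vapply(1:6, function(k)
    .mol_add_atom(m, "R", pos, "C", 4L, ring_member = TRUE,
                  component = P$component), integer(1))
  for (k in 1:6) .mol_add_bond(m, ids[k], ids[k %% 6L + 1L], 1L)
  if (!is.na(parent)) .mol_add_bond(m, parent, ids[1], ord)
  P$pending_u <- 0L
  m$ring_systems[[length(m$ring_systems) + 1L]] <-
    list(path = ids, rings = list(ids), aromatic = TRUE, opener = "R",
         chelate = FALSE)
  P$ring_stack <- c(P$ring_stack, length(m$ring_systems))
  P$cur <- ids[1]
  P$at_branch <- FALSE
}

.cur_ring <- function(P) {
  if (!length(P$ring_stack)) return(NULL)
  P$mol$ring_systems[[P$ring_stack[length(P$ring_stack)]]]
}

# space: ion separator, macro-return clause, or ring-substituent locant
.handle_space <- function(P) {
  n <- length(P$chars)
  rest <- if (P$i < n) paste(P$chars[(P$i + 1L):n], collapse = "") else ""

  if (rest == "") {
    if (P$strict) .perr(P, "ParseError", "trailing space")
    .pwarn(P, "ignoring trailing space")
    P$i <- P$i + 1L
    return(invisible())
  }
  if (grepl("^&- ?[A-X]&*([0-9]+J|[LTD])", rest)) {
    # " &- ..." macro return or ring chain: the '&' is a genuine branch /
    # ring pop before the hyphen clause
    .handle_amp(P)
    P$i <- P$i + 2L
    return(invisible())
  }
  if (grepl("^&", rest)) {                  # new ion component
    P$i <- P$i + 2L
    P$cur <- NA_integer_
    P$stack <- integer(0)
    P$at_branch <- FALSE
    P$ring_stack <- integer(0)
    P$component <- P$component + 1L
    P$allow_new_root <- TRUE
    return(invisible())
  }
  first <- substr(rest, 1L, 1L)
  ring <- .cur_ring(P)
  if (grepl("^[A-X]", rest) && !is.null(ring)) {
    # ring-substituent clause: locant addresses the current ring's path
    m <- regmatches(rest, regexpr("^[A-X]&*", rest))
    base <- substr(rest, 1L, 1L)
    after1 <- substr(rest, 2L, nchar(rest))
    if (grepl("^&- ?[A-X]&*[LTD]", after1)) {
      # spiro clause " X&- YL...J": the locant branch character is an '&'
      # and the two rings share the atom at X
      idx <- locant_to_index(base)
      if (idx > length(ring$path))
        stop(wln_error("BadLocant",
                       sprintf("position %d: spiro locant %s off the ring path",
                               P$i, base), position = P$i))
      shared <- ring$path[idx]
      P$i <- P$i + 3L                       # space, locant, '&'; now at '-'
      rest2 <- paste(P$chars[P$i:length(P$chars)], collapse = "")
      mm <- regmatches(rest2, regexpr("^- ?[A-X]&*", rest2))
      loc2 <- regmatches(mm, regexpr("[A-X]&*", mm))
      P$i <- P$i + nchar(mm)
      ridx <- .parse_block_at(P)
      P$ring_stack <- c(P$ring_stack, ridx)
      newring <- P$mol$ring_systems[[ridx]]
      idx2 <- locant_to_index(loc2)
      if (idx2 > length(newring$path))
        stop(wln_error("BadLocant", sprintf("spiro locant %s off the chained ring path", loc2)))
      .mol_merge_atoms(P$mol, shared, newring$path[idx2])
      P$cur <- NA_integer_
      P$stack <- integer(0)
      P$at_branch <- FALSE
      return(invisible())
    }
    idx <- locant_to_index(m)
    if (idx > length(ring$path))
      stop(wln_error("BadLocant",
                     sprintf("position %d: locant %s exceeds the %d-atom ring path",
                             P$i, m, length(ring$path)), position = P$i))
    P$cur <- ring$path[idx]
    P$stack <- integer(0)
    P$at_branch <- FALSE
    P$i <- P$i + 1L + nchar(m)
    return(invisible())
  }
  # a space that makes no semantic sense here: OCR recovery skips it
  if (P$strict) .perr(P, "ParseError",
                      sprintf("space before '%s' makes no semantic sense", first))
  .pwarn(P, sprintf("skipping space before '%s' (no semantic sense)", first))
  P$i <- P$i + 1L
  invisible()
}

# '-': element code, chained/spiro ring, or macro-return bond
.handle_hyphen <- function(P) {
  n <- length(P$chars)
  rest <- paste(P$chars[P$i:n], collapse = "")
  m <- regmatches(rest, regexpr("^-[A-Z]{1,2}-", rest))
  if (length(m) && !grepl("^- ", rest)) {   # element code -XX- / hypervalent -X-
    code <- gsub("-", "", m)
    if (nchar(code) == 1L) {
      el <- .wln_core_element[[code]] %||% NA_character_
      if (is.na(el) || el == "")
        stop(wln_error("UnknownElement",
                       sprintf("position %d: '%s' has no element meaning", P$i - 1L, m),
                       position = P$i - 1L))
      info <- list(element = el, capacity = 6L, charge = 0L,
                   fill = "hydrogen", must_unsat = FALSE, terminating = FALSE)
    } else {
      el <- .element_from_code(code)
      if (is.na(el))
        stop(wln_error("UnknownElement",
                       sprintf("position %d: unknown element code '%s'", P$i - 1L, m),
                       position = P$i - 1L))
      info <- list(element = el,
                   capacity = max(.std_valences[[el]] %||% 8L), charge = 0L,
                   fill = "hydrogen", must_unsat = FALSE, terminating = FALSE)
    }
    .attach_atom(P, m, info, P$i - 1L)
    P$i <- P$i + nchar(m)
    return(invisible())
  }
  mm <- regmatches(rest, regexpr("^- ?[A-X]&*", rest))
  if (length(mm)) {
    loc <- regmatches(mm, regexpr("[A-X]&*", mm))
    idx <- locant_to_index(loc)
    after <- substr(rest, nchar(mm) + 1L, nchar(rest))
    if (grepl("^[0-9]+J", after)) {
      # macro return: bond the pending branch back onto the current ring
      ring <- .cur_ring(P)
      if (is.null(ring))
        .perr(P, "RingParseError", "macro return with no open ring system")
      if (idx > length(ring$path))
        stop(wln_error("BadLocant",
                       sprintf("position %d: macro-return locant %s off the ring path",
                               P$i - 1L, loc), position = P$i - 1L))
      if (is.na(P$cur))
        .perr(P, "ParseError", "macro return with no pending branch")
      size <- as.integer(regmatches(after, regexpr("^[0-9]+", after)))
      target <- ring$path[idx]
      .mol_add_bond(P$mol, P$cur, target, 1L + P$pending_u)
      P$pending_u <- 0L
      cyc <- .mol_shortest_path(P$mol, P$cur, target)
      # the declared size counts the ring the return bond completes
      if (!is.null(cyc) && length(cyc) != size)
        .pwarn(P, sprintf("macro return declares a %d-ring but closes a %d-ring",
                          size, length(cyc)))
      P$i <- P$i + nchar(mm) + nchar(regmatches(after, regexpr("^[0-9]+J", after)))
      .pop_to_open(P)
      return(invisible())
    }
    if (grepl("^[LTD]", after)) {
      # chained ring: new block attached at *its* locant `loc`
      parent <- P$cur
      ord <- 1L + P$pending_u
      P$pending_u <- 0L
      P$i <- P$i + nchar(mm)
      ridx <- .parse_block_at(P)
      P$ring_stack <- c(P$ring_stack, ridx)
      ring <- P$mol$ring_systems[[ridx]]
      if (idx > length(ring$path))
        stop(wln_error("BadLocant", sprintf("locant %s off the chained ring path", loc)))
      if (!is.na(parent)) .mol_add_bond(P$mol, parent, ring$path[idx], ord)
      P$cur <- NA_integer_
      P$stack <- integer(0)
      P$at_branch <- FALSE
      return(invisible())
    }
    .perr(P, "ParseError",
          sprintf("expected a ring block or macro-return size after '%s'", mm))
  }
  .perr(P, "ParseError", "dangling '-'")
}
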