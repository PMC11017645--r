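# Cyclic WLN: ring-block parsing, fused/multicyclic assembly and locant
# paths.
#
# A ring block is the text between an opener (L carbocycle, T heterocycle,
# D chelate) and its closing J. Inside, sub-ring sizes are cited with
# optional fuse locants; digit-led clauses declare multicyclic points,
# followed by the system size as a locant; further clauses place
# heteroatoms, unsaturations, bridges and crossed bonds; trailing '&'/'T'
# marks give per-ring aromatic/aliphatic status.
#
# Assembly model: the locant path A, B, C, ... is grown ring by ring. Each
# cited ring (locant l, size s) reaches the current path end through the
# shortest existing route from l, appends the new atoms it needs, and
# closes back onto the consecutive-locant segment starting at l. The
# closure offset along that segment is not always zero (perifused and
# multicyclic systems need it), so it is chosen by a small backtracking
# search constrained by the declared multicyclic points and system size:
# every declared point must end up shared by three or more sub-rings, every
# other atom by at most two, and the atom count must equal the size locant.

.ring_hetero_chars <- c("B", "C", "K", "M", "N", "O", "P", "S", "V",
                        "X", "Y", "H")

#' Parse the text of a WLN ring block
#'
#' @param block Full block text including the opener and the closing `J`,
#'   e.g. `"L C666J"` or `"T6NJ"`.
#' @return An object of class `ring_block`: a list with `opener`, `macro`,
#'   `citations` (locant + size per sub-ring), `multicyclic` (locants),
#'   `size_locant`, `heteros` (position/element/extras), `unsats`,
#'   `bridges`, `crossed`, `aromatic` (per-ring flags, TRUE = aromatic).
#' @examples
#' parse_ring_block("L C666J")$citations
#' @export
parse_ring_block <- function(block) {
  if (!grepl("^[LTD]", block) || !grepl("J$", block))
    stop(wln_error("RingParseError",
                   sprintf("ring block must open with L, T or D and close with J: '%s'", block),
                   position = nchar(block) - 1L))
  opener <- substr(block, 1L, 1L)
  body <- substr(block, 2L, nchar(block) - 1L)
  jpos <- nchar(block) - 1L                 # 0-based offset of the closing J
  rerr <- function(msg) stop(wln_error("RingParseError",
                                       sprintf("%s (ring closed at J, position %d)", msg, jpos),
                                       position = jpos))

  macro <- FALSE
  if (grepl("^-[LTD]", body)) {            # embedded macrocyclic opener T-T...
    macro <- TRUE
    opener <- substr(body, 2L, 2L)
    body <- substr(body, 3L, nchar(body))
  }

  # collect trailing aromaticity flags (scan backwards over '&', 'T', ' ')
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  k <- length(chars)
  while (k >= 1L && chars[k] %in% c("&", "T", " ")) k <- k - 1L
  # a 'T' directly after 'U' belongs to the flag run's boundary decision:
  # flags begin after the last non-flag character, which the loop found
  flag_chars <- chars[seq_len(length(chars))[-seq_len(k)]]
  flag_chars <- flag_chars[flag_chars != " "]
  aromatic_flags <- if (length(flag_chars)) flag_chars == "&" else logical(0)
  body <- paste(chars[seq_len(k)], collapse = "")

  clauses <- strsplit(body, " ", fixed = TRUE)[[1]]
  clauses <- clauses[nzchar(clauses)]

  citations <- list()
  heteros <- list()    # list(pos =, element =, char =)
  unsats <- list()     # list(from =, to = NA or locant index, order_add =)
  dioxo <- integer(0)  # positions receiving a W dioxo pair
  bridges <- integer(0)
  crossed <- list()
  multicyclic <- integer(0)
  size_locant <- NA_integer_
  expect_size <- FALSE
  in_citations <- TRUE
  pointer <- 1L                              # next implied hetero position
  last_named <- 1L                           # position U / W refer to
  pending_partner <- FALSE                   # explicit bond target ("XU- Y")

  take_locant <- function(s) {               # returns list(idx, rest)
    m <- regmatches(s, regexpr("^[A-X]&*", s))
    if (!length(m)) return(NULL)
    list(idx = locant_to_index(m), rest = substr(s, nchar(m) + 1L, nchar(s)))
  }

  parse_hetero_seq <- function(s) {
    # sequence of element letters / U / W / -XX- codes; a locant points at
    # the position the next element fills, each placed element advances the
    # implied position by one
    while (nzchar(s)) {
      ch <- substr(s, 1L, 1L)
      if (ch == "-") {
        if (grepl("^-$", s)) {               # explicit-target continuation
          pending_partner <<- TRUE
          s <- ""
          next
        }
        m <- regmatches(s, regexpr("^-[A-Z]{1,2}-", s))
        if (!length(m)) rerr(sprintf("malformed element code in ring clause '%s'", s))
        el <- .element_from_code(gsub("-", "", m))
        if (is.na(el)) stop(wln_error("UnknownElement",
                                      sprintf("unknown element code '%s'", m)))
        heteros[[length(heteros) + 1L]] <<- list(pos = pointer, element = el, char = m)
        last_named <<- pointer
        pointer <<- pointer + 1L
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (ch == "U") {
        n <- attr(regexpr("^U+", s), "match.length")
        unsats[[length(unsats) + 1L]] <<- list(from = last_named, to = NA_integer_,
                                               order_add = n)
        s <- substr(s, n + 1L, nchar(s))
      } else if (ch == "W") {
        dioxo <<- c(dioxo, last_named)
        s <- substr(s, 2L, nchar(s))
      } else if (ch %in% .ring_hetero_chars) {
        heteros[[length(heteros) + 1L]] <<- list(pos = pointer, element = NA, char = ch)
        last_named <<- pointer
        pointer <<- pointer + 1L
        s <- substr(s, 2L, nchar(s))
      } else {
        rerr(sprintf("unexpected character '%s' in ring clause", ch))
      }
    }
  }

  first_clause <- TRUE
  for (cl in clauses) {
    is_first <- first_clause
    first_clause <- FALSE
    if (pending_partner) {
      # this clause starts with the explicit target of the previous 'U-'
      tk <- take_locant(cl)
      if (is.null(tk)) rerr("expected a locant after 'U-'")
      unsats[[length(unsats)]]$to <- tk$idx
      pending_partner <- FALSE
      if (nzchar(tk$rest)) parse_hetero_seq(tk$rest)
      next
    }
    # a digit-led clause is a multicyclic declaration unless it opens the
    # block (the first clause is always a size citation, e.g. "6N" = pyridine)
    if (!is_first && grepl("^[0-9]+[A-X]", cl)) {
      m <- regmatches(cl, regexpr("^[0-9]+", cl))
      cnt <- as.integer(m)
      rest <- substr(cl, nchar(m) + 1L, nchar(cl))
      locs <- regmatches(rest, gregexpr("[A-X]&*", rest))[[1]]
      if (length(locs) != cnt)
        rerr(sprintf("multicyclic clause '%s' declares %d points but lists %d",
                     cl, cnt, length(locs)))
      multicyclic <- vapply(locs, locant_to_index, integer(1), USE.NAMES = FALSE)
      expect_size <- TRUE
      in_citations <- FALSE
      next
    }
    if (grepl("^[0-9]+/[A-X]&*[A-X]&*$", cl)) {  # crossed bond "6/BE"
      m <- regmatches(cl, regexpr("^[0-9]+", cl))
      locs <- regmatches(cl, gregexpr("[A-X]&*", cl))[[1]]
      crossed[[length(crossed) + 1L]] <-
        list(size = as.integer(m),
             from = locant_to_index(locs[1]), to = locant_to_index(locs[2]))
      in_citations <- FALSE
      next
    }
    if (in_citations && grepl("^([A-X]&*)?([0-9]|-[0-9]+-)", cl)) {
      # citation clause: optional fuse locant, then sub-ring sizes; trailing
      # letters are heteroatoms at implied positions (e.g. "6N" in T6NJ)
      s <- cl
      tk <- take_locant(s)
      first_loc <- NA_integer_
      if (!is.null(tk) && grepl("^([0-9]|-[0-9]+-)", tk$rest)) {
        first_loc <- tk$idx
        s <- tk$rest
      }
      while (grepl("^([0-9]|-[0-9]+-)", s)) {
        m <- regmatches(s, regexpr("^-[0-9]+-|^[0-9]", s))
        size <- as.integer(gsub("-", "", m))
        loc <- if (!is.na(first_loc)) first_loc else 1L
        first_loc <- NA_integer_
        if (size < 3L) rerr(sprintf("sub-ring size %d is impossible", size))
        citations[[length(citations) + 1L]] <- list(loc = loc, size = size)
        s <- substr(s, nchar(m) + 1L, nchar(s))
      }
      if (nzchar(s)) parse_hetero_seq(s)
      next
    }
    in_citations <- FALSE
    if (grepl("^[A-X]&*$", cl)) {            # lone locant
      if (expect_size) {
        size_locant <- locant_to_index(cl)
        expect_size <- FALSE
      } else {
        bridges <- c(bridges, locant_to_index(cl))
      }
      next
    }
    expect_size <- FALSE
    # hetero/unsaturation clause: leading letter after a space is a locant
    tk <- take_locant(cl)
    if (is.null(tk)) rerr(sprintf("cannot interpret ring clause '%s'", cl))
    pointer <- tk$idx
    last_named <- tk$idx
    parse_hetero_seq(tk$rest)
  }

  if (!length(citations)) rerr("ring block cites no sub-ring sizes")
  structure(list(opener = opener, macro = macro, citations = citations,
                 multicyclic = multicyclic, size_locant = size_locant,
                 heteros = heteros, unsats = unsats, dioxo = dioxo,
                 bridges = bridges, crossed = crossed,
                 aromatic = aromatic_flags, text = block, jpos = jpos),
            class = "ring_block")
}

# ---------------------------------------------------------------------------
# assembly ------------------------------------------------------------------

# shortest paths between a and b over an edge list (indices into 1..n);
# returns list of atom index vectors (all shortest routes, depth-first order)
.all_shortest_paths <- function(edges, n, a, b) {
  if (a == b) return(list(a))
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  dist <- rep(NA_integer_, n); dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
  }
  if (is.na(dist[b])) return(list())
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in sort(adj[[v]])) {
      if (!is.na(dist[w]) && dist[w] == dist[v] + 1L) walk(c(path, w))
    }
  }
  walk(a)
  out
}

#' Assemble a fused ring system from a parsed ring block
#'
#' Runs the citation-by-citation construction with a backtracking choice of
#' each ring's closure offset, validated against the declared multicyclic
#' points and system size (see the file header for the model).
#'
#' @param block A `ring_block` from [parse_ring_block()].
#' @return List with `n` (atom count), `edges` (two-column matrix of path /
#'   closure bonds in locant-index space), `rings` (list of atom index
#'   vectors in cycle order), `aromatic` (per-ring logical), plus the
#'   heteroatom/unsaturation/bridge annotations carried through.
#' @export
assemble_ring_system <- function(block) {
  cites <- block$citations
  nr <- length(cites)
  rerr <- function(msg) stop(wln_error("RingParseError",
                                       sprintf("%s (ring closed at J, position %d)", msg, block$jpos),
                                       position = block$jpos))

  solve <- function(i, natoms, edges, rings) {
    if (i > nr) {
      share <- integer(natoms)
      for (r in rings) share[r] <- share[r] + 1L
      if (any(share == 0L)) return(NULL)
      if (!is.na(block$size_locant) && natoms != block$size_locant) return(NULL)
      mc <- block$multicyclic
      if (length(mc)) {
        if (any(mc > natoms)) return(NULL)
        if (any(share[mc] < 3L)) return(NULL)
        if (any(share[setdiff(seq_len(natoms), mc)] > 2L)) return(NULL)
      } else {
        if (any(share > 2L)) return(NULL)
      }
      return(list(n = natoms, edges = edges, rings = rings))
    }
    l <- cites[[i]]$loc; s <- cites[[i]]$size
    if (i == 1L) {
      # seed the path up to the first ring's fuse locant
      if (natoms < l) {
        for (a in seq.int(natoms + 1L, l)) {
          if (a > 1L) edges <- rbind(edges, c(a - 1L, a))
        }
        natoms <- l
      }
    }
    if (l > natoms) return(NULL)
    end <- natoms
    sps <- .all_shortest_paths(edges, natoms, l, end)
    if (!length(sps)) sps <- list(l)         # empty graph start: path is just l
    for (sp in sps) {
      d <- length(sp) - 1L
      for (t in 0:(s - 2L)) {
        nnew <- s - t - d - 1L
        if (nnew < 0L) next
        tgt <- l + t
        if (tgt > natoms) next
        seg <- if (t > 0L) seq.int(l, tgt) else l
        ring_atoms <- unique(c(rev(seg), sp,
                               if (nnew > 0L) seq.int(end + 1L, end + nnew)))
        if (length(ring_atoms) != s) next
        if (t > 0L && any(seg[-1] %in% sp)) next
        e2 <- edges
        if (nnew > 0L) {
          for (a in seq.int(end + 1L, end + nnew)) e2 <- rbind(e2, c(a - 1L, a))
          e2 <- rbind(e2, c(end + nnew, tgt))
        } else {
          if (end == tgt) next
          e2 <- rbind(e2, c(end, tgt))
        }
        res <- solve(i + 1L, natoms + nnew, e2,
                     c(rings, list(ring_atoms)))
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }

  sol <- solve(1L, 0L, matrix(integer(0), 0, 2), list())
  if (is.null(sol))
    rerr("no ring assembly satisfies the cited sizes, multicyclic points and system size")

  # crossed bonds add explicit ring-closing bonds between two locants
  for (cx in block$crossed) {
    if (cx$from > sol$n || cx$to > sol$n) rerr("crossed-bond locant off the path")
    sol$edges <- rbind(sol$edges, c(cx$from, cx$to))
    cyc <- .shortest_cycle_through(sol$edges, sol$n, cx$from, cx$to)
    if (!is.null(cyc)) sol$rings <- c(sol$rings, list(cyc))
  }
  # bridges: the cited position bonds back to the end of the path
  for (b in block$bridges) {
    if (b > sol$n) rerr("bridge locant off the path")
    sol$edges <- rbind(sol$edges, c(b, sol$n))
  }

  aro <- block$aromatic
  nring <- length(sol$rings)
  aromatic <- if (!length(aro)) rep(TRUE, nring)
              else if (length(aro) == 1L) rep(aro, nring)
              else rep_len(aro, nring)

  list(n = sol$n, edges = sol$edges, rings = sol$rings, aromatic = aromatic,
       heteros = block$heteros, unsats = block$unsats, dioxo = block$dioxo,
       bridges = block$bridges, opener = block$opener, macro = block$macro,
       jpos = block$jpos)
}

# smallest cycle through the edge (a, b): shortest a-b path avoiding that edge
.shortest_cycle_through <- function(edges, n, a, b) {
  keep <- !(pmin(edges[, 1], edges[, 2]) == min(a, b) &
            pmax(edges[, 1], edges[, 2]) == max(a, b))
  sps <- .all_shortest_paths(edges[keep, , drop = FALSE], n, a, b)
  if (!length(sps)) return(NULL)
  sps[[1]]
}

# ---------------------------------------------------------------------------
# locant paths --------------------------------------------------------------

#' Derive the canonical locant path of a ring system
#'
#' The locant path visits each ring atom exactly once (a Hamiltonian path).
#' Its start is an atom sharing the most sub-rings (a perifused or
#' multicyclic centre takes priority); from a multicyclic atom with an
#' unvisited adjacent multicyclic atom the path must pass through it; ties
#' are broken by minimizing the locant sum of ring-shared atoms.
#'
#' The path walks the ring perimeter: ring-closure chords (the fuse bonds
#' the notation creates when a cited ring closes back onto the path) are
#' not traversable, which is this package's concrete reading of the rule
#' that the path never crosses a fuse junction except to reach a
#' multicyclic point. Assembly produces atoms already in locant order, so
#' on assembled systems this is a validation and numbering tool.
#'
#' @param system Either a `ring_block` or the result of
#'   [assemble_ring_system()].
#' @param max_exhaustive Size limit for the exhaustive search.
#' @return List with `path` (atom indices in locant order), `share`
#'   (sub-ring count per atom) and `locant_sum`; or an error of class
#'   `NoLocantPath` when no Hamiltonian path exists.
#' @export
build_locant_path <- function(system, max_exhaustive = 16L) {
  if (inherits(system, "ring_block")) system <- assemble_ring_system(system)
  n <- system$n
  share <- integer(n)
  for (r in system$rings) share[r] <- share[r] + 1L
  multi <- share >= 3L
  adj <- vector("list", n)
  for (k in seq_len(nrow(system$edges))) {
    a <- system$edges[k, 1]; b <- system$edges[k, 2]
    if (abs(a - b) != 1L) next              # closure chords are not walkable
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  score <- function(path) {
    pos <- integer(n); pos[path] <- seq_len(n)
    sum(pos[share >= 2L])
  }
  if (n > max_exhaustive) {
    return(list(path = seq_len(n), share = share,
                locant_sum = score(seq_len(n)), exhaustive = FALSE))
  }
  starts <- which(share == max(share))
  best <- NULL; best_score <- Inf
  walk <- function(path, seen) {
    if (length(path) == n) {
      sc <- score(path)
      if (sc < best_score) { best <<- path; best_score <<- sc }
      return(invisible())
    }
    v <- path[length(path)]
    nxt <- adj[[v]][!seen[adj[[v]]]]
    if (multi[v] && any(multi[nxt])) nxt <- nxt[multi[nxt]]   # forced through
    for (w in sort(nxt)) {
      seen[w] <- TRUE; walk(c(path, w), seen); seen[w] <- FALSE
    }
  }
  for (s0 in starts) {
    seen <- logical(n); seen[s0] <- TRUE
    walk(s0, seen)
  }
  if (is.null(best))
    stop(wln_error("NoLocantPath",
                   "ring system admits no Hamiltonian locant path; branch/macro notation required"))
  list(path = best, share = share, locant_sum = best_score, exhaustive = TRUE)
}
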