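# From WLN graph to chemistry: shorthand expansion, implied unsaturation,
# kekulization by maximum matching, and the connection table.

#' Expand WLN shorthand symbols into explicit atoms
#'
#' Materializes what the condensed symbols imply: `V` gains its carbonyl
#' oxygen, `W` adds two double-bonded oxygens to its adjacent atom, unused
#' branch slots on `X`, `Y` and `K` are filled with methyl groups, and
#' explicit `H` nodes are folded into their neighbour's hydrogen count.
#' `Q`, `Z`, `M` need no extra atoms: their implied hydrogens follow from
#' standard valence at connection-table time.
#'
#' @param g A `wln_graph` from [parse_wln()]; modified in place and
#'   returned.
#' @return The expanded graph.
#' @export
expand_shorthand <- function(g) {
  # V carbonyl oxygens
  for (a in which(g$carbonyl[seq_len(g$n)])) {
    o <- .mol_add_atom(g, "V=O", g$pos[a], "O", 1L, component = g$component[a])
    .mol_add_bond(g, a, o, 2L)
    g$no_double[o] <- TRUE
  }
  # W dioxo pairs
  for (a in which(g$pending_dioxo[seq_len(g$n)] > 0L)) {
    k <- g$pending_dioxo[a]
    vals <- .std_valences[[g$element[a]]]
    if (!is.null(vals) &&
        .mol_order_sum(g, a) + 4L * k > max(vals) + abs(g$charge[a]))
      stop(wln_error("ValenceError",
                     sprintf("position %d: '%s' cannot accept %d double-bonded oxygens",
                             g$pos[a], g$element[a], 2L * k), position = g$pos[a]))
    for (j in seq_len(2L * k)) {
      o <- .mol_add_atom(g, "W=O", g$pos[a], "O", 1L, component = g$component[a])
      .mol_add_bond(g, a, o, 2L)
      g$no_double[o] <- TRUE
    }
    g$no_double[a] <- TRUE
  }
  # implied methyl fills on X, Y, K
  for (a in which(g$fill[seq_len(g$n)] == "methyl")) {
    while (g$used[a] < g$capacity[a]) {
      c <- .mol_add_atom(g, "fill", g$pos[a], "C", 1L, component = g$component[a])
      .mol_add_bond(g, a, c, 1L)
    }
  }
  # fold explicit hydrogens into their neighbour
  if (is.null(g$extra_h)) g$extra_h <- integer(g$n)
  length(g$extra_h) <- g$n
  g$extra_h[is.na(g$extra_h)] <- 0L
  for (a in which(g$char[seq_len(g$n)] == "H")) {
    nb <- .mol_neighbors(g, a)
    if (length(nb) == 1L) {
      k <- .mol_bond_index(g, a, nb)
      if (g$bond_order[k] != 1L)
        stop(wln_error("ValenceError",
                       sprintf("position %d: hydrogen cannot take a multiple bond", g$pos[a]),
                       position = g$pos[a]))
      g$bond_order[k] <- 0L                 # dead bond, dropped at table time
      g$element[a] <- NA_character_
      g$extra_h[nb] <- g$extra_h[nb] + 1L
    }
  }
  g
}

#' Resolve implied double bonds
#'
#' With `implied = TRUE` (the historical default) adjacent `O` symbols
#' imply a double bond (`OO` is dioxygen, not peroxide) and every `C`
#' symbol is raised to full valence with at least one unsaturated bond
#' (`SCN` gains its C#N triple). With `implied = FALSE` bonds stay single;
#' unfilled valence on `O` symbols is read as negative charge (the
#' peroxide ion reading) and elsewhere as implicit hydrogen.
#'
#' @param g Expanded `wln_graph`.
#' @param implied Apply the implied-double-bond conventions.
#' @return The graph, with `implied` recorded for table building.
#' @export
apply_implied_unsaturation <- function(g, implied = TRUE) {
  g$implied <- implied
  if (!implied) return(g)
  free_val <- function(a) {
    vals <- .std_valences[[g$element[a]]]
    if (is.null(vals)) return(0L)
    s <- .mol_order_sum(g, a)
    fit <- vals[vals >= s]
    if (!length(fit)) return(0L)
    fit[1] - s
  }
  # adjacent O-O implies a double bond
  for (k in seq_along(g$bond_from)) {
    a <- g$bond_from[k]; b <- g$bond_to[k]
    if (g$bond_order[k] == 1L && g$char[a] == "O" && g$char[b] == "O" &&
        !g$ring_member[a] && !g$ring_member[b] &&
        free_val(a) >= 1L && free_val(b) >= 1L) {
      g$bond_order[k] <- 2L
    }
  }
  # the 'C' symbol forces a full-valence carbon with unsaturated bonding
  for (a in which(g$must_unsat[seq_len(g$n)])) {
    deficit <- 4L - .mol_order_sum(g, a)
    if (deficit > 0L) {
      nb <- .mol_neighbors(g, a)
      # heteroatom partners take the implied unsaturation first (SC#N), then
      # later-written neighbours; free valence decides feasibility only
      is_c <- g$element[nb] == "C"
      nb <- nb[order(is_c, -vapply(nb, free_val, integer(1)), -nb)]
      for (b in nb) {
        if (deficit <= 0L) break
        raise <- min(deficit, free_val(b), 2L)
        if (raise > 0L) {
          k <- .mol_bond_index(g, a, b)
          g$bond_order[k] <- g$bond_order[k] + raise
          deficit <- deficit - raise
        }
      }
      if (deficit > 0L && length(nb) > 0L)
        stop(wln_error("ValenceError",
                       sprintf("position %d: no legal bond-order assignment fills the 'C' symbol",
                               g$pos[a]), position = g$pos[a]))
    }
  }
  g
}

# ---------------------------------------------------------------------------
# maximum matching (Edmonds' blossom algorithm) ------------------------------

#' Maximum matching in a general graph
#'
#' Augmenting-path search with blossom contraction; on bipartite inputs the
#' contraction step simply never fires. Used for kekulization, where the
#' number of double bonds placed in an aromatic ring system is the size of
#' a maximum matching over the atoms that can still take one.
#'
#' @param n Number of vertices.
#' @param edges Two-column matrix of undirected edges (1-based).
#' @return Integer vector `match` of length `n`; `match[v]` is the partner
#'   of `v`, or 0 if unmatched.
#' @export
max_matching <- function(n, edges) {
  match <- integer(n)
  if (n == 0L || is.null(edges) || nrow(edges) == 0L) return(match)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  p <- integer(n)
  base <- seq_len(n)
  used <- logical(n)
  blossom <- logical(n)

  lca <- function(a, b) {
    seen <- logical(n)
    a <- base[a]
    repeat {
      seen[a] <- TRUE
      if (match[a] == 0L) break
      a <- base[p[match[a]]]
    }
    b <- base[b]
    repeat {
      if (seen[b]) return(b)
      b <- base[p[match[b]]]
    }
  }
  mark_path <- function(v, b, child) {
    while (base[v] != b) {
      blossom[base[v]] <<- TRUE
      blossom[base[match[v]]] <<- TRUE
      p[v] <<- child
      child <- match[v]
      v <- p[match[v]]
    }
  }
  find_path <- function(root) {
    used <<- logical(n)
    p <<- integer(n)
    base <<- seq_len(n)
    used[root] <<- TRUE
    q <- root
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (to in adj[[v]]) {
        if (base[v] == base[to] || match[v] == to) next
        if (to == root || (match[to] != 0L && p[match[to]] != 0L)) {
          curbase <- lca(v, to)
          blossom <<- logical(n)
          mark_path(v, curbase, to)
          mark_path(to, curbase, v)
          for (i in seq_len(n)) {
            if (blossom[base[i]]) {
              base[i] <<- curbase
              if (!used[i]) { used[i] <<- TRUE; q <- c(q, i) }
            }
          }
        } else if (p[to] == 0L) {
          p[to] <<- v
          if (match[to] == 0L) {
            u <- to
            while (u != 0L) {
              pv <- p[u]; ppv <- match[pv]
              match[u] <<- pv
              match[pv] <<- u
              u <- ppv
            }
            return(TRUE)
          }
          used[match[to]] <<- TRUE
          q <- c(q, match[to])
        }
      }
    }
    FALSE
  }
  for (v in seq_len(n)) if (match[v] == 0L) find_path(v)
  match
}

# brute-force maximum matching size by recursion over the edge list; the
# independent oracle for small ring systems
.matching_bruteforce <- function(n, edges) {
  m <- if (is.null(edges)) 0L else nrow(edges)
  best <- 0L
  recurse <- function(k, used, count) {
    if (count + (m - k + 1L) <= best) return(invisible())
    if (k > m) { best <<- max(best, count); return(invisible()) }
    a <- edges[k, 1]; b <- edges[k, 2]
    if (!used[a] && !used[b]) {
      used[a] <- used[b] <- TRUE
      recurse(k + 1L, used, count + 1L)
      used[a] <- used[b] <- FALSE
    }
    recurse(k + 1L, used, count)
    invisible()
  }
  recurse(1L, logical(n), 0L)
  best
}

#' Kekulize aromatic-flagged ring systems
#'
#' WLN aromaticity is relaxed: a cycle is aromatic if, after heteroatom
#' assignment, it carries the maximum number of double bonds that can be
#' placed; the Hueckel 4n+2 count is not consulted. Eligible ring atoms
#' (a free valence slot, not barred by their symbol: `M`, ring `O`/`S`,
#' carbonyl `V`, indicated-hydrogen positions are barred) are matched over
#' the ring bonds; matched bonds become double, unmatched atoms keep their
#' implicit hydrogens.
#'
#' @param g Expanded, unsaturation-resolved `wln_graph`.
#' @param shuffle Optional permutation seed used by tests to confirm the
#'   canonical output is invariant to matching tie-breaks.
#' @return The graph with kekulized bond orders.
#' @export
kekulize <- function(g, shuffle = NULL) {
  free_val <- function(a) {
    vals <- .std_valences[[g$element[a]]]
    if (is.null(vals)) return(0L)
    s <- .mol_order_sum(g, a) + (g$extra_h %||% integer(g$n))[a]
    eff <- vals + if (g$element[a] %in% c("N", "P")) g$charge[a] else 0L
    fit <- eff[eff >= s]
    if (!length(fit)) return(0L)
    fit[1] - s
  }
  for (rs in g$ring_systems) {
    arom <- rep_len(rs$aromatic, length(rs$rings))
    ring_atoms <- unique(unlist(rs$rings[arom]))
    if (!length(ring_atoms)) next
    eligible <- ring_atoms[!g$no_double[ring_atoms] &
                           vapply(ring_atoms, free_val, integer(1)) >= 1L]
    # candidate edges: order-1 ring bonds between eligible atoms
    ks <- which(g$bond_order == 1L &
                g$bond_from %in% eligible & g$bond_to %in% eligible)
    # keep only bonds lying in an aromatic-flagged ring of this system
    in_ring <- vapply(ks, function(k) {
      any(vapply(rs$rings[arom], function(r)
        g$bond_from[k] %in% r && g$bond_to[k] %in% r, logical(1)))
    }, logical(1))
    ks <- ks[in_ring]
    if (!length(ks)) next
    verts <- sort(unique(c(g$bond_from[ks], g$bond_to[ks])))
    vid <- match(seq_len(g$n), verts)
    edges <- cbind(vid[g$bond_from[ks]], vid[g$bond_to[ks]])
    if (!is.null(shuffle)) {
      perm <- sample(nrow(edges))
      edges <- edges[perm, , drop = FALSE]
      ks <- ks[perm]
    }
    mt <- max_matching(length(verts), edges)
    for (j in seq_along(ks)) {
      a <- edges[j, 1]; b <- edges[j, 2]
      if (mt[a] == b) {
        g$bond_order[ks[j]] <- 2L
        mt[a] <- 0L; mt[b] <- 0L           # each matched pair used once
      }
    }
  }
  g
}

#' Build the final connection table
#'
#' @param g Fully processed `wln_graph`.
#' @return A list of class `connection_table`: `atoms` (data.frame with
#'   element, charge, implicit hydrogens, ring membership, component,
#'   source position) and `bonds` (from/to/order in atom-table indices).
#' @export
build_connection_table <- function(g) {
  live <- which(!is.na(g$element[seq_len(g$n)]) & g$element[seq_len(g$n)] != "")
  idx <- match(seq_len(g$n), live)
  extra <- g$extra_h %||% integer(g$n)
  length(extra) <- g$n; extra[is.na(extra)] <- 0L
  implied <- !isFALSE(g$implied)
  atoms <- lapply(live, function(a) {
    s <- .mol_order_sum(g, a)
    charge <- g$charge[a]
    if (!implied && g$char[a] == "O" && s < 2L) charge <- s - 2L
    h <- .implicit_h(g$element[a], charge, s)
    if (is.na(h)) {
      if (g$element[a] %in% c("C", "O", "F", "Cl", "Br", "I", "H"))
        stop(wln_error("ValenceError",
                       sprintf("position %d: atom '%s' (%s) exceeds its valence",
                               g$pos[a], g$char[a], g$element[a]),
                       position = g$pos[a]))
      h <- 0L
    }
    h <- max(h, extra[a])
    data.frame(element = g$element[a], charge = charge, hcount = h,
               ring = g$ring_member[a], component = g$component[a],
               pos = g$pos[a], stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, atoms)
  keep <- which(g$bond_order > 0L & !is.na(idx[g$bond_from]) & !is.na(idx[g$bond_to]))
  bonds <- data.frame(from = idx[g$bond_from[keep]], to = idx[g$bond_to[keep]],
                      order = g$bond_order[keep])
  structure(list(atoms = atoms, bonds = bonds,
                 n_components = length(unique(atoms$component))),
            class = "connection_table")
}
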