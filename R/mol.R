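# Mutable molecular-graph builder used by the parser, plus element data.
#
# The WLN graph is held in an environment for O(1) in-place updates while
# the string is read character by character; it is frozen into plain lists
# / data.frames when handed to the assembler.

.wln_new_mol <- function() {
  m <- new.env(parent = emptyenv())
  m$n <- 0L
  m$char <- character(0)       # source WLN character
  m$pos <- integer(0)          # 0-based source offset
  m$element <- character(0)
  m$charge <- integer(0)
  m$capacity <- integer(0)     # WLN degree: max allowed branches (connections)
  m$used <- integer(0)         # connections so far
  m$closed <- logical(0)       # no further children allowed
  m$fill <- character(0)       # hydrogen / methyl
  m$must_unsat <- logical(0)   # the 'C' symbol
  m$no_double <- logical(0)    # ring atoms barred from kekulized double bonds
  m$ring_member <- logical(0)
  m$component <- integer(0)    # ion component id
  m$pending_dioxo <- integer(0)# number of W dioxo pairs to add at expansion
  m$carbonyl <- logical(0)     # V nodes: one =O added at expansion
  m$bond_from <- integer(0)
  m$bond_to <- integer(0)
  m$bond_order <- integer(0)
  m$ring_systems <- list()
  m$warnings <- character(0)
  m
}

.mol_add_atom <- function(m, char, pos, element, capacity,
                          charge = 0L, fill = "hydrogen",
                          must_unsat = FALSE, ring_member = FALSE,
                          component = 1L) {
  i <- m$n + 1L
  m$n <- i
  m$char[i] <- char
  m$pos[i] <- pos
  m$element[i] <- element
  m$charge[i] <- as.integer(charge)
  m$capacity[i] <- as.integer(capacity)
  m$used[i] <- 0L
  m$closed[i] <- FALSE
  m$fill[i] <- fill
  m$must_unsat[i] <- must_unsat
  m$no_double[i] <- FALSE
  m$ring_member[i] <- ring_member
  m$component[i] <- component
  m$pending_dioxo[i] <- 0L
  m$carbonyl[i] <- FALSE
  i
}

# redirect every reference from atom `drop` to atom `keep` (spiro sharing);
# the dropped atom is marked dead and skipped downstream
.mol_merge_atoms <- function(m, keep, drop) {
  sel <- m$bond_from == drop
  m$bond_from[sel] <- keep
  sel <- m$bond_to == drop
  m$bond_to[sel] <- keep
  m$used[keep] <- m$used[keep] + m$used[drop]
  m$element[drop] <- NA_character_
  for (k in seq_along(m$ring_systems)) {
    rs <- m$ring_systems[[k]]
    rs$path[rs$path == drop] <- keep
    rs$rings <- lapply(rs$rings, function(r) { r[r == drop] <- keep; r })
    m$ring_systems[[k]] <- rs
  }
  invisible(m)
}

.mol_add_bond <- function(m, a, b, order = 1L) {
  stopifnot(a >= 1L, b >= 1L, a <= m$n, b <= m$n, a != b)
  k <- length(m$bond_from) + 1L
  m$bond_from[k] <- a
  m$bond_to[k] <- b
  m$bond_order[k] <- as.integer(order)
  m$used[a] <- m$used[a] + 1L
  m$used[b] <- m$used[b] + 1L
  k
}

.mol_neighbors <- function(m, a) {
  c(m$bond_to[m$bond_from == a], m$bond_from[m$bond_to == a])
}

.mol_bond_index <- function(m, a, b) {
  k <- which((m$bond_from == a & m$bond_to == b) |
             (m$bond_from == b & m$bond_to == a))
  if (length(k)) k[1] else NA_integer_
}

.mol_order_sum <- function(m, a) {
  sum(m$bond_order[m$bond_from == a | m$bond_to == a])
}

# shortest path between two atoms over bonds (BFS); returns atom id vector
# including both endpoints, or NULL when disconnected
.mol_shortest_path <- function(m, a, b) {
  if (a == b) return(a)
  prev <- integer(m$n)
  seen <- logical(m$n); seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in .mol_neighbors(m, v)) {
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v
        if (w == b) {
          path <- b
          while (path[1] != a) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# ---------------------------------------------------------------------------
# element data --------------------------------------------------------------

.periodic_symbols <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr","Rf","Db","Sg",
  "Bh","Hs","Mt","Ds","Rg","Cn","Nh","Fl","Mc","Lv","Ts","Og")

# resolve a 1-2 letter code written between hyphens to an element symbol
.element_from_code <- function(code) {
  target <- paste0(substr(code, 1, 1),
                   tolower(substr(code, 2, nchar(code))))
  i <- match(target, .periodic_symbols)
  if (is.na(i)) NA_character_ else .periodic_symbols[i]
}

# allowed total bond-order sums per element, smallest first; implicit
# hydrogen fills to the smallest value that covers the bond sum
.std_valences <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L,
  Se = c(2L, 4L, 6L), Te = c(2L, 4L, 6L), As = c(3L, 5L), Si = 4L,
  Ge = 4L, Sn = 4L, Pb = 4L, Al = 3L, Ga = 3L, Sb = c(3L, 5L), Bi = 3L
)

# implicit hydrogen count given element, charge and bond-order sum
.implicit_h <- function(element, charge, order_sum) {
  vals <- .std_valences[[element]]
  if (is.null(vals)) return(0L)          # metals etc.: no implicit hydrogens
  # charge shifts the effective valence for the common organic elements
  if (charge != 0L) {
    vals <- if (element %in% c("N", "P")) vals + charge
            else if (element %in% c("O", "S", "Se", "Te")) vals + charge
            else if (element %in% c("C", "B")) vals - abs(charge)
            else vals
    vals <- vals[vals >= 0L]
    if (!length(vals)) return(0L)
  }
  fit <- vals[vals >= order_sum]
  if (!length(fit)) return(NA_integer_)  # hypervalent beyond table: caller decides
  as.integer(fit[1] - order_sum)
}
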