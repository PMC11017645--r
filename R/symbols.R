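# WLN symbol table and locant arithmetic.
#
# Every other module consults this table: the matcher derives its token
# classes from it, the parser takes branch limits and implied groups from
# it, and the assembler reads the implied charges and fills.

#' The WLN character set and per-symbol semantics
#'
#' One row per WLN character: the 26 upper-case letters, the ten digits and
#' the four punctuation marks (`&`, `-`, `/`, space). Columns give the
#' chemical meaning of the symbol in an acyclic context, the number of
#' branches (graph connections) the symbol permits, whether it terminates a
#' branch, whether the letter can serve as a ring locant (letters A through
#' X), any implied formal charge, how unused branch slots are filled
#' (`hydrogen` for most symbols, `methyl` for X, Y and K), and whether the
#' symbol demands an unsaturated bond (the `C` carbon, which makes an
#' adjacent explicit `U` redundant and disallowed).
#'
#' WLN valence counts branches, not bond orders: `Y` is a carbon with up to
#' three connected neighbours whatever the bond orders involved.
#'
#' @return A data.frame with columns `char`, `meaning`, `max_branches`,
#'   `exact_branches`, `expandable`, `terminating`, `locant_capable`,
#'   `implied_charge`, `implied_fill`, `must_unsaturate`.
#' @examples
#' tab <- wln_symbol_table()
#' tab[tab$char == "E", ]  # bromine: one branch, terminating, locant-capable
#' @export
wln_symbol_table <- function() {
  .wln_symbols
}

# row helper used only at table build time
.sym <- function(char, meaning, max_branches, terminating = FALSE,
                 locant_capable = FALSE, implied_charge = 0L,
                 implied_fill = "hydrogen", exact_branches = FALSE,
                 expandable = FALSE, must_unsaturate = FALSE) {
  data.frame(char = char, meaning = meaning,
             max_branches = as.integer(max_branches),
             exact_branches = exact_branches, expandable = expandable,
             terminating = terminating, locant_capable = locant_capable,
             implied_charge = as.integer(implied_charge),
             implied_fill = implied_fill,
             must_unsaturate = must_unsaturate,
             stringsAsFactors = FALSE)
}

.build_symbol_table <- function() {
  rows <- list(
    .sym("A", "locant only",                     0, locant_capable = TRUE),
    .sym("B", "boron",                           3, locant_capable = TRUE),
    .sym("C", "carbon",                          4, locant_capable = TRUE,
         exact_branches = TRUE, must_unsaturate = TRUE),
    .sym("D", "open chelate",                    0, locant_capable = TRUE),
    .sym("E", "bromine",                         1, terminating = TRUE, locant_capable = TRUE),
    .sym("F", "fluorine",                        1, terminating = TRUE, locant_capable = TRUE),
    .sym("G", "chlorine",                        1, terminating = TRUE, locant_capable = TRUE),
    .sym("H", "hydrogen",                        1, terminating = TRUE, locant_capable = TRUE),
    .sym("I", "iodine",                          1, terminating = TRUE, locant_capable = TRUE),
    .sym("J", "ring closure",                    0, terminating = TRUE, locant_capable = TRUE),
    .sym("K", "nitrogen (1+, 4 implied methyls)", 4, locant_capable = TRUE,
         implied_charge = 1L, implied_fill = "methyl"),
    .sym("L", "open carbocycle",                 0, locant_capable = TRUE),
    .sym("M", "secondary amine (NH)",            2, locant_capable = TRUE),
    .sym("N", "nitrogen",                        3, locant_capable = TRUE),
    .sym("O", "oxygen",                          2, locant_capable = TRUE),
    .sym("P", "phosphorus",                      3, locant_capable = TRUE),
    .sym("Q", "hydroxyl",                        1, terminating = TRUE, locant_capable = TRUE),
    .sym("R", "benzene",                         1, locant_capable = TRUE, expandable = TRUE),
    .sym("S", "sulphur",                         3, locant_capable = TRUE),
    .sym("T", "open heterocycle",                0, locant_capable = TRUE),
    .sym("U", "unsaturate bond",                 0, locant_capable = TRUE),
    .sym("V", "carbonyl",                        2, locant_capable = TRUE),
    .sym("W", "add -oxylate (dioxo)",            0, locant_capable = TRUE),
    .sym("X", "carbon (4 implied methyls)",      4, locant_capable = TRUE,
         implied_fill = "methyl"),
    .sym("Y", "carbon (3 implied methyls)",      3, implied_fill = "methyl"),
    .sym("Z", "primary amine (NH2)",             0, terminating = TRUE)
  )
  for (d in 0:9)
    rows[[length(rows) + 1L]] <- .sym(as.character(d),
                                      sprintf("alkane chain of length n"), 0)
  rows[[length(rows) + 1L]] <- .sym("&", "punctuation", 0)
  rows[[length(rows) + 1L]] <- .sym("-", "punctuation", 0)
  rows[[length(rows) + 1L]] <- .sym(" ", "punctuation", 0)
  rows[[length(rows) + 1L]] <- .sym("/", "punctuation", 0)
  tab <- do.call(rbind, rows)
  rownames(tab) <- tab$char
  tab
}

.wln_symbols <- .build_symbol_table()

# element symbol each atom-forming WLN character stands for (after shorthand
# expansion Q, Z, M, V, W etc. contribute extra atoms; this is the core atom)
.wln_core_element <- c(
  B = "B", C = "C", E = "Br", F = "F", G = "Cl", H = "H", I = "I",
  K = "N", M = "N", N = "N", O = "O", P = "P", Q = "O", S = "S",
  V = "C", W = "", X = "C", Y = "C", Z = "N", R = "C", U = "", A = "", D = ""
)

#' Look up the semantics of a single WLN character
#'
#' @param c A single character from the WLN character set.
#' @param pos Optional 1-based position, used only to contextualise errors.
#' @return A one-row data.frame (see [wln_symbol_table()]).
#' @examples
#' lookup_symbol("X")  # carbon, 4 branches, implied methyl fill
#' @export
lookup_symbol <- function(c, pos = NA_integer_) {
  stopifnot(is.character(c), length(c) == 1L, nchar(c) == 1L)
  tab <- .wln_symbols
  i <- match(c, tab$char)
  if (is.na(i)) {
    stop(wln_error("UnknownSymbol",
                   sprintf("unknown WLN character '%s'%s", c,
                           if (is.na(pos)) "" else sprintf(" at position %d", pos)),
                   position = pos))
  }
  tab[i, , drop = FALSE]
}

#' Convert a locant string to its path index
#'
#' A locant is one letter `A`..`X` optionally followed by trailing `&`
#' characters that index past `X`: each `&` adds 24 (the size of the A-X
#' range), so `"A"` is 1, `"X"` is 24 and `"A&"` is 25.
#'
#' @param s Locant string.
#' @return Positive integer path index.
#' @seealso [index_to_locant()] for the inverse.
#' @examples
#' locant_to_index("A")   # 1
#' locant_to_index("A&")  # 25
#' @export
locant_to_index <- function(s) {
  if (length(s) != 1L || !is.character(s) || is.na(s) ||
      !grepl("^[A-X]&*$", s)) {
    stop(wln_error("MalformedLocant",
                   sprintf("malformed locant '%s' (expect one letter A-X plus optional trailing '&')",
                           if (length(s) == 1L) s else "<vector>")))
  }
  letter <- substr(s, 1L, 1L)
  ext <- nchar(s) - 1L
  (utf8ToInt(letter) - utf8ToInt("A") + 1L) + 24L * ext
}

#' Convert a path index back to its locant string
#'
#' @param i Positive integer path index.
#' @return Locant string; round-trips with [locant_to_index()].
#' @export
index_to_locant <- function(i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L) stop(wln_error("MalformedLocant", "index must be >= 1"))
  ext <- (i - 1L) %/% 24L
  rank <- (i - 1L) %% 24L + 1L
  paste0(intToUtf8(utf8ToInt("A") + rank - 1L),
         strrep("&", ext))
}

# condition constructor shared across modules; `class` mirrors the fault
# taxonomy (UnknownSymbol, MalformedLocant, ParseError, RingParseError,
# ValenceError, BadLocant, UnknownElement, RecordError)
wln_error <- function(class, message, position = NA_integer_, ...) {
  structure(class = c(class, "wln_error", "error", "condition"),
            list(message = message, call = sys.call(-1),
                 position = position, ...))
}
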