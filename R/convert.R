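# SMILES emission and the end-to-end WLN converter. The reader itself is
# toolkit-native; OpenBabel (via ChemmineOB) supplies only the final
# canonicalization and the InChI output.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.smiles_default_valence <- list(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L,
                                S = c(2L, 4L, 6L), F = 1L, Cl = 1L,
                                Br = 1L, I = 1L)

.bond_symbol <- function(order) switch(as.character(order),
                                       "1" = "", "2" = "=", "3" = "#", "")

#' Write a (non-canonical) SMILES string from a connection table
#'
#' Deterministic depth-first emission with explicit kekulized bond orders;
#' disconnected ion components are joined with `.`. Atoms are bracketed
#' whenever the bare-symbol implicit-hydrogen convention would not
#' reproduce the computed hydrogen count.
#'
#' @param ct A `connection_table`.
#' @return SMILES string.
#' @export
write_smiles <- function(ct) {
  atoms <- ct$atoms
  n <- nrow(atoms)
  if (n == 0L) return("")
  adj <- vector("list", n)
  order_sum <- integer(n)
  for (k in seq_len(nrow(ct$bonds))) {
    a <- ct$bonds$from[k]; b <- ct$bonds$to[k]; o <- ct$bonds$order[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    order_sum[a] <- order_sum[a] + o
    order_sum[b] <- order_sum[b] + o
  }
  atom_token <- function(i) {
    el <- atoms$element[i]; ch <- atoms$charge[i]; h <- atoms$hcount[i]
    if (el %in% .organic_subset && ch == 0L) {
      vals <- .smiles_default_valence[[el]]
      fit <- vals[vals >= order_sum[i]]
      if (length(fit) && fit[1] - order_sum[i] == h) return(el)
    }
    paste0("[", el,
           if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
           if (ch > 0L) paste0("+", if (ch > 1L) ch else "")
           else if (ch < 0L) paste0("-", if (ch < -1L) -ch else ""),
           "]")
  }
  # spanning forest by DFS; back edges become numbered ring closures
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  closures <- vector("list", n)
  ring_id <- 0L
  comp_out <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    parent[root] <- 0L
    stack <- root
    comp_atoms <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp_atoms <- c(comp_atoms, v)
      for (b in rev(sort(unique(adj[[v]])))) {
        if (!visited[b]) {
          visited[b] <- TRUE
          parent[b] <- v
          stack <- c(stack, b)
        }
      }
    }
    for (k in seq_len(nrow(ct$bonds))) {
      a <- ct$bonds$from[k]; b <- ct$bonds$to[k]
      if (!(a %in% comp_atoms)) next
      if ((!is.na(parent[a]) && parent[a] == b) ||
          (!is.na(parent[b]) && parent[b] == a)) next
      ring_id <- ring_id + 1L
      d <- if (ring_id <= 9L) as.character(ring_id) else
        paste0("%", sprintf("%02d", ring_id))
      sym <- .bond_symbol(ct$bonds$order[k])
      closures[[a]] <- c(closures[[a]], paste0(sym, d))
      closures[[b]] <- c(closures[[b]], d)
    }
    emit_tree <- function(i) {
      out <- paste0(atom_token(i), paste(closures[[i]], collapse = ""))
      kids <- sort(which(parent == i))
      branches <- vapply(kids, function(b) {
        k <- .ct_bond_index(ct, i, b)
        paste0(.bond_symbol(ct$bonds$order[k]), emit_tree(b))
      }, character(1))
      if (length(branches) > 1L)
        out <- paste0(out,
                      paste0("(", branches[-length(branches)], ")", collapse = ""),
                      branches[length(branches)])
      else if (length(branches) == 1L) out <- paste0(out, branches)
      out
    }
    comp_out <- c(comp_out, emit_tree(root))
  }
  paste(comp_out, collapse = ".")
}

.ct_bond_index <- function(ct, a, b) {
  which((ct$bonds$from == a & ct$bonds$to == b) |
        (ct$bonds$from == b & ct$bonds$to == a))[1]
}

#' Canonicalize a SMILES string with OpenBabel
#' @param smiles SMILES string (may contain `.`-separated components).
#' @return Canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", smiles)
  out <- sub("[ \t\n]+$", "", out)
  if (!nzchar(out))
    stop(wln_error("RecordError", sprintf("OpenBabel could not read '%s'", smiles)))
  out
}

#' Convert a WLN string to SMILES or InChI
#'
#' End-to-end pipeline: parse, expand shorthand, resolve implied
#' unsaturation, kekulize by maximum matching, build the connection table,
#' write SMILES and (by default) canonicalize through OpenBabel. A pure
#' function of its arguments.
#'
#' @param wln WLN string.
#' @param format `"smiles"` or `"inchi"`.
#' @param implied_double Apply implied-double-bond conventions (default on;
#'   see [apply_implied_unsaturation()]).
#' @param strict Disable run-time error recovery.
#' @param canonical Canonicalize through OpenBabel (SMILES only; InChI is
#'   canonical by construction).
#' @return A single string.
#' @examples
#' \dontrun{
#' wln_convert("Q1XGG2Y1Q1Z")   # OCC(Cl)(Cl)CCC(CO)CN, canonical form
#' wln_convert("L C666J")       # anthracene
#' }
#' @export
wln_convert <- function(wln, format = c("smiles", "inchi"),
                        implied_double = TRUE, strict = FALSE,
                        canonical = TRUE) {
  format <- match.arg(format)
  g <- parse_wln(wln, strict = strict)
  g <- expand_shorthand(g)
  g <- apply_implied_unsaturation(g, implied = implied_double)
  g <- kekulize(g)
  ct <- build_connection_table(g)
  smi <- write_smiles(ct)
  if (format == "inchi") {
    out <- ChemmineOB::convertFormat("SMI", "INCHI", smi)
    out <- sub("[ \t\n]+$", "", out)
    if (!nzchar(out))
      stop(wln_error("RecordError", sprintf("InChI generation failed for '%s'", wln)))
    return(out)
  }
  if (canonical) canonical_smiles(smi) else smi
}

#' Convert a connection table for inspection
#' @param g A `wln_graph`.
#' @param implied_double,strict See [wln_convert()].
#' @return A `connection_table`.
#' @export
wln_to_table <- function(g, implied_double = TRUE, strict = FALSE) {
  g <- expand_shorthand(g)
  g <- apply_implied_unsaturation(g, implied = implied_double)
  g <- kekulize(g)
  build_connection_table(g)
}

#' File/line interface mirroring the `readwln` command-line tool
#'
#' @param lines Character vector of WLN strings, one per element.
#' @param format,implied_double,strict See [wln_convert()].
#' @return Character vector of outputs; failures yield `NA` with the
#'   diagnostic written to standard error as `ERROR <position> <message>`.
#' @export
readwln <- function(lines, format = "smiles", implied_double = TRUE,
                    strict = FALSE) {
  vapply(lines, function(l) {
    tryCatch(wln_convert(l, format = format, implied_double = implied_double,
                         strict = strict),
             wln_error = function(e) {
               message(sprintf("ERROR %s %s",
                               if (is.null(e$position) || is.na(e$position)) "?"
                               else e$position, conditionMessage(e)))
               NA_character_
             },
             error = function(e) {
               message(sprintf("ERROR ? %s", conditionMessage(e)))
               NA_character_
             })
  }, character(1), USE.NAMES = FALSE)
}
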