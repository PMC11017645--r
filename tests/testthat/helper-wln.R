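# Shared helpers: canonicalization shorthand, fixture access, random string
# generators and independent oracles.

canon <- function(s) canonical_smiles(s)

fixture <- function(name) {
  p <- system.file("extdata", name, package = "wlntools")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", name)
  p
}

smith_fixture <- function() read_benchmark(fixture("synthetic_smith.tsv"))

convert_quiet <- function(w, ...) suppressMessages(wln_convert(w, ...))

# random string accepted by the matcher: a random walk over the minimal DFA
# that stops at accepting states with some probability
random_accepted <- function(dfa, max_len = 30L, stop_p = 0.15) {
  repeat {
    s <- dfa$start
    out <- character(0)
    for (k in seq_len(max_len)) {
      if (dfa$accepts[s] && length(out) && runif(1) < stop_p) break
      choices <- which(dfa$trans[s, ] != 0L)
      if (!length(choices)) break
      ci <- choices[sample.int(length(choices), 1L)]
      out <- c(out, wlntools:::.wln_alphabet[ci])
      s <- dfa$trans[s, ci]
    }
    if (dfa$accepts[s] && length(out)) return(paste(out, collapse = ""))
  }
}

mutate_string <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- sample(length(chars), 1L)
  chars[i] <- sample(c(LETTERS, 0:9, "&", "-", " ", "/"), 1L)
  paste(chars, collapse = "")
}

# naive leftmost-longest extraction testing every substring independently
greedy_oracle <- function(dfa, text, min_len = 2L) {
  n <- nchar(text)
  out <- list()
  i <- 1L
  while (i <= n) {
    best <- -1L
    for (j in seq.int(i, n)) {
      if (dfa_match(dfa, substr(text, i, j))) best <- j
    }
    if (best >= i && (best - i + 1L) >= min_len) {
      out[[length(out) + 1L]] <- data.frame(start = i - 1L, end = best,
                                            text = substr(text, i, best))
      i <- best + 1L
    } else i <- i + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0)))
  do.call(rbind, out)
}

# independent valence audit of a connection table
valence_table <- list(C = 4L, N = c(3L, 5L), O = 2L, S = c(2L, 4L, 6L),
                      P = c(3L, 5L), B = 3L, F = 1L, Cl = 1L, Br = 1L,
                      I = 1L, Se = c(2L, 4L, 6L), H = 1L)
check_valences <- function(ct) {
  for (i in seq_len(nrow(ct$atoms))) {
    el <- ct$atoms$element[i]
    vals <- valence_table[[el]]
    if (is.null(vals)) next
    s <- sum(ct$bonds$order[ct$bonds$from == i | ct$bonds$to == i])
    ch <- ct$atoms$charge[i]
    eff <- if (el %in% c("N", "P")) vals + ch else vals + ch
    total <- s + ct$atoms$hcount[i]
    if (!(total %in% eff))
      return(sprintf("atom %d (%s, charge %d): bond sum %d + %dH not a standard valence",
                     i, el, ch, s, ct$atoms$hcount[i]))
  }
  TRUE
}

# edge list (two columns, local indices) of the aromatic subgraph a ring
# system offers to the kekulizer, rebuilt independently from a parsed graph
ring_match_edges <- function(wln) {
  g <- parse_wln(wln)
  g <- expand_shorthand(g)
  g <- apply_implied_unsaturation(g, TRUE)
  rs <- g$ring_systems[[1]]
  arom <- rep_len(rs$aromatic, length(rs$rings))
  atoms <- unique(unlist(rs$rings[arom]))
  free <- vapply(atoms, function(a) {
    vals <- wlntools:::.std_valences[[g$element[a]]]
    if (is.null(vals)) return(0L)
    s <- wlntools:::.mol_order_sum(g, a)
    fit <- vals[vals >= s]
    if (!length(fit)) 0L else fit[1] - s
  }, integer(1))
  eligible <- atoms[free >= 1L & !g$no_double[atoms]]
  ks <- which(g$bond_order == 1L & g$bond_from %in% eligible &
              g$bond_to %in% eligible)
  keep <- vapply(ks, function(k) any(vapply(rs$rings[arom], function(r)
    g$bond_from[k] %in% r && g$bond_to[k] %in% r, logical(1))), logical(1))
  ks <- ks[keep]
  verts <- sort(unique(c(g$bond_from[ks], g$bond_to[ks])))
  list(n = length(verts),
       edges = cbind(match(g$bond_from[ks], verts), match(g$bond_to[ks], verts)))
}
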