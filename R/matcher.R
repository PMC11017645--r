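# The wlngrep matcher: cached minimal DFA plus exact / greedy matching and
# the CAOCI double-ampersand annotation-suffix convention.

.wln_cache <- new.env(parent = emptyenv())

#' Build (or fetch) the WLN matcher
#'
#' Constructs the NFA from the relaxed grammar, determinizes it by subset
#' construction and minimizes it. The result is cached for the session;
#' the construction is deterministic so a rebuild always yields the same
#' machine.
#'
#' @param rebuild Force reconstruction instead of using the cache.
#' @return Minimal DFA (see [nfa_determinize()]).
#' @examples
#' dfa <- build_matcher()
#' dfa_size(dfa)
#' @export
build_matcher <- function(rebuild = FALSE) {
  if (!rebuild && !is.null(.wln_cache$dfa)) return(.wln_cache$dfa)
  nfa <- build_wln_nfa()
  dfa <- dfa_minimize(nfa_determinize(nfa))
  .wln_cache$nfa <- nfa
  .wln_cache$dfa <- dfa
  dfa
}

#' Matcher configuration
#'
#' @param mode `"exact"` (whole line) or `"greedy"` (extract substrings).
#' @param allow_single_letter Keep single-character matches? Most lone
#'   capital letters are themselves valid WLN strings, which would match the
#'   start of any sentence, so this defaults to FALSE.
#' @param strip_suffix Strip `&&` annotation suffixes before matching.
#' @return A list of class `matcher_config`.
#' @export
matcher_config <- function(mode = c("greedy", "exact"),
                           allow_single_letter = FALSE,
                           strip_suffix = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, allow_single_letter = allow_single_letter,
                 strip_suffix = strip_suffix), class = "matcher_config")
}

#' Exact whole-line matching
#'
#' TRUE only if the entire line is a syntactically valid (relaxed-grammar)
#' WLN string: every character consumed and the machine left in an accepting
#' state with all ring blocks closed.
#'
#' @param dfa Matcher DFA from [build_matcher()]; built on demand if missing.
#' @param line A single line of text (no newline).
#' @return Logical scalar.
#' @examples
#' match_exact(line = "SCN")      # TRUE
#' match_exact(line = "SCUUN")    # FALSE: explicit U after C is disallowed
#' @export
match_exact <- function(dfa = build_matcher(), line) {
  stopifnot(is.character(line), length(line) == 1L)
  if (grepl("\n", line, fixed = TRUE)) stop("line must not contain newlines")
  dfa_match(dfa, line)
}

#' Greedy extraction of WLN candidates from text
#'
#' Scans the text left to right and returns the leftmost-longest
#' non-overlapping substrings accepted by the matcher; scanning resumes
#' after each match. Single-character spans are suppressed unless
#' `cfg$allow_single_letter`.
#'
#' @param dfa Matcher DFA.
#' @param text Character scalar to scan.
#' @param cfg A [matcher_config()].
#' @return A data.frame with columns `start`, `end` (0-based, half-open)
#'   and `text`; zero rows when nothing matches.
#' @examples
#' match_greedy(text = "prepared Q1XGG2Y1Q1Z in two steps")
#' @export
match_greedy <- function(dfa = build_matcher(), text,
                         cfg = matcher_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cidx <- match(chars, .wln_alphabet)      # NA for non-WLN characters
  min_len <- if (isTRUE(cfg$allow_single_letter)) 1L else 2L
  out <- list()
  i <- 1L
  while (i <= n) {
    if (is.na(cidx[i])) { i <- i + 1L; next }
    s <- dfa$start
    best_end <- -1L                        # exclusive end of longest accept
    j <- i
    while (j <= n && !is.na(cidx[j])) {
      s <- dfa$trans[s, cidx[j]]
      if (s == 0L) break
      if (dfa$accepts[s]) best_end <- j
      j <- j + 1L
    }
    if (best_end >= i && (best_end - i + 1L) >= min_len) {
      out[[length(out) + 1L]] <-
        data.frame(start = i - 1L, end = best_end,
                   text = substr(text, i, best_end),
                   stringsAsFactors = FALSE)
      i <- best_end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Strip a CAOCI-style annotation suffix
#'
#' Historic repositories (notably the Commercially Available Organic
#' Chemicals Index) appended free-text qualifiers to a valid WLN string
#' after a double ampersand. This splits at the first `" &&"` whose prefix
#' is itself a complete WLN match, returning the WLN part and the suffix.
#'
#' @param line Input line.
#' @param dfa Matcher DFA used to re-test the prefix.
#' @return List with elements `wln` and `suffix` (empty string if none).
#' @examples
#' strip_annotation_suffix("Q &&beta form")
#' @export
strip_annotation_suffix <- function(line, dfa = build_matcher()) {
  hits <- gregexpr(" &&", line, fixed = TRUE)[[1]]
  if (hits[1] != -1L) {
    for (pos in hits) {
      prefix <- substr(line, 1L, pos - 1L)
      if (match_exact(dfa, prefix)) {
        return(list(wln = prefix,
                    suffix = substr(line, pos + 3L, nchar(line))))
      }
    }
  }
  list(wln = line, suffix = "")
}

#' grep-like extraction of WLN strings from lines of text
#'
#' The programmatic face of the `wlngrep` command-line tool. Lines are
#' treated independently.
#'
#' @param lines Character vector of input lines.
#' @param exact Whole-line matching instead of greedy extraction.
#' @param allow_single_letter Keep single-letter matches.
#' @param keep_suffix Do not strip `&&` annotation suffixes first.
#' @return For `exact`, the subset of lines that match. Otherwise a
#'   data.frame with `line` (1-based line number), `start`, `end`, `text`.
#' @export
wlngrep <- function(lines, exact = FALSE, allow_single_letter = FALSE,
                    keep_suffix = FALSE) {
  dfa <- build_matcher()
  cfg <- matcher_config(allow_single_letter = allow_single_letter,
                        strip_suffix = !keep_suffix)
  if (exact) {
    probe <- vapply(lines, function(l) {
      if (!keep_suffix) l <- strip_annotation_suffix(l, dfa)$wln
      match_exact(dfa, l)
    }, logical(1), USE.NAMES = FALSE)
    return(lines[probe])
  }
  res <- lapply(seq_along(lines), function(i) {
    l <- lines[i]
    if (!keep_suffix) l <- strip_annotation_suffix(l, dfa)$wln
    m <- match_greedy(dfa, l, cfg)
    if (nrow(m)) cbind(line = i, m) else NULL
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    return(data.frame(line = integer(0), start = integer(0),
                      end = integer(0), text = character(0)))
  do.call(rbind, res)
}
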