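# Conversion testing: reference comparison, FP2/Tanimoto similarity, the
# four-step wlngrep triage pipeline, and benchmark summaries over
# WLN<TAB>SMILES tables.

#' Strip stereochemistry from a SMILES string
#'
#' WLN carried little to no stereo information, so reference SMILES are
#' flattened before comparison: tetrahedral marks (`@`, `@@`) and
#' double-bond marks (`/`, `\`) are removed and the result is
#' re-canonicalized.
#'
#' @param s SMILES string.
#' @return Canonical SMILES without stereo descriptors.
#' @export
strip_stereo <- function(s) {
  flat <- gsub("@", "", s, fixed = TRUE)
  flat <- gsub("[/\\\\]", "", flat)
  # [C@@H] style brackets may collapse to plain-atom semantics; let the
  # toolkit renormalize hydrogen counts
  canonical_smiles(flat)
}

#' Compare a conversion output against a reference SMILES
#'
#' Both sides are canonicalized with the same toolkit (the reference after
#' stereo stripping) and compared as strings, which also verifies all
#' implicit/explicit hydrogens.
#'
#' @param out SMILES produced by the converter.
#' @param ref Reference SMILES (may carry stereo).
#' @return TRUE iff the canonical forms are string-identical.
#' @export
compare_canonical <- function(out, ref) {
  identical(canonical_smiles(out), strip_stereo(ref))
}

.fp2_bits <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "FP2")
  fp > 0
}

#' Tanimoto similarity of two molecules (FP2 fingerprints)
#'
#' Path-based 1024-bit FP2 fingerprints from OpenBabel; the Tanimoto
#' coefficient |A&B| / |A|B| scores how close a failed conversion came.
#'
#' @param out,ref SMILES strings (stereo stripped beforehand if desired).
#' @return Numeric in [0, 1].
#' @export
smiles_similarity <- function(out, ref) {
  bits <- .fp2_bits(c(out, ref))
  if (nrow(bits) != 2L)
    stop(wln_error("RecordError", "fingerprint generation failed"))
  a <- bits[1, ]; b <- bits[2, ]
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Triage one benchmark record through the wlngrep pipeline
#'
#' The four steps: (1) strip any `&&` annotation suffix and attempt an
#' exact match; (2) if the whole string matches, test the full conversion
#' against the reference; (3) if only substrings match, test the extracted
#' candidates and record a correction suggestion; (4) otherwise flag the
#' record as an incorrect WLN. Similarity is computed for failed
#' conversions only.
#'
#' @param wln WLN string as found in the source database.
#' @param reference Reference SMILES.
#' @return A list of class `triage_result`: `status` (one of `exact_pass`,
#'   `exact_fail`, `partial`, `rejected`), `substrings`, `similarity`,
#'   `note`.
#' @export
triage <- function(wln, reference) {
  dfa <- build_matcher()
  res <- function(status, substrings = character(0), similarity = NA_real_,
                  note = "") {
    structure(list(status = status, substrings = substrings,
                   similarity = similarity, note = note),
              class = "triage_result")
  }
  ref_ok <- !inherits(try(strip_stereo(reference), silent = TRUE), "try-error")
  if (!nzchar(wln) || !ref_ok)
    return(res("rejected", note = "unusable record"))
  stripped <- strip_annotation_suffix(wln, dfa)
  candidate <- stripped$wln
  note <- if (nzchar(stripped$suffix))
    sprintf("annotation suffix '%s' stripped (CAOCI convention)", stripped$suffix)
  else ""
  if (match_exact(dfa, candidate)) {
    out <- tryCatch(suppressMessages(wln_convert(candidate)),
                    error = function(e) NA_character_)
    if (!is.na(out) && compare_canonical(out, reference))
      return(res("exact_pass", substrings = candidate, note = note))
    sim <- if (!is.na(out))
      tryCatch(smiles_similarity(out, strip_stereo(reference)),
               error = function(e) NA_real_)
    else NA_real_
    return(res("exact_fail", substrings = candidate, similarity = sim,
               note = paste(note, "syntactically valid but conversion differs")))
  }
  spans <- match_greedy(dfa, candidate, matcher_config())
  if (nrow(spans)) {
    subs <- spans$text
    hit <- FALSE
    for (s in subs) {
      out <- tryCatch(suppressMessages(wln_convert(s)),
                      error = function(e) NA_character_)
      if (!is.na(out) && compare_canonical(out, reference)) { hit <- TRUE; break }
    }
    suggestion <- paste(subs, collapse = " | ")
    # OCR-damaged strings may still convert whole under space-skip recovery
    rec <- tryCatch(suppressMessages(wln_convert(candidate)),
                    error = function(e) NA_character_)
    if (!is.na(rec) && compare_canonical(rec, reference))
      suggestion <- paste0(suggestion, "; recoverable by skipping a semantically impossible space")
    if (grepl("[a-z]", candidate))
      suggestion <- paste0(suggestion,
                           "; lower-case characters were never part of the language",
                           " - a valid form would append the suffix after ' &&'")
    return(res("partial", substrings = subs,
               similarity = if (hit) 1 else NA_real_,
               note = sprintf("correction candidates: %s", suggestion)))
  }
  res("rejected", note = "no valid WLN substring; flagged as an incorrect WLN")
}

#' Read a WLN benchmark table
#'
#' Tab-separated, no header, UTF-8, `WLN<TAB>SMILES`; extra columns are
#' ignored. Malformed rows stay in the set and triage as rejected.
#'
#' @param path File path.
#' @return data.frame with columns `wln`, `reference`.
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(wln = vapply(parts, function(p) p[1] %||% "", character(1)),
             reference = vapply(parts, function(p)
               if (length(p) >= 2L) p[2] else "", character(1)),
             stringsAsFactors = FALSE)
}

#' Run a conversion benchmark over a WLN:SMILES table
#'
#' For every record: exact matching, greedy substring extraction (all
#' spans counted, so the greedy total can exceed the set size) and
#' conversion scoring. A record counts as converted when the full string
#' or its `&&`-stripped form converts to the reference.
#'
#' @param path TSV path, or a data.frame from [read_benchmark()].
#' @param progress Print a line per 100 records.
#' @return A list of class `benchmark_summary`: `set_size`,
#'   `exact_matches`, `greedy_matches`, `conversions_correct`,
#'   `mean_failure_similarity`, `status_counts`, and the per-record
#'   `details` data.frame.
#' @export
run_benchmark <- function(path, progress = FALSE) {
  tab <- if (is.data.frame(path)) path else read_benchmark(path)
  dfa <- build_matcher()
  n <- nrow(tab)
  status <- character(n)
  exact <- logical(n)
  greedy_n <- integer(n)
  correct <- logical(n)
  sims <- rep(NA_real_, n)
  notes <- character(n)
  outs <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (progress && i %% 100L == 0L) message(sprintf("record %d / %d", i, n))
    w <- tab$wln[i]
    stripped <- strip_annotation_suffix(w, dfa)$wln
    exact[i] <- match_exact(dfa, stripped)
    # benchmark lines are whole entities, so single-letter candidates stay on
    greedy_n[i] <- nrow(match_greedy(dfa, stripped,
                                     matcher_config(allow_single_letter = TRUE)))
    tr <- triage(w, tab$reference[i])
    status[i] <- tr$status
    sims[i] <- tr$similarity
    notes[i] <- tr$note
    correct[i] <- tr$status == "exact_pass" ||
      (tr$status == "partial" && !is.na(tr$similarity) && tr$similarity == 1)
    if (correct[i])
      outs[i] <- tryCatch(suppressMessages(wln_convert(stripped)),
                          error = function(e) NA_character_)
  }
  fail_sims <- sims[!correct & !is.na(sims)]
  structure(list(
    set_size = n,
    exact_matches = sum(exact),
    greedy_matches = sum(greedy_n),
    conversions_correct = sum(correct),
    mean_failure_similarity = if (length(fail_sims)) mean(fail_sims) else NA_real_,
    status_counts = table(factor(status, levels = c("exact_pass", "exact_fail",
                                                    "partial", "rejected"))),
    details = data.frame(wln = tab$wln, status = status, exact = exact,
                         greedy_spans = greedy_n, correct = correct,
                         output = outs, reference = tab$reference,
                         similarity = sims, note = notes,
                         stringsAsFactors = FALSE)),
    class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("WLN benchmark: %d records\n", x$set_size))
  cat(sprintf("  exact matches        %d (%.1f%%)\n", x$exact_matches,
              100 * x$exact_matches / max(1L, x$set_size)))
  cat(sprintf("  greedy matches       %d\n", x$greedy_matches))
  cat(sprintf("  conversions correct  %d (%.1f%%)\n", x$conversions_correct,
              100 * x$conversions_correct / max(1L, x$set_size)))
  if (!is.na(x$mean_failure_similarity))
    cat(sprintf("  mean failure Tanimoto %.3f\n", x$mean_failure_similarity))
  invisible(x)
}

#' Write benchmark outputs as JSON / failures TSV
#'
#' @param summary A `benchmark_summary`.
#' @param report Optional JSON path for the summary.
#' @param failures Optional TSV path listing non-correct records.
#' @return The summary, invisibly.
#' @export
write_benchmark_report <- function(summary, report = NULL, failures = NULL) {
  if (!is.null(report)) {
    jsonlite::write_json(
      c(list(set_size = summary$set_size,
             exact_matches = summary$exact_matches,
             greedy_matches = summary$greedy_matches,
             conversions_correct = summary$conversions_correct,
             mean_failure_similarity = summary$mean_failure_similarity),
        as.list(summary$status_counts)),
      report, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(failures)) {
    bad <- summary$details[!summary$details$correct, , drop = FALSE]
    utils::write.table(bad[, c("wln", "status", "output", "reference",
                               "similarity", "note")],
                       failures, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(summary)
}
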