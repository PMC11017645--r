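---
title: "Reading Wiswesser Line Notation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading Wiswesser Line Notation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlntools)
```

## The problem

Wiswesser Line Notation encodes a molecular graph as a string over the
upper-case letters, the digits and four punctuation marks. Unlike SMILES,
most letters are *shorthand*: `Q` is a hydroxyl, `Z` a primary amine, `V` a
carbonyl carbon, `W` adds two double-bonded oxygens to its neighbour, and
`X`/`Y`/`K` fill their unused branch slots with methyl groups. Valence in
WLN counts *branches* (graph connections), not bond orders: `Y` is a carbon
with up to three neighbours whatever the orders of those bonds. Reading WLN
therefore needs three layers: a tokenizer/matcher that recognises
syntactically plausible strings, a parser that builds the symbol graph, and
an assembler that turns symbol shorthand into atoms, bonds and hydrogens.

Legacy WLN survives mostly in OCR'd documents and old database exports, so
the package treats error tolerance as part of the model: recognition is
deliberately a *relaxation* of the language, and the parser can repair two
documented fault classes at run time.

## The matcher

`build_matcher()` constructs an NFA over the WLN alphabet whose states
encode syntactic context (after an atom symbol, after the must-unsaturate
carbon `C`, inside a digit run, inside a ring block, after a space, inside
an element code, and so on), determinizes it by subset construction and
minimizes it by partition refinement. The relaxations are the classic ones for WLN text
matching: any number of branches after a branching
symbol and any number of `&` closures anywhere. What remains enforced is
token adjacency: spaces introduce only ion separators and locant clauses
(two spaces in a row end a candidate), ring blocks must open with
`L`/`T`/`D` and close with a `J` that is not in locant position, `-XX-`
element codes need their closing hyphen, and `U` may not sit next to `C`
(whose unsaturation is implied, which is exactly why `SCUUN` is invalid
while `SCN` is valid). The minimized machine here has
`r paste(dfa_size(build_matcher()), collapse = " states / ")` edges; machines built
with different relaxation boundaries differ in size, so state and edge
counts are recorded as informational numbers, not targets.

Greedy extraction is leftmost-longest with scanning resuming after each
match, 0-based half-open spans, and single-letter matches suppressed unless
requested — most lone capitals are themselves valid WLN, which would match
the start of every sentence. The matcher runs with a companion stack that
tracks open branches and ring blocks; unmatched *trailing* `&` closures are
permitted, which is the relaxation at work.

## The parser and its recovery rules

`parse_wln()` reads character by character, holding the current attachment
node, the pending `U` unsaturation count and a stack of open branching
symbols. Terminators (`E F G H I Q Z`) close their branch and return to the
last open branching symbol; `&` pops one level, and consecutive `&`s pop
repeatedly; `space &` starts a new ion component. Ring blocks are located
first and spliced out to the ring machinery. Canonical (Rule 2) symbol
ordering is *not* enforced — database strings frequently are not canonical,
and rejecting them would defeat the curation purpose.

Two recoveries are on by default (`strict = TRUE` disables both, turning
them into `ParseError`s with 0-based character positions):

* **Symbol raising.** A branch demanded of a saturated `M` (an NH with two
  connections) re-types it as `N`, the same element one degree up. No other
  symbol in the table has a same-element higher-degree counterpart, so `N`
  over-branching is fatal.
* **Space skipping.** A space that cannot open any legal clause — the
  classic OCR fault, as in `Z2Z & GH` — is skipped with a diagnostic.

## Ring systems: citations, locant paths, assembly

A ring block cites sub-ring sizes, each with an optional fuse locant
(`L C666J` cites rings of 6, 6, 6 with the first fused at `C`); digit-led
clauses declare multicyclic points and are followed by the system size as a
locant; later clauses place heteroatoms (`KO`: oxygen at `K`),
unsaturations (`NU`; `HU- M` names an explicit partner), bridges and
crossed bonds (`6/BE`); trailing `&`/`T` marks flag each cited ring
aromatic or aliphatic, one mark covering the whole system.

The assembly model implemented here reconstructs the numbering path ring by
ring: each cited ring reaches the current end of the locant path through
the shortest existing route from its fuse locant, appends the new atoms it
needs, and closes back onto the consecutive-locant segment that starts at
the fuse locant. The closure offset along that segment is usually zero
(plain ortho-fusion, which yields naphthalene from `L66J` and
anthracene/phenanthrene from `L C666J`/`L B666J`), but perifused and
multicyclic systems need non-zero offsets; the parser finds them by a small
backtracking search constrained by the declared multicyclic points (each
must end up shared by at least three sub-rings, every other atom by at most
two) and by the declared system size. Those two declarations are exactly
what makes the citation list unambiguous, which is presumably why the
notation requires them. The search space is tiny (offsets are bounded by
ring size and blocks rarely cite more than six rings), so assembly is
effectively instant.

`build_locant_path()` validates the numbering: the locant path must visit
every ring atom exactly once, start at an atom of maximal ring-share count
(a perifused centre takes priority), pass through an adjacent multicyclic
point when on one, and minimize the locant sum of ring-shared atoms. One
formalization detail is deliberate: the path walks only perimeter
(consecutive-locant) bonds — ring-closure chords are not traversable. This
is this package's concrete reading of the rule that the path never crosses
a fuse junction except toward a multicyclic point; a fully unrestricted
Hamiltonian search can find chord-using paths with smaller locant sums that
no published WLN numbering uses, so the perimeter restriction is treated as
part of the rule. Under it, the construction's own numbering is verified
(exhaustively, for systems of up to 16 atoms) to be among the legal minima.

Macrocyclic notation defines a branch that wraps back onto the ring
(`&- D6J`: bond the pending branch to locant `D`, closing a declared
six-ring); a declared size that disagrees with the cycle actually closed is
reported. Spiro clauses substitute `&` for the locant branch character and
share a single atom. Bridges (a lone locant clause: a bond from the cited
position to the end of the path) and `D` chelate blocks (parsed as regular
blocks and flagged) follow minimal semantics and are marked experimental:
their full specification lives in the encoding manuals rather than in any
machine-readable source, and pseudo-bridge locant pairs collide with
locant-plus-boron heteroatom clauses, so the heteroatom reading wins.

## Implied bonding, kekulization, hydrogens

Two conventions from the notation's human-reader history are applied by
default and can be disabled (`implied_double = FALSE`):

* Adjacent `O` symbols imply a double bond: `OO` is dioxygen; hydrogen
  peroxide must be written `QQ`. With the flag off, a bare `O` with
  unfilled valence reads as the anionic oxygen of the tentative charge
  rules, so `OO` becomes the peroxide dianion.
* The `C` symbol is a full-valence carbon with at least one unsaturated
  bond: `SCN` gains its C#N triple. Deficits are placed on heteroatom
  neighbours first, then on later-written ones, bounded by each partner's
  free valence; an unplaceable deficit is a `ValenceError`.

WLN aromaticity is relaxed: a flagged cycle is aromatic if it carries the
*maximum number of double bonds* placeable after heteroatom assignment —
the 4n+2 count is never consulted. That is a maximum-matching problem over
the ring atoms that still have a free valence slot (`M`, ring `O`/`S`,
carbonyl `V` and indicated-hydrogen positions are barred). `max_matching()`
implements Edmonds' blossom algorithm — augmenting paths with odd-cycle
contraction, which on bipartite ring systems simply never contracts — and
matched bonds become double. Among equal-size maximum matchings any choice
is acceptable: the canonical SMILES is invariant to the tie-break, which
the tests confirm by shuffling the edge order. Unmatched eligible atoms
keep implicit hydrogens, computed at connection-table time from standard
valences (N 3/5, S 2/4/6, P 3/5, halogens 1, …) with charge adjustments;
explicit `H` nodes fold into their neighbour's hydrogen count.

The final connection table orders atoms by source position, so conversion
is a pure function of the string and options. The SMILES writer emits
kekulized bond orders explicitly and lets OpenBabel's aromaticity model
re-perceive them during canonicalization — exporting WLN's relaxed
aromaticity as lowercase atoms directly would bake a non-standard model
into the output.

## Scoring conversions

Reference comparison canonicalizes both sides with the same toolkit
(OpenBabel via ChemmineOB) and compares strings, after stripping stereo
descriptors from the reference — WLN carried essentially no stereo
information. Near-misses are scored by the Tanimoto coefficient over
OpenBabel FP2 path fingerprints, appropriate for the small drug-like
molecules WLN typically encodes. The triage pipeline mirrors the standard
curation procedure for legacy WLN records: strip any `&&` annotation suffix, try exact matching,
then full conversion, then extracted substrings (recording correction
suggestions, including recoverability by space skipping), otherwise flag
the record as an incorrect WLN. `run_benchmark()` aggregates a
`WLN<TAB>SMILES` table into set size, exact and greedy match counts
(benchmark lines are whole entities, so single-letter candidates are kept
there), conversion-correct counts and mean failure similarity.

## What the bundled data does and does not show

The package ships two small synthetic tables built for the test suite:
`synthetic_smith.tsv`, sixty-odd rule-by-rule examples (chains, branches,
ions, shorthand, element codes, mono- and polycyclics, heterocycles,
spiro, macrocyclic morphine) with reference SMILES written independently
from the structures, and `synthetic_triage.tsv`, a curation set with OCR
faults, annotation suffixes, junk rows and one wrong reference. Passing on
these shows the machinery is internally correct on every covered
construction class; it does not measure recall on the tens of thousands of
real WLN records in public databases, whose exports are not redistributed
here. The test suite contains a reproduction check that
activates when those four exports are placed under
`inst/extdata/benchmarks/`; until then it reports their absence. Real
records also exercise rare constructs — chelates, metallocene contractions,
ionic charge clauses — that this package either flags as unsupported
(charge clauses beyond `K`'s implied +1: their syntax exists only in the
encoding manuals, and guessing it would be worse than refusing) or treats
with minimal experimental semantics (bridges, chelates).

## Numerical and procedural choices

* Locant `&` extensions add 24 per mark (the size of the A–X range), so
  `A&` is position 25; round-tripping is tested to position 200.
* Digit `0` is accepted by the matcher but rejected by the parser as a
  zero-length chain; no published compound example uses it.
* Greedy tie-breaks: leftmost-longest, resume after the match end; spans
  are 0-based half-open.
* The assembly search explores closure offsets in increasing order and
  shortest routes in lexicographic order, so results are deterministic.
* Property tests run on seeded pseudo-random inputs: 1,500 (unit) and
  10,000 (acceptance) strings for NFA/DFA/minimal-DFA language agreement,
  random 60–200-character texts against a naive all-substrings extraction
  oracle, and 60 random graphs of up to 10 vertices against brute-force
  matching enumeration. Sizes were chosen to keep the default suite in the
  tens of seconds while covering every state of the machine many times
  over.
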