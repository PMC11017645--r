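# wlntools — extraction and conversion of Wiswesser Line Notation

Wiswesser Line Notation (WLN) is the line notation chemists used to encode
molecules before SMILES and InChI existed: strings over `A–Z`, `0–9` and the
four punctuation marks `&`, `-`, `/` and space, designed for punch-card
machines. Decades of chemical literature, supplier indexes and database
records carry structures only as WLN, and much of that text has passed
through OCR since. `wlntools` is for anyone modernising such legacy data: it
finds candidate WLN strings in free text, converts them to SMILES or InChI,
and scores conversions against reference structures so that incorrect
database entries can be identified and corrected.

## What is inside

* **Symbol semantics** (`wln_symbol_table()`, `locant_to_index()`): each WLN
  character's element or functional-group meaning, its *WLN degree* (the
  number of allowed branches, not a bond-order sum), terminator and locant
  roles, implied charges and implied methyl fills (`X`, `Y`, `K`).
* **A grammar-derived matcher** (`build_matcher()`, `match_exact()`,
  `match_greedy()`, `wlngrep()`): an NFA built from a relaxed WLN token
  grammar (unbounded branches and closures, but token adjacency enforced —
  e.g. explicit `U` next to the must-unsaturate carbon `C` is rejected),
  determinized by subset construction and minimized; greedy extraction
  returns leftmost-longest candidates from text, with single-letter matches
  suppressed by default and CAOCI `&&` annotation suffixes stripped.
* **A full parser** (`parse_wln()`): character-by-character construction of
  the WLN graph — branch stack and `&` popping, ions (`space &`), digit
  chains, `-XX-` element codes, `U`/`UU` unsaturation — with ring blocks
  (`L`/`T`/`D` … `J`) spliced out and assembled separately: fused,
  perifused/multicyclic, bridged, spiro, chained and macrocyclic ring
  systems with locant-path numbering, heteroatom placement and per-ring
  aromaticity flags. Run-time recovery raises over-branched `M` to `N` and
  skips OCR-damaged spaces (disable with `strict = TRUE`).
* **Chemistry assembly** (`expand_shorthand()`,
  `apply_implied_unsaturation()`, `kekulize()`,
  `build_connection_table()`): shorthand expansion (`V` carbonyl, `W`
  dioxo, methyl fills), the historical implied-double-bond conventions
  (`OO` is O=O; `SCN` is SC#N), and kekulization by **maximum matching**
  (Edmonds' blossom algorithm; WLN aromaticity places the maximum number of
  double bonds and does not consult the Hückel rule).
* **Conversion & scoring** (`wln_convert()`, `triage()`,
  `run_benchmark()`): canonical SMILES / InChI through OpenBabel
  (ChemmineOB), stereo-stripped canonical-string comparison, FP2/Tanimoto
  similarity for near-misses, and the four-step triage pipeline (exact
  match → full conversion → substring rescue → reject) over `WLN<TAB>SMILES`
  tables.

Command-line wrappers `wlngrep.R`, `readwln.R` and `wlnbench.R` live in
`inst/cli/`.

## A worked example

```r
library(wlntools)

wln_convert("Q1XGG2Y1Q1Z")
#> [1] "NCC(CCC(CO)(Cl)Cl)CO"

wln_convert("L C666J")           # anthracene
#> [1] "c1ccc2c(c1)cc1c(c2)cccc1"

# the same molecule in two notations: macrocyclic vs plain locant path
wln_convert("T-T665 B6 2AB O KO NUT &TTJ IQ MQ B2N1 &- D6J")
#> [1] "OC1C=CC2C34C1Oc1c4c(CC2N(CC3)C)ccc1O"
wln_convert("T B65 H6 F6 F6 3FGH R AO DU GX PN HU- MTT &TTJ CQ JQ P1")
#> [1] "OC1C=CC2C34C1Oc1c4c(CC2N(CC3)C)ccc1O"

match_greedy(text = "prepared Q1XGG2Y1Q1Z in two steps")
#>   start end        text
#> 1     9  20 Q1XGG2Y1Q1Z

triage("Z2Z & GH", "NCCN.Cl")$substrings   # OCR-damaged hydrochloride
#> [1] "Z2Z" "GH"
```

The first call reads: hydroxyl, one-carbon chain, a four-branch carbon
carrying two chlorines, a two-carbon chain, a three-branch carbon, and so
on — the converter returns OpenBabel's canonical SMILES for
2,2-dichloro-substituted amino-diol, and the two morphine notations agree
to the same canonical string.

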