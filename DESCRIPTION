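Package: wlntools
Title: Extraction and Conversion of Wiswesser Line Notation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for Wiswesser Line Notation (WLN), the pre-SMILES
    chemical line notation used by legacy chemical databases and documents.
    Provides a grammar-derived finite-state matcher ('wlngrep') for
    recognising and extracting candidate WLN strings from free text, a full
    character-by-character parser that converts WLN strings (acyclic and
    cyclic, including fused, perifused, multicyclic, bridged, spiro and
    macrocyclic ring systems) into molecular graphs, kekulisation by maximum
    matching, emission of canonical SMILES and InChI through OpenBabel, and
    a benchmark/triage harness for scoring conversions against reference
    SMILES tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
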