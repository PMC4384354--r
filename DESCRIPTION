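Package: fraglib
Title: Interface Fragment Pair Libraries for Protein Complex Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing protein-protein interfaces into pairs of
    9-residue backbone fragments, clustering those fragment pairs by
    superposition RMSD into a library of recurrent binding motifs,
    characterizing the secondary-structure preferences of the motifs, and
    using the library to enumerate candidate rigid-body models of a
    two-domain complex. Includes deterministic generators of synthetic
    helices, strands, coils and packed dimers so the whole pipeline can be
    exercised without downloading structure databases.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
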