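Package: snowflake
Title: Allele-Specific HLA Surface Accessibility and Epitope Mismatch Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes per-residue solvent-accessible surface area of HLA Class I
    structures with the Shrake-Rupley algorithm, compares structures through
    backbone-dihedral (SDA/RMSDA) and surface-area (SSA/RMSSA) distance metrics,
    trains a bidirectional long short-term memory network that predicts
    per-position solvent accessibility from the alpha-chain amino-acid sequence,
    and scores donor/recipient HLA mismatches restricted to surface-accessible,
    allele-specific positions (the Snowflake epitope mismatch score). Includes a
    synthetic-fixture generator (ideal-geometry backbones, atom clusters with a
    Monte-Carlo surface-area oracle, allele families with ground-truth
    accessibility) so the full pipeline can be exercised without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
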