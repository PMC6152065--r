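Package: hmwgs
Title: Identification of Wheat High-Molecular-Weight Glutenin Subunits from
    RP-HPLC and SDS-PAGE Evidence
Version: 1.0.0
Authors@R: person("Jae", "Park", email = "jae.park@example.org",
    role = c("aut", "cre"))
Description: Calls allelic compositions of wheat high-molecular-weight
    glutenin subunits (HMW-GS) at the Glu-A1, Glu-B1 and Glu-D1 loci by
    combining reversed-phase HPLC retention-time evidence with SDS-PAGE
    band-mobility evidence. Provides chromatogram peak detection with
    baseline correction and sub-grid apex refinement, retention-time
    matching against a packaged statistical reference table, constraint
    based peak-to-locus assignment, resolution of retention-time-ambiguous
    candidates by gel mobility, peak intensity (1Bx7 overexpression) and
    Dx-Dy linkage, discrepancy reporting against prior assignments, and a
    seeded synthetic chromatogram and gel-lane generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
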