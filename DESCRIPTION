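Package: snotool
Title: Structural Annotation of S-Nitrosylation Sites and Proximal Cysteines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and structurally characterizes cysteines in the spatial
    neighborhood of S-nitrosylation (SNO) sites in protein structure models.
    Provides disulfide-bond stereochemistry (S-gamma distances, chi1 rotamers,
    CB-SG-SG-CB dihedrals with A-D grading), Shrake-Rupley solvent
    accessibility with relative side-chain normalization, three-state
    secondary-structure assignment from backbone hydrogen bonds, an empirical
    cysteine pKa model with a sentinel convention for disulfide-locked thiols,
    and side-chain center-of-mass contact searches. Two pipelines build on
    these primitives: a site-discovery pipeline that annotates vicinal and
    proximal cysteine pairs from a PTM site table plus a directory of
    structure models, and an ensemble pipeline that summarizes per-model
    metrics over multi-model structural ensembles and classifies missense
    variants as stabilizing, neutral, destabilizing or uncertain for the
    SNO-induced disulfide population-shift mechanism. A deterministic
    synthetic-structure generator makes every analysis testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
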