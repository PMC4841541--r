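Package: phosready
Title: Kinase Substrate Scanning, Peptide Threading and Phospho-Readiness
    Scoring of Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for in-silico analysis of kinase substrate recognition on
    arginine/serine (RS) repeat domains, modelled on the Akt and SRPK1
    phosphorylation of the Lamin B Receptor N-terminal RS domain. Provides
    consensus-motif scanning and rule-based site classification (minimal Akt
    consensus R-X-R-X-X-S/T and SRPK-type Arg-Ser dipeptides), extraction of
    10-mer candidate substrate peptides, template-based threading of candidates
    onto a kinase-bound peptide backbone, fixed-width PDB input/output for
    single structures and multi-model ensembles, conformational-ensemble
    analytics (Kabsch superposition, RMSD convergence, RMSD-cutoff neighbour
    clustering, structure averaging, RMSF and Debye-Waller B-factor
    estimation), and catalytic-geometry readiness scoring (Ser-O-gamma to
    ATP P-gamma distance, key-residue contacts, competence classes, and the
    efficiency-mobility correlation). A synthetic-ensemble generator emulates
    multi-replica molecular-dynamics output so the whole pipeline runs at desk
    scale without a simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
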