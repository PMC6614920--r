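Package: tectofit
Title: Thermodynamic Analysis of TectoRNA Self-Assembly
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of RNA tertiary-module self-assembly
    measured by gel-shift titrations and lead(II) cleavage footprinting.
    Fits the homodimerization isotherm (dissociation constant Kd and
    active fraction beta) to fraction-dimerized data, converts Kd values
    into association free energies (dG, ddG versus a reference construct,
    and the ligand-induced shift ddG_FA), quantifies chemical-probing
    band intensities under a two-state monomer/dimer model to estimate
    apparent Kd values, and analyses loop-receptor sequence signatures
    (pair classification, mutation distances, sequence families, IUPAC
    consensus). A synthetic-data generator emulates both assays so the
    full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
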