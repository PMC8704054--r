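Package: qtykit
Title: QTY-Code Water-Solubilization of Membrane Proteins and Native/Variant Comparison
Version: 0.1.0
Authors@R: person("QTY", "Toolkit Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Applies the QTY code -- systematic replacement of the hydrophobic
    residues leucine, isoleucine, valine and phenylalanine by the hydrophilic
    residues glutamine, threonine and tyrosine within annotated transmembrane
    segments -- to protein sequences, and quantifies the consequences of the
    transformation. Provides sequence and segment-annotation I/O with a
    hydropathy-based transmembrane fallback, positional identity and variation
    statistics, isoelectric point and molecular weight calculation in the
    Expasy convention, PDB parsing with Kabsch Calpha superposition and RMSD,
    Shrake-Rupley solvent-accessible surface area with hydrophobic patch
    detection, idealized alpha-helix and seven-helix-bundle generators for
    download-free testing, and a batch report driver with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
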