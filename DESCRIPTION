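Package: switchmd
Title: Activation Microswitch and G-Protein Coupling Analysis for GPCR
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level analysis of class A G-protein-coupled receptor
    (GPCR) activation hallmarks in molecular dynamics trajectories stored as
    multi-model PDB files. Implements Ballesteros-Weinstein residue mapping
    with sequence-motif anchor detection (DRY, CWxP, NPxxY), chi1 side-chain
    rotamer switch tracking, the TM3-TM6 ionic lock and TM5-TM7 tyrosine
    distances, TM6 kink angles, receptor/G-alpha approach trends with a
    best-fit-line coupling classifier, continuous internal water-channel
    detection across the hydrophobic barrier, and C-alpha principal component
    analysis with the normalized covariance-matrix overlap between
    simulations. A deterministic synthetic-trajectory generator with known
    ground truth (drift slope, rotamer kinetics, TM6 bend, channel state)
    supports validation of every analysis stage without MD data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
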