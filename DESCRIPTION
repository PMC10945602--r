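Package: chromoMC
Title: Mesoscale Chromatin Monte Carlo with Implicit Transcription-Factor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nucleosome-resolution mesoscale chromatin modelling by Metropolis
    Monte Carlo. Fibers are built from uniform, life-like, or gene-locus
    topologies (nucleosome-free regions, linker-histone occupancy, histone-tail
    acetylation islands) and sampled with pivot, local, and configurational-bias
    tail-regrowth moves under a worm-like-chain DNA model with Debye-Hueckel
    electrostatics and excluded volume. Bivalent transcription-factor binding
    (Myc:Max-like bridging) is modelled implicitly as dynamically engaged
    harmonic restraints between marked linker-DNA beads. Analysis tools compute
    packing ratios, sedimentation coefficients, radii of gyration, simulated
    contact maps and contact-decay profiles, DBSCAN microdomain detection, and
    alpha-shape promoter accessibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
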