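Package: genomesizer
Title: Genome Size Estimation from Sequence Data and Cytometry, with a
    Repeat-Collapse Simulator
Version: 0.1.0
Authors@R:
    person("Morgan", "Reeve", email = "morgan.reeve@example.org",
           role = c("aut", "cre"))
Description: Estimates genome size from sequencing reads by canonical k-mer
    spectra and by modal-coverage (Lander-Waterman) extrapolation of mapped
    read depth, converts flow-cytometry and Feulgen-densitometry measurements
    of nuclear DNA content into genome sizes via internal reference standards,
    and compares assemblies by shredding them into fixed-length synthetic
    reads aligned with a seed-and-extend local aligner under blastn-style
    scoring. A synthetic-genome module generates repeat-rich genomes with
    dispersed and tandem repeat families, simulates reads, and produces
    collapsed-repeat assemblies, so that the systematic underestimation of
    genome size caused by repeat collapse can be reproduced and studied under
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
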