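Package: opsinminer
Title: Opsin Gene Mining, Diagnostic-Residue Classification and
    Photobehaviour Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering and classifying opsin
    genes in nucleotide assemblies of non-model invertebrates.  Candidate
    loci are found by translated (six-frame) Smith-Waterman homology
    search against a reference opsin panel, validated by reciprocal best
    hit against a mixed GPCR decoy database, checked for seven
    transmembrane helices by Kyte-Doolittle hydropathy, and mapped onto a
    mammalian rhodopsin residue frame to call the diagnostic sites of the
    opsin family (Schiff-base lysine K296, counterions E113/Y113 and
    E181, the D(E)RY tripeptide, the NPxxY(x)6F pattern and its internal
    NxQ/HxK triad, disulfide and palmitoylation cysteines).  Candidates
    are assigned to opsin families by trimmed local-alignment similarity,
    corroborated by a bootstrapped neighbor-joining placement, matched
    against transcript sequences to flag detected expression, and a
    companion module analyses day/night photo-behaviour count tables with
    F-test and normality gating and unpaired t-tests.  A fully seeded
    synthetic-data generator provides assemblies, transcripts and
    behaviour tables with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
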