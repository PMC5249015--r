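Package: dgwarp
Title: Alignment and Clustering of Epigenomic Peak Profiles by Dynamic Genome Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous alignment and clustering of ChIP-seq peak profiles
    using band-constrained, strand-flip-aware, multidimensional Dynamic Time
    Warping. Peaks called upstream (e.g. by MACS2) are binned into fixed-width
    windows, pairwise warping distances are computed under a Sakoe-Chiba band,
    and profiles are grouped by complete-linkage hierarchical clustering with
    per-node prototype sequences obtained by weighted warping averages.
    Includes a peak-shape simulation benchmark scored with the multi-class
    Matthews Correlation Coefficient, points-of-interest histogram and entropy
    analyses of warped landmarks, and transcription-factor cluster-enrichment
    curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    parallel,
    jsonlite,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
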