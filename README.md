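# dgwarp — alignment and clustering of epigenomic peak profiles

Histone-mark ChIP-seq peaks are extended, structured objects: a
H3K4me3 enrichment region typically shows a bimodal peak flanking the
transcription start site, with sub-peak extents that stretch or shrink
with the gene architecture underneath. Grouping such peaks by *shape*
requires an alignment that can locally rescale the genomic axis.
`dgwarp` does this with Dynamic Time Warping (DTW): for binned peak
profiles **a** = (a₁,…,a_N) and **b** = (b₁,…,b_M) it finds the warping
path **p** minimising

  D(**a**, **b**) = min_p Σᵢ d(a_{p⁰ᵢ}, b_{p¹ᵢ})

subject to pinned endpoints and monotone steps of at most one, with a
Sakoe-Chiba band (default half-width 12 bins) bounding compression, a
strand-flip-aware minimum over both orientations of the second profile,
squared-Euclidean or cosine local distances, optional height
normalization, and joint alignment of multiple epigenomic tracks. The
pairwise distances drive complete-linkage hierarchical clustering;
every dendrogram node carries a prototype sequence obtained by
weighted flip-aware DTW averaging of its children, onto which cluster
members can be warped for visualisation and landmark analysis.

The package is aimed at regulatory genomics analyses downstream of a
peak caller (e.g. MACS2): cluster peaks by shape, export per-cluster
BED files, examine how transcription start sites or splice sites align
under the warping, and test whether transcription-factor binding is
concentrated in particular shape clusters. A self-contained simulation
benchmark (five seed shapes, multiplicative noise, bin
indels, orientation flips) scores the whole pipeline with the
multi-class Matthews Correlation Coefficient.

## Worked example

Simulate the 500-peak benchmark dataset and cluster it end to end:

```r
library(dgwarp)

sim <- simulate_dataset(simulation_params(v = 0.1, p = 0.1, fp = 0.1,
                                          rng_seed = 42))
sim
#> <dgw_sim> 500 profiles from 5 seeds (v=0.1, p=0.1, fp=0.1), 56 flipped

labels <- dgw_cluster(sim$profiles, dtw_config(), n_clusters = 5)
table(truth = sim$labels, cluster = labels)
#>      cluster
#> truth   1   2   3   4   5
#>     1 100   0   0   0   0
#>     2   0 100   0   0   0
#>     3   0   0 100   0   0
#>     4   0   0   0 100   0
#>     5   0   0   0   0 100

mcc_multiclass(sim$labels, labels)
#> [1] 1
```

Each of the 500 simulated peaks — despite 10% per-bin noise, random
bin deletions/duplications and 56 orientation flips — is returned to
the cluster of its generating seed shape (multi-class MCC of 1). The
dendrogram behind the labels carries prototypes for every node:

```r
dend <- attr(labels, "dendrogram")
dend
#> <dgw_dendrogram> 500 leaves, 499 internal nodes, heights 0.0138349-14.2407
compute_prototype(dend, nrow(dend$hclust$merge))  # root prototype
#> <dgw_prototype> 40 bins x 1 track(s), 500 leaves
```

For real data, start from a BED file and BAM files instead:

```r
run <- dgw_worker(regions = "peaks.bed",
                  alignment_sources = c("H3K4me3.bam", "H3K9ac.bam"),
                  out_dir = "run", n_clusters = 45)
dgw_report(run, "report", poi_beds = list(TSS = "tss.bed"),
           tf_beds = list(ATF3 = "atf3_peaks.bed"))
```

which writes the distance matrix, linkage table, Newick tree,
prototypes, one BED per cluster, a JSON manifest, and static report
artefacts (pre/post-warp heat maps, landmark histograms with entropy
changes and bootstrap intervals, TF enrichment curves).

A command-line front end wrapping the same functions ships at
`inst/cli/dgw` (subcommands `worker`, `simulate`, `benchmark`,
`report`).

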