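# kfmindex

Succinct, FM-index-like storage and traversal of k-mer de Bruijn graphs in
R, for people who need to hold the k-mer graph of a large read set in a few
bits per vertex and still walk it: assembler writers, k-mer-level QC, and
anyone indexing more genome than their RAM would like.

## The data structure

For a read set and word length *k*, the order-(k−1) de Bruijn subgraph has
the (k−1)-mers as vertices and the k-mers as edges. The kFM-index keeps the
vertices in lexicographic order but never stores their strings: vertex *i*
holds only σ in-edge flags η(a,i) and one group-end flag f_i marking runs of
vertices that share a (k−2)-prefix — σ+1 = 5 bits per vertex for DNA.
Navigation goes through a single FM-index-style map,

    ρ(a, i) = 1 + Σ_{b<a} τ(b) + c(a, i) = min{ j : v_j ≥ a·v_i⁻ },

the position of the origin vertex of the `a` in-edge of v_i, where c(a,i)
counts vertex *groups* with an `a` in-edge before position i (groups, not
vertices, because all members of a group share in-edge origins). Only every
q-th column of ρ is stored, decomposed as κ = u + qU with checkpointed U —
σ(lg q + 2)/q ≈ 0.875 extra bits per vertex at the default q = 32, about
6.2 bits per vertex all in. Backward search, k-mer membership, vertex-string
reconstruction, index merging, pruning of the sentinel-padded
("final-completing") vertices that construction adds at read ends, and
unitig extraction are all built on ρ. A diploid read simulator generates
the benchmark world the test suite validates against.

## Worked example

Index a simulated diploid sample (50 knt per haplotype, 52 realized SNPs,
15,000 × 100 nt error-free reads ≈ 30× coverage) and pre-assemble it:

```r
library(kfmindex)
cfg   <- kfm_sim_config(genome_length = 5e4, n_reads = 15000, rng_seed = 42)
hap   <- kfm_simulate_diploid(cfg)       # 52 SNPs at these settings
reads <- kfm_simulate_reads(hap, cfg)
ix    <- kfm_build(reads, k = 23, add_rc = TRUE)
ix
#> kFM-index: k = 23 (22-mer vertices), n = 102,271 vertices, 102,374 edges
#>   alphabet: ACGT  store: q = 32, w = 64
```

About 2 × 50,000 vertices (both haplotypes, both strands) plus 2·(k−1) per
SNP strand. Each SNP forms a bubble; between bubbles the graph is a simple
path, so pre-assembly should give 2·(3s+1) unitigs for s = 52 well-separated
SNPs — and does:

```r
nrow(kfm_extract_paths(ix))
#> [1] 314                      # = 2 * (3*52 + 1)
kfm_query(ix, substr(hap$hap1, 1000, 1022))
#> [1] TRUE                     # any genome 23-mer is an edge
kfm_memory_estimate(ix$n, sigma = 4, q = 32)
#> kFM-index memory estimate (sigma = 4, q = 32, word = 64 bit)
#>   core (eta + f)     : 5.000 bit/vertex (+0.333 packing)
#>   rho store          : 0.875 bit/vertex
#>   total (packed)     : 6.208 bit/vertex
```

`kfm_serialize()` / `kfm_deserialize()` round-trip the index bit-exactly in
the `KFMI` format at the accounted size; `kfm_merge()` combines indexes
built from read subsets (`kfm_build(..., partition_size = ...)` does the
partitioning and pairwise merging for you); `exec/kfm` exposes the same
pipeline as a command line (`kfm build|query|merge|prune|assemble|stats|simulate`).

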