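Package: kfmindex
Title: Succinct FM-Index-Like Storage and Traversal of k-mer de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("kfmindex", "maintainers", email = "kfmindex@example.org", role = c("aut", "cre"))
Description: Builds and queries the kFM-index, a compact representation of the
    order-(k-1) de Bruijn subgraph induced by the k-mers of a read set. Vertices
    are stored implicitly as sorted (k-1)-mers using sigma+1 bits each (in-edge
    flags plus a vertex-group end flag), together with a sparse, checkpointed
    table of previous-vertex positions that plays the role of the FM-index rank
    structure. Supports backward search, k-mer membership queries, vertex string
    reconstruction, merging of indexes, pruning of sentinel-padded vertices,
    unitig pre-assembly, FASTA/FASTQ input with quality-based read splitting,
    binary serialization, and a diploid read simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
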