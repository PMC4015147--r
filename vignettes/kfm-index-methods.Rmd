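---
title: "The kFM-index: model, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kFM-index: model, algorithms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfmindex)
```

## The model

A set of sequencing reads $S$ determines, for a chosen word length $k$, the
set $S[k]$ of its $k$-mers. The natural graph view is the **de Bruijn
subgraph of order $k-1$**: vertices are the $(k-1)$-mers $S[k-1]$, and each
$k$-mer $e$ is an edge from $e_{[1,k-1]}$ to $e_{[2,k]}$. The kFM-index
stores exactly this subgraph, in a form that is close to an FM-index of the
vertex set: vertices are kept in lexicographic order but their strings are
*not* stored — each vertex record holds only

* $\sigma$ **in-edge flags** $\eta(a,i)$ (is $a \cdot v_i$ an edge?), and
* one **group-end flag** $f_i$, set on the last vertex of each run sharing a
  $(k-2)$-prefix (a *vertex group*).

That is $\sigma + 1$ bits per vertex — 5 bits for DNA — and the whole graph,
including every vertex string, is recoverable from these bits alone.

### Sentinel completion

Vertices that occur only as read suffixes have no out-edge and could never
be reached by backward search, so the stored graph is *final-completed*:
from every $(k-1)$-suffix a path of sentinel-padded vertices
$v_{[2,k-1]}\$,\; v_{[3,k-1]}\$\$,\;\dots$ leads down to the unique final
vertex $\$^{k-1}$, which always occupies position 0. The sentinel `$` sorts
before every letter; a virtual $\infty$ sorts after every letter. Because
construction pads *every* read suffix, most of these vertices are
redundant and are removed again by pruning (below).

### The previous-position map

All navigation uses one function, the analogue of FM-index rank:

$$\rho(a, i) = 1 + \sum_{b<a} \tau(b) + c(a, i),$$

where $\tau(b)$ counts vertex groups containing a $b$ in-edge and $c(a,i)$
counts such groups wholly before position $i$. If $a \in E_{v_i}$, that
edge originates from vertex $\rho(a,i)$; equivalently $\rho(a,i) =
\min\{j : v_j \ge a\,v_i^{-}\}$. Counting *groups* rather than vertices is
what accommodates branching: all members of a group share the same in-edge
origins.

Backward search folds $\rho$ right-to-left
($\gamma(ax, i) = \rho(a, \gamma(x, i))$), giving the half-open interval
$[\alpha(x), \beta(x))$ of vertices with prefix $x$, membership tests for
full strings (one $\eta$ check plus one $\rho$ per letter), and — through
the inverse map $\rho^{inv}$, found by binary search over the stored table —
reconstruction of any vertex string in $O(k \log(n\sigma))$.

### The sparse store

Storing $\rho$ outright would cost $\sigma \lg n$ bits per vertex, so only
every $q$-th column is kept: $\kappa(a\zeta + r) = \rho(a, i_r)$ at
positions $i_r = \min(rq, n)$. Because consecutive $\kappa$ values differ
by at most $q$, each is decomposed as $\kappa = u + qU$ with $u \in [0,q)$
bit-packed, the unit increments $\Delta U$ stored as single bits, and every
$w$-th $U$ checkpointed in a full word. Reconstruction of any stored value
is exact; an arbitrary $\rho(a,i)$ is then recovered by scanning at most
$q$ vertex records forward from $i_r$ (rewinding first to the start of a
group that straddles $i_r$, so each group is counted once).

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | — | $k$-mer length (edges); vertices are $(k-1)$-mers. Words are packed in base $\sigma+1$ into 64-bit integers, so $k \le 26$ for DNA. |
| `q` | 32 | stride between stored $\rho$ columns. Memory cost is $\sigma(\lg q + 2)/q$ bits/vertex (1.5 / 0.875 / 0.5 at $q=16/32/64$); query cost grows linearly in $q$, and gains below $q \approx 30$ are marginal, so 32 is the shipped balance. |
| `w` | 64 | checkpoint stride of the $U$ sequence; one 64-bit word per $w$ entries contributes the "+1" inside $\lg q + 2$. |
| `partition_size` | `Inf` | maximum edge words sorted in memory at once; smaller values trade speed for memory via pairwise merging. |
| `prune_policy` | `final_only` | when to remove redundant sentinel-padded vertices; `every_merge` keeps intermediate indexes small at extra cost. |
| `quality_threshold` | 30 | Phred cutoff; reads are split at bases below it (and at non-alphabet symbols), which removes most raw-read errors before indexing. |

Memory accounting is exact and available analytically via
`kfm_memory_estimate()`: $\sigma + 1$ bits of core data per vertex, an
effective $64/\lfloor 64/(\sigma+1)\rfloor = 5.333$ bits once vertices are
packed whole into words, plus the store, about 6.2 bits per vertex for DNA
at $q = 32$. The `KFMI` serialization reproduces these numbers up to the
header and per-array word rounding, which the test suite asserts at
$n = 10^6$.

## Construction, merging, pruning

**Construction** enumerates every $k$-substring plus the $k-1$
sentinel-padded words of each read as (target, in-letter) integer keys,
sorts, deduplicates, and emits records in one pass. A subtlety worth
stating: a vertex that is only ever an edge *origin* (a read-start
$(k-1)$-mer that never recurs internally) is the target of no word, yet
$\rho$ must be able to land on it, so the word stream carries an explicit
marker for each read-start vertex.

**Merging** two indexes $A$ and $B$ ($n_A \le n_B$) places A-vertex $i$ at
merged position $i + \alpha_B(v^A_i)$. Rather than materializing strings, a
joint recursion extends prefixes one letter at a time on both indexes; the
sentinel-padded vertex of each prefix is tracked through the in-edge chain
of its parent's sentinel vertex. Three bit arrays of exactly
$3n_A + 2n_B$ bits (source, duplicate, group-end-clear) then drive a single
sequential pass; duplicates combine by OR. The result is asserted
record-identical to a direct build of the union.

**Pruning** walks the sentinel tree depth-first from $\$^{k-1}$ (at most
$k-2$ steps). An in-edge $a$ of a single-`$` vertex $u\$$ is dropped when
another vertex $ub$ of the same group has an $a$ in-edge (its origin $au$
remains reachable through $ub$); a sentinel vertex with no surviving
in-edges is dropped together with the in-edge of its `$`-extension.
Because $\rho$ depends on group composition, marks are collected first and
applied in one compaction pass. Pruning never changes the sentinel-free
$k$-mer set and is idempotent.

**Pre-assembly** classifies vertices by degree in one sweep (out-degrees
are accumulated through running per-letter $\rho$ counters, no strings
needed) and walks backward from every non-simple vertex through simple
ones; collected in-edge letters are the first letters of the traversed
vertices, so a path's sequence is the reversed letters plus the terminal
vertex string, with trailing sentinels trimmed and sentinel-only paths
dropped.

## Numerical and design choices

* **Indices are 0-based** and intervals half-open, matching the
  $[\alpha, \beta)$ convention; R users see this convention everywhere.
* **Letter codes** are A=0 < C=1 < G=2 < T=3 by default; `$` is a virtual
  code below 0 (never stored in $\eta$), $\infty$ a virtual code above
  $\sigma-1$.
* **Backward-search minimality.** $\gamma(x, 0)$ equals
  $\min\{i : x \le v_i\}$ for $|x| < k$. For $|x| \ge k$ it is a *lower
  bound* on the first vertex with a compatible forward extension — the fold
  tracks only ranks, not whether the dominating in-edge exists — with
  equality whenever $x$ is realizable as a path. The membership algorithm
  therefore checks $\eta$ at every step; the property suite tests exactly
  these corrected statements.
* **Vertex records in 32-bit integers** limit $\sigma \le 30$ (DNA needs
  4); 64-bit word packing appears only in the serialized form.
* **All-simple cycles** can arise for (near-)circular input and are not
  covered by the anchored walk; they are detected by a visited-mark sweep
  and emitted once each with `circular = TRUE`, a documented extension
  excluded from benchmark comparisons.
* **Degenerate inputs**: an empty input yields the 1-vertex index
  $\{\$^{k-1}\}$; strings shorter than $k-1$ induce no vertex and are
  skipped with a warning; foreign symbols are an error at this layer
  (the FASTQ reader splits reads at them instead).

## The simulator and what a green test establishes

`kfm_simulate_diploid()` / `kfm_simulate_reads()` emulate the reference
benchmark this package validates against: haplotype 1 is uniform random
over ACGT (1 Mnt by default), haplotype 2 differs at each position
independently with probability 0.001 (a SNP substitutes a uniformly chosen
different base), and 300,000 reads of 100 nt (30x total coverage) are drawn
uniformly from the two haplotypes with independent per-base substitution
errors at 0, 0.1% or 1%. Reads are sampled from the forward strand and
reverse-complemented at indexing time, which yields the same $k$-mer set as
strand-symmetric sampling.

With error-free reads the pruned graph measures about $2 \times 10^6$
vertices plus $2(k-1)$ per SNP strand, and pre-assembly yields about
$2(3g+1)$ uniquely determined paths for $g$ SNP *clusters* (SNPs closer
than $k$ merge into one bubble) — the tests assert both against the
realized SNP draw. These counts inherit the binomial spread of the SNP
draw (about 32 SNPs, hence about 190 paths, per seed at 1 Mnt).

The generator does **not** emulate real data features such as indels,
quality-correlated or position-dependent error profiles, coverage biases,
paired ends, or genomic repeat structure. Consequently a green benchmark
test establishes that the index machinery (construction, pruning,
pre-assembly) behaves correctly at scale under the stated model — not that
the simulator reproduces any particular sequencing instrument. At the 1%
error rate the graph size is dominated by error-induced vertices and
becomes sensitive to unstated details of the error process (errors near
read ends create fewer than $k-1$ novel vertices; clustered errors share
windows); reference counts for that regime assume roughly $k$ novel
vertices per error and are *not* reproduced by this per-base Bernoulli
model (measured about 19% lower), while the 0.1% counts are matched within
about 1%. The corresponding acceptance check is intentionally left failing
rather than loosened.

## Known limitations

* Single-threaded; construction is sort-bound
  ($O(Nk \lg\sigma \lg N)$ in memory, merges add a coverage-dependent
  factor when partitioned).
* No $k$-mer multiplicities, hence no frequency-based error correction;
  quality splitting is the only error handling.
* $\sigma \le 30$ and $(\sigma+1)^k < 2^{62}$; DNA supports $k \le 26$.
* Disk-backed external sorting is not implemented; `partition_size` plus
  merging is the supported low-memory route.

## A worked miniature

```{r toy}
ix <- kfm_build(c("ACG", "CGT", "CGA"), k = 3)
ix
kfm_vertex_string(ix, 0:(ix$n - 1))
kfm_prev_position(ix, "A", 0)       # origin of the A in-edge of $$
kfm_prefix_interval(ix, "G")        # the vertices GA, GT
kfm_contains(ix, "ACGT")            # ACG and CGT are both edges
kfm_extract_paths(ix)$sequence      # the three unitigs
```
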