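# Diploid read simulator: two near-identical random haplotypes and uniform
# substitution-error short reads, matching the benchmark conditions the
# index is validated against (2 x 1 Mnt, 0.1% SNPs, 300 k x 100 nt reads at
# error rates 0 / 0.1% / 1%, i.e. 30x coverage).

#' Simulation configuration
#'
#' Defaults describe the reference benchmark: a diploid pair of 1 Mnt
#' random sequences differing at rate 0.001, and 300,000 reads of 100 nt
#' (30x coverage) with substitution errors only.
#'
#' @param genome_length Haplotype length in nt (default 1e6).
#' @param snp_rate Per-position probability that haplotype 2 differs
#'   (default 0.001).
#' @param n_reads Number of reads (default 300000).
#' @param read_length Read length in nt (default 100).
#' @param error_rate Per-base substitution error rate (benchmarked values:
#'   0, 0.001, 0.01; default 0).
#' @param rng_seed Optional integer seed; when set, output is byte-identical
#'   across runs.
#' @return A list of class `kfm_sim_config`.
#' @export
kfm_sim_config <- function(genome_length = 1e6, snp_rate = 0.001,
                           n_reads = 3e5, read_length = 100,
                           error_rate = 0, rng_seed = NULL) {
  stopifnot(genome_length >= 1, read_length >= 1,
            read_length <= genome_length,
            snp_rate >= 0, snp_rate <= 1, error_rate >= 0, error_rate <= 1,
            n_reads >= 0)
  structure(list(genome_length = as.integer(genome_length),
                 snp_rate = snp_rate, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, rng_seed = rng_seed),
            class = "kfm_sim_config")
}

# substitute positions `at` of base-character vector `chars` with a
# uniformly chosen *different* base
substitute_bases <- function(chars, at, letters) {
  if (length(at) == 0L) return(chars)
  cur <- match(chars[at], letters) - 1L
  shift <- sample.int(length(letters) - 1L, length(at), replace = TRUE)
  chars[at] <- letters[((cur + shift) %% length(letters)) + 1L]
  chars
}

#' Simulate a diploid genome
#'
#' Haplotype 1 is uniform random over ACGT; haplotype 2 is identical except
#' that each position is independently substituted with probability
#' `snp_rate` by a uniformly chosen different base.
#'
#' @param config A [kfm_sim_config()].
#' @return A list with `hap1`, `hap2` (strings) and the integer vector
#'   `snp_positions` (1-based).
#' @export
kfm_simulate_diploid <- function(config = kfm_sim_config()) {
  stopifnot(inherits(config, "kfm_sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  letters <- c("A", "C", "G", "T")
  L <- config$genome_length
  h1 <- sample(letters, L, replace = TRUE)
  snp <- which(runif(L) < config$snp_rate)
  h2 <- substitute_bases(h1, snp, letters)
  list(hap1 = paste(h1, collapse = ""), hap2 = paste(h2, collapse = ""),
       snp_positions = snp)
}

#' Simulate reads from a diploid genome
#'
#' Each read picks a haplotype uniformly, a start position uniform in
#' `[1, L - read_length + 1]`, and substitutes each base independently at
#' `error_rate` with a uniformly chosen different base. Reads are emitted
#' from the forward strand only; reverse complements are added at indexing
#' time (`kfm_build(..., add_rc = TRUE)`), which yields the same k-mer set
#' as strand-symmetric sampling.
#'
#' @param haplotypes Result of [kfm_simulate_diploid()] (or any list with
#'   `hap1`, `hap2`).
#' @param config A [kfm_sim_config()].
#' @return Character vector of `n_reads` reads.
#' @export
kfm_simulate_reads <- function(haplotypes, config = kfm_sim_config()) {
  stopifnot(inherits(config, "kfm_sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed + 1L)
  letters <- c("A", "C", "G", "T")
  rl <- config$read_length
  n <- config$n_reads
  L <- config$genome_length
  hap <- sample(c(haplotypes$hap1, haplotypes$hap2), n, replace = TRUE)
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  reads <- substring(hap, starts, starts + rl - 1L)
  if (config$error_rate > 0 && n > 0) {
    cells <- n * rl
    nerr <- rbinom(1L, cells, config$error_rate)
    if (nerr > 0) {
      at <- sample.int(cells, nerr) # uniform subset == Bernoulli given count
      rid <- (at - 1L) %/% rl + 1L
      pos <- (at - 1L) %% rl + 1L
      o <- order(rid, pos)
      rid <- rid[o]
      pos <- pos[o]
      runs <- rle(rid)
      ends <- cumsum(runs$lengths)
      begs <- ends - runs$lengths + 1L
      for (t in seq_along(runs$values)) {
        r <- runs$values[t]
        chars <- strsplit(reads[r], "", fixed = TRUE)[[1L]]
        reads[r] <- paste(substitute_bases(chars, pos[begs[t]:ends[t]],
                                           letters), collapse = "")
      }
    }
  }
  reads
}
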