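#' Edge words of a string
#'
#' Enumerates the k-symbol edge words a string contributes to the
#' final-completed graph: every k-substring, plus the k-1 sentinel-padded
#' words obtained by sliding a window over `v $^(k-1)` where `v` is the
#' (k-1)-suffix (the path that completes the read end down to the final
#' vertex). Each word is read as (in-letter, target vertex) =
#' (word[1], word[2..k]). Duplicates are kept; they are removed when words
#' are sorted.
#'
#' @param x A string over the alphabet; strings shorter than k-1 contribute
#'   nothing and are skipped with a warning.
#' @param k k-mer length (>= 3).
#' @param alphabet A [kfm_alphabet()].
#' @return Character vector of k-symbol words (possibly with trailing `$`).
#' @examples
#' kfm_edge_words("ACGT", 3)  # ACG CGT GT$ T$$
#' @export
kfm_edge_words <- function(x, k, alphabet = kfm_alphabet()) {
  stopifnot(length(x) == 1L)
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  m <- nchar(x)
  if (m < k - 1L) {
    warning("string shorter than k-1 contributes no edge words; skipped")
    return(character(0))
  }
  encode_string(x, alphabet) # validates symbols
  kmers <- if (m >= k) substring(x, 1:(m - k + 1L), k:m) else character(0)
  v <- substr(x, m - k + 2L, m)
  padded <- paste0(substring(v, 1:(k - 1L), k - 1L),
                   strrep("$", 1:(k - 1L)))
  c(kmers, padded)
}

#' Build a kFM-index from sorted, deduplicated edge words
#'
#' Emits one vertex record per distinct target (k-1)-mer, with one in-edge
#' bit per word, sets the group-end flag on the last vertex of each
#' (k-2)-prefix group, inserts the final vertex `$^(k-1)` if absent, and
#' builds the previous-position store in one linear pass.
#'
#' @param words Character vector of k-symbol edge words, sorted by
#'   (target, letter) with `$` before every letter, and unique.
#' @param k k-mer length.
#' @param alphabet A [kfm_alphabet()].
#' @param q,w Store strides, see [kfm_rebuild_store()].
#' @return A `kfm_index`.
#' @export
kfm_build_from_sorted_words <- function(words, k, alphabet = kfm_alphabet(),
                                        q = 32L, w = 64L) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  if (length(words) == 0L) {
    rec <- bitwShiftL(1L, alphabet$sigma) # lone final vertex, group end set
    return(new_kfm_index(rec, k, alphabet, q, w))
  }
  if (any(nchar(words) != k)) stop("edge words must have exactly k symbols")
  targets <- substr(words, 2L, k)
  inlet <- substr(words, 1L, 1L)
  ord <- order(targets, inlet, method = "radix")
  if (!identical(ord, seq_along(words)) || anyDuplicated(words))
    stop("contract violation: words must be sorted by (target, letter) and unique")
  codes <- match(inlet, alphabet$letters) - 1L
  if (anyNA(codes)) stop("edge word with in-letter outside the alphabet")
  # vertices: every edge target, every edge origin (origins with no in-edge
  # of their own, e.g. read starts, still need a record), plus $^(k-1)
  origins <- paste0(inlet, substr(targets, 1L, k - 2L))
  final <- strrep("$", k - 1L)
  vs <- sort(unique(c(targets, origins, final)), method = "radix")
  rec <- integer(length(vs))
  at <- match(targets, vs)
  for (t in seq_along(at))
    rec[at[t]] <- bitwOr(rec[at[t]], bitwShiftL(1L, codes[t]))
  n <- length(vs)
  prefix <- substr(vs, 1L, k - 2L)
  fend <- c(prefix[-1L] != prefix[-n], TRUE)
  rec <- bitwOr(unname(rec), bitwShiftL(as.integer(fend), alphabet$sigma))
  new_kfm_index(rec, k, alphabet, q, w)
}

#' Build a kFM-index from strings or reads
#'
#' The in-memory path encodes every edge word as one 64-bit integer keyed
#' (target, letter), sorts, deduplicates, and emits vertex records directly.
#' When the number of edge words exceeds `partition_size` the strings are
#' split into chunks, one sub-index is built per chunk, and the sub-indexes
#' are reduced by balanced pairwise merging; the result is identical (as a
#' k-mer set) to a single-pass build.
#'
#' @param x Character vector of strings over the alphabet. Strings shorter
#'   than k-1 are skipped with a warning.
#' @param k k-mer length (>= 3; vertices are (k-1)-mers). For DNA, k <= 26.
#' @param q,w Previous-position store strides (defaults 32 and 64).
#' @param alphabet A [kfm_alphabet()].
#' @param partition_size Maximum number of edge words per in-memory
#'   partition (default `Inf`: monolithic build).
#' @param prune_policy When to prune sentinel-padded vertices:
#'   `"final_only"` (default; once, at the end), `"every_merge"`, or
#'   `"never"`.
#' @param add_rc If `TRUE`, every string is indexed together with its
#'   reverse complement (requires a complement map in the alphabet).
#' @param verbose Log partition/merge progress.
#' @return A `kfm_index`.
#' @examples
#' ix <- kfm_build(c("ACG", "CGT", "CGA"), k = 3)
#' ix
#' @export
kfm_build <- function(x, k, q = 32L, w = 64L, alphabet = kfm_alphabet(),
                      partition_size = Inf,
                      prune_policy = c("final_only", "every_merge", "never"),
                      add_rc = FALSE, verbose = FALSE) {
  prune_policy <- match.arg(prune_policy)
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  if (partition_size < 1) stop("partition_size must be >= 1")
  x <- as.character(x)
  short <- nchar(x) < k - 1L
  if (any(short)) {
    warning(sum(short), " string(s) shorter than k-1 skipped")
    x <- x[!short]
  }
  if (add_rc) x <- kfm_add_reverse_complements(x, alphabet)
  lets <- letters_string(alphabet)
  counts <- if (length(x)) kfm_word_counts_cpp(x, k) else numeric(0)
  if (sum(counts) <= partition_size) {
    ix <- new_kfm_index(kfm_records_build_cpp(x, k, lets), k, alphabet, q, w)
    if (prune_policy != "never") ix <- kfm_prune(ix)
    return(ix)
  }
  # greedy chunking by word count; an oversized string forms its own chunk
  chunk <- integer(length(x))
  id <- 1L
  acc <- 0
  for (s in seq_along(x)) {
    if (acc > 0 && acc + counts[s] > partition_size) {
      id <- id + 1L
      acc <- 0
    }
    chunk[s] <- id
    acc <- acc + counts[s]
  }
  parts <- split(x, chunk)
  if (verbose)
    message("building ", length(parts), " partitions of <= ",
            format(partition_size, big.mark = ","), " edge words")
  ixs <- lapply(parts, function(p)
    new_kfm_index(kfm_records_build_cpp(p, k, lets), k, alphabet, q, w))
  round <- 0L
  while (length(ixs) > 1L) {
    round <- round + 1L
    merged <- vector("list", ceiling(length(ixs) / 2))
    for (t in seq_along(merged)) {
      a <- ixs[[2L * t - 1L]]
      if (2L * t <= length(ixs)) {
        m <- kfm_merge(a, ixs[[2L * t]])
        if (prune_policy == "every_merge") m <- kfm_prune(m)
        merged[[t]] <- m
      } else {
        merged[[t]] <- a
      }
    }
    if (verbose)
      message("merge round ", round, ": ", length(ixs), " -> ",
              length(merged), " indexes")
    ixs <- merged
  }
  ix <- ixs[[1L]]
  if (prune_policy != "never") ix <- kfm_prune(ix)
  ix
}
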