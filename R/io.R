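#' Read sequences from FASTA/FASTQ with quality-based splitting
#'
#' FASTQ reads are split into fragments at bases with Phred quality below
#' `quality_threshold` (default 30) and at symbols outside the alphabet
#' (e.g. N); the low-quality/foreign bases themselves are dropped. FASTA
#' input bypasses quality filtering but is still split at foreign symbols.
#' Fragments shorter than k-1 are discarded downstream by [kfm_build()].
#'
#' @param path FASTA or FASTQ file (format detected from the first record
#'   unless given).
#' @param quality_threshold Minimum Phred score to keep a base (0 disables
#'   filtering).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @param alphabet A [kfm_alphabet()].
#' @return Character vector of fragments.
#' @export
kfm_read_sequences <- function(path, quality_threshold = 30,
                               format = c("auto", "fasta", "fastq"),
                               alphabet = kfm_alphabet()) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) return(character(0))
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  ok <- paste0(alphabet$letters, collapse = "")
  bad_re <- paste0("[^", ok, "]+")
  if (format == "fasta") {
    seqs <- as.character(Biostrings::readBStringSet(path))
    frags <- unlist(strsplit(toupper(seqs), bad_re), use.names = FALSE)
    return(frags[nzchar(frags)])
  }
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- as.character(qs)
  quals <- as(Biostrings::quality(qs), "IntegerList")
  out <- vector("list", length(seqs))
  for (r in seq_along(seqs)) {
    ch <- strsplit(seqs[[r]], "", fixed = TRUE)[[1L]]
    good <- ch %in% alphabet$letters & quals[[r]] >= quality_threshold
    if (all(good)) {
      out[[r]] <- seqs[[r]]
    } else if (any(good)) {
      runs <- rle(good)
      ends <- cumsum(runs$lengths)
      begs <- ends - runs$lengths + 1L
      keep <- which(runs$values)
      out[[r]] <- substring(seqs[[r]], begs[keep], ends[keep])
    } else {
      out[[r]] <- character(0)
    }
  }
  unlist(out, use.names = FALSE)
}

#' Reverse-complement augmentation
#'
#' Yields each fragment followed by its reverse complement, making the
#' indexed k-mer set closed under reverse complementation.
#'
#' @param x Character vector of sequences.
#' @param alphabet A [kfm_alphabet()] with a complement map.
#' @return Character vector of length `2 * length(x)`, interleaved.
#' @examples
#' kfm_add_reverse_complements("AAC")  # AAC GTT
#' @export
kfm_add_reverse_complements <- function(x, alphabet = kfm_alphabet()) {
  if (is.null(alphabet$complements))
    stop("alphabet has no complement map; reverse complements undefined")
  rc <- kfm_revcomp_cpp(x, letters_string(alphabet),
                        paste(alphabet$complements, collapse = ""))
  as.vector(rbind(x, rc))
}

#' Serialize a kFM-index ("KFMI" format, version 1)
#'
#' The on-disk layout mirrors the in-memory accounting: a small header
#' (magic, version, alphabet, k, n, q, w), then the vertex records packed
#' at sigma+1 bits each into 64-bit words (12 vertices per word for DNA),
#' then the store's low values at ceil(log2 q) bits, the single-bit U
#' increments, and one full 64-bit word per U checkpoint. Round trips are
#' bit-exact.
#'
#' @param index A `kfm_index`.
#' @param path Output file.
#' @return Invisibly, the number of bytes written.
#' @export
kfm_serialize <- function(index, path) {
  stopifnot(inherits(index, "kfm_index"))
  bytes <- kfm_serialize_cpp(index, letters_string(index$alphabet))
  writeBin(as.vector(bytes), path, useBytes = TRUE)
  invisible(length(bytes))
}

#' Deserialize a kFM-index
#'
#' @param path A file written by [kfm_serialize()].
#' @return A `kfm_index`.
#' @export
kfm_deserialize <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  parts <- kfm_deserialize_cpp(bytes)
  letters <- strsplit(parts$letters, "", fixed = TRUE)[[1L]]
  alphabet <- kfm_alphabet(letters)
  structure(
    list(alphabet = alphabet, sigma = alphabet$sigma, k = parts$k,
         n = length(parts$records), records = parts$records,
         store = parts$store, tau = parts$tau),
    class = "kfm_index"
  )
}

#' Analytic per-vertex memory accounting
#'
#' The core (in-edge flags + group-end flag) costs exactly sigma+1 bits per
#' vertex; packing whole vertices into machine words leaves
#' `word_size %% (sigma+1)` unused bits per word (0.333 bit/vertex for DNA
#' in 64-bit words, i.e. an effective 64/12 = 5.333 bits). The sparse
#' previous-position store adds about `sigma * (log2(q) + 2) / q` bits per
#' vertex: ceil(log2 q) low bits and one increment bit per stored value,
#' plus one full word per w stored values for the U checkpoints. For DNA at
#' q = 16/32/64 this is 1.5 / 0.875 / 0.5 bit per vertex, and the total at
#' q = 32 is about 6.2 bits per vertex.
#'
#' @param n Vertex count (only used for the refined checkpoint term
#'   `sigma*log2(n/q)/(q*w)`; may be `NULL`).
#' @param sigma Alphabet size (default 4, DNA).
#' @param q Store stride (default 32).
#' @param word_size Machine word size in bits (default 64).
#' @return A list of class `kfm_memory_estimate` with per-vertex bit costs.
#' @examples
#' kfm_memory_estimate(q = 32)  # store 0.875, total ~6.2 bit/vertex
#' @export
kfm_memory_estimate <- function(n = NULL, sigma = 4, q = 32, word_size = 64) {
  stopifnot(sigma >= 1, q >= 1, word_size >= sigma + 1)
  per_word <- word_size %/% (sigma + 1)
  core <- sigma + 1
  packing <- word_size / per_word - core
  store <- sigma * (log2(q) + 2) / q
  est <- list(
    bits_core_per_vertex = core,
    packing_overhead_per_vertex = packing,
    bits_store_per_vertex = store,
    bits_total_per_vertex = core + store,
    bits_effective_per_vertex = word_size / per_word + store,
    bits_store_checkpoint_refined = if (is.null(n)) NA_real_ else
      sigma * (log2(q) + 1 + log2(n / q) / word_size) / q,
    n = n, sigma = sigma, q = q, word_size = word_size
  )
  class(est) <- "kfm_memory_estimate"
  est
}

#' @export
print.kfm_memory_estimate <- function(x, ...) {
  cat("kFM-index memory estimate (sigma = ", x$sigma, ", q = ", x$q,
      ", word = ", x$word_size, " bit)\n", sep = "")
  cat(sprintf("  core (eta + f)     : %.3f bit/vertex (+%.3f packing)\n",
              x$bits_core_per_vertex, x$packing_overhead_per_vertex))
  cat(sprintf("  rho store          : %.3f bit/vertex\n",
              x$bits_store_per_vertex))
  cat(sprintf("  total (packed)     : %.3f bit/vertex\n",
              x$bits_effective_per_vertex))
  invisible(x)
}
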