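# The kfm_index object: a list of plain R vectors so that compiled code can
# view it without copying.
#   records: one integer per vertex; bits 0..sigma-1 = in-edge flags by
#            letter code, bit sigma = vertex-group end flag f_i
#   store:   sparse previous-position table (q, w, zeta, u, delta,
#            checkpoints) with kappa(a*zeta + r) = rho(a, i_r) = u + q*U
#   tau:     per-letter count of vertex groups with an a in-edge

new_kfm_index <- function(records, k, alphabet, q = 32L, w = 64L) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  st <- kfm_store_build_cpp(records, alphabet$sigma, as.integer(q), as.integer(w))
  structure(
    list(alphabet = alphabet, sigma = alphabet$sigma, k = k,
         n = length(records), records = records,
         store = st[c("q", "w", "zeta", "u", "delta", "checkpoints")],
         tau = st$tau),
    class = "kfm_index"
  )
}

#' Rebuild the sparse previous-position store of an index
#'
#' The store is an accelerator, not part of the graph semantics: rebuilding
#' it at a different stride `q` changes memory/speed trade-offs only. Stored
#' positions are `i_r = min(r*q, n)`; every `w`-th reconstructed high part
#' `U` is checkpointed in full.
#'
#' @param index A `kfm_index`.
#' @param q Stride between stored rho positions (default 32, the
#'   recommended balance; the store adds about `sigma*(log2(q)+2)/q` bits
#'   per vertex).
#' @param w Checkpoint stride (default 64, one full word per 64 entries).
#' @return The index with a fresh store.
#' @export
kfm_rebuild_store <- function(index, q = 32L, w = 64L) {
  stopifnot(inherits(index, "kfm_index"))
  new_kfm_index(index$records, index$k, index$alphabet, q, w)
}

#' Number of edges stored in a kFM-index
#'
#' Counts set in-edge flags, i.e. distinct k-symbol edge words including the
#' sentinel-padded ones.
#' @param index A `kfm_index`.
#' @return Edge count (double).
#' @export
kfm_n_edges <- function(index) {
  stopifnot(inherits(index, "kfm_index"))
  sum(vapply(seq_len(index$sigma) - 1L, function(a)
    sum(bitwAnd(index$records, bitwShiftL(1L, a)) != 0L), 0))
}

#' @export
print.kfm_index <- function(x, ...) {
  cat("kFM-index: k = ", x$k, " (", x$k - 1L, "-mer vertices), n = ",
      format(x$n, big.mark = ","), " vertices, ",
      format(kfm_n_edges(x), big.mark = ","), " edges\n", sep = "")
  cat("  alphabet: ", paste(x$alphabet$letters, collapse = ""),
      "  store: q = ", x$store$q, ", w = ", x$store$w, "\n", sep = "")
  invisible(x)
}

#' Vertex record accessor
#'
#' Returns the in-edge letter set E_i and group-end flag f_i of vertex `i`.
#'
#' @param index A `kfm_index`.
#' @param i Vertex index, 0-based (all vertex indices in this package are
#'   0-based, matching the half-open interval convention).
#' @return A list with `letters` (in-edge letters), `mask` (the same as a
#'   bit mask over letter codes) and `group_end` (logical).
#' @export
kfm_vertex_record <- function(index, i) {
  stopifnot(inherits(index, "kfm_index"))
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 0L || i >= index$n)
    stop("vertex index out of range [0, n)")
  r <- index$records[i + 1L]
  mask <- bitwAnd(r, bitwShiftL(1L, index$sigma) - 1L)
  codes <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(index$sigma) - 1L)) != 0L)
  list(letters = index$alphabet$letters[codes], mask = mask,
       group_end = bitwAnd(r, bitwShiftL(1L, index$sigma)) != 0L)
}

#' Per-letter vertex-group counts tau(a)
#'
#' `tau(a)` is the number of vertex groups (maximal runs of vertices sharing
#' a (k-2)-prefix) that contain an `a` in-edge; it equals `c(a, n)` and is
#' cached at construction.
#'
#' @param index A `kfm_index`.
#' @param a Letter (character) or 0-based letter code; `NULL` returns the
#'   whole named vector.
#' @return Integer count(s).
#' @export
kfm_letter_group_count <- function(index, a = NULL) {
  stopifnot(inherits(index, "kfm_index"))
  tau <- structure(index$tau, names = index$alphabet$letters)
  if (is.null(a)) return(tau)
  tau[letter_code(index, a) + 1L]
}

# letter -> 0-based code, accepting characters or codes
letter_code <- function(index, a) {
  if (is.character(a)) {
    code <- match(a, index$alphabet$letters) - 1L
    if (anyNA(code)) stop("letter not in the alphabet: ", a[which(is.na(code))[1L]])
    code
  } else {
    code <- as.integer(a)
    if (anyNA(code) || any(code < 0L | code >= index$sigma))
      stop("letter code out of range [0, sigma)")
    code
  }
}
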