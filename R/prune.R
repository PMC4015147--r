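#' Prune superfluous final-completing vertices
#'
#' The construction adds, for every read-end (k-1)-suffix, a full path of
#' sentinel-padded vertices down to the final vertex `$^(k-1)` so that every
#' vertex can be reached by backtracking. Most of these are redundant once
#' the same (k-1)-mer occurs internally elsewhere. Pruning backtracks
#' depth-first from the final vertex through the sentinel tree (at most k-2
#' steps) and applies two rules: an in-edge `a` of a single-`$` vertex `u$`
#' is removable when another vertex `u.b` of the same group has an `a`
#' in-edge; and a sentinel-padded vertex with no remaining in-edges is
#' removed together with the in-edge of its `$`-extension. Marks are
#' collected first and applied in one compaction pass (rho depends on group
#' composition), after which the store is rebuilt. The set of
#' sentinel-free k-mers is unchanged.
#'
#' @param index A `kfm_index`.
#' @return The pruned `kfm_index`, with attributes `removed_vertices` and
#'   `removed_edges`.
#' @examples
#' ix <- kfm_build(c("ACG", "CGT"), k = 3, prune_policy = "never")
#' ix$n                 # 6 vertices, G$ still present
#' kfm_prune(ix)$n      # 5 after pruning
#' @export
kfm_prune <- function(index) {
  stopifnot(inherits(index, "kfm_index"))
  res <- kfm_prune_cpp(index)
  out <- new_kfm_index(res$records, index$k, index$alphabet,
                       index$store$q, index$store$w)
  attr(out, "removed_vertices") <- res$removed_vertices
  attr(out, "removed_edges") <- res$removed_edges
  out
}

#' Would pruning remove this sentinel-padded vertex?
#'
#' Runs the depth-first pruning marks and reports whether vertex `i` ends up
#' with no in-edges (after recursive child processing and removal of
#' group-redundant in-edges) and would therefore be removed. Only defined
#' for final-completing vertices (strings with >= 1 trailing `$`); the
#' final vertex itself (position 0) is the root of the sentinel tree and is
#' never removable.
#'
#' @param index A `kfm_index`.
#' @param i Vertex position in `[0, n)`.
#' @return Logical.
#' @export
kfm_vertex_removable <- function(index, i) {
  stopifnot(inherits(index, "kfm_index"))
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 0L || i >= index$n)
    stop("vertex index out of range [0, n)")
  if (!endsWith(kfm_vertex_string(index, i), "$"))
    stop("contract violation: vertex ", i, " is not final-completing")
  if (i == 0L) return(FALSE)
  res <- kfm_prune_cpp(index)
  res$vertex_removed[i + 1L]
}
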