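#' Vertex degree classification
#'
#' Computes in- and out-degrees in one synchronized sweep (no strings are
#' materialized: `rho(a, .)` is constant within a vertex group, so a running
#' per-letter origin counter attributes every edge to its origin vertex).
#' A vertex is *simple* when both degrees are one; all others are the
#' branching/ending vertices between which uniquely determined paths run.
#'
#' @param index A `kfm_index`.
#' @return A list with integer vectors `in_degree` and `out_degree` (length
#'   n) and `non_simple`, the 0-based positions with a degree different
#'   from one.
#' @export
kfm_classify_vertices <- function(index) {
  stopifnot(inherits(index, "kfm_index"))
  deg <- kfm_classify_cpp(index)
  deg$non_simple <- which(deg$in_degree != 1L | deg$out_degree != 1L) - 1L
  deg
}

#' Extract uniquely determined paths (unitigs)
#'
#' Iterates over the non-simple vertices and each of their in-edges,
#' backtracking through simple vertices until another non-simple vertex is
#' hit. The terminal vertex's string is materialized once; the remaining
#' letters accrue during backtracking and the sequence is reversed to read
#' forward. Paths consisting solely of sentinel-padded vertices are
#' dropped and trailing `$` are trimmed from the emitted sequences.
#' Isolated all-simple cycles (which the sentinel-completed graph can only
#' contain for circular input) are emitted once each with `circular = TRUE`.
#'
#' @param index A `kfm_index`.
#' @param classification Optional result of [kfm_classify_vertices()].
#' @return A data.frame with columns `sequence`, `start_vertex`,
#'   `end_vertex`, `n_vertices` and `circular`.
#' @examples
#' ix <- kfm_build(c("ACG", "CGT", "CGA"), k = 3)
#' sort(kfm_extract_paths(ix)$sequence)  # ACG CGA CGT
#' @export
kfm_extract_paths <- function(index, classification = NULL) {
  stopifnot(inherits(index, "kfm_index"))
  if (is.null(classification)) classification <- kfm_classify_vertices(index)
  res <- kfm_paths_cpp(index, classification$in_degree,
                       classification$out_degree,
                       letters_string(index$alphabet))
  data.frame(sequence = res$sequence, start_vertex = res$start_vertex,
             end_vertex = res$end_vertex, n_vertices = res$n_vertices,
             circular = res$circular == 1L, stringsAsFactors = FALSE)
}

#' Upper estimate of the number of uniquely determined paths
#'
#' Sums the in-degrees of all non-simple vertices; this counts every path
#' anchor, including paths that consist solely of sentinel-padded vertices
#' and are excluded from [kfm_extract_paths()] output.
#'
#' @param index A `kfm_index`.
#' @param classification Optional result of [kfm_classify_vertices()].
#' @return Numeric count, `>=` the number of emitted non-circular paths.
#' @export
kfm_path_estimate <- function(index, classification = NULL) {
  if (is.null(classification)) classification <- kfm_classify_vertices(index)
  sum(as.numeric(classification$in_degree[classification$non_simple + 1L]))
}

#' Write unitigs as FASTA
#'
#' @param paths Result of [kfm_extract_paths()].
#' @param path Output file.
#' @return Invisibly, the number of records written.
#' @export
kfm_write_unitigs <- function(paths, path) {
  hdr <- sprintf(">path_%d len=%d start=%d end=%d%s",
                 seq_len(nrow(paths)), nchar(paths$sequence),
                 paths$start_vertex, paths$end_vertex,
                 ifelse(paths$circular, " circular", ""))
  writeLines(as.vector(rbind(hdr, paths$sequence)), path)
  invisible(nrow(paths))
}
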