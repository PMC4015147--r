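#' Plan the merge of two kFM-indexes
#'
#' Computes the three bit arrays that drive a merge (3 n_A + 2 n_B bits in
#' total): for every A vertex its position in the preliminary merged list is
#' `i + alpha_B(v_i^A)`; A vertices also present in B are flagged duplicate
#' (their B twin immediately follows); and for every (k-2)-prefix vertex
#' group present in both indexes, all but the last merged position are
#' flagged for group-end removal. Positions are found by a joint recursion
#' that extends prefixes one letter at a time on both indexes, handling the
#' trailing-`$` (sentinel-padded) vertex of each prefix along the way.
#'
#' @param A,B Two `kfm_index` objects with identical k and alphabet.
#' @return A list of class `kfm_merge_plan` with logical vectors
#'   `source_flags` (length n_A+n_B, `TRUE` = position taken from A),
#'   `duplicate_flags` (length n_A) and `groupend_clear_flags` (length
#'   n_A+n_B), plus the number of rho calls spent.
#' @export
kfm_merge_plan <- function(A, B) {
  stopifnot(inherits(A, "kfm_index"), inherits(B, "kfm_index"))
  if (A$k != B$k) stop("indexes have different k")
  if (!identical(A$alphabet$letters, B$alphabet$letters))
    stop("indexes have different alphabets")
  structure(kfm_merge_plan_cpp(A, B), class = "kfm_merge_plan")
}

#' Apply a merge plan
#'
#' Single sequential pass emitting merged vertex records: duplicate (A, B)
#' pairs are combined by OR-ing their in-edge sets, flagged group-end flags
#' are cleared, and the previous-position store is rebuilt.
#'
#' @param A,B The indexes the plan was computed for.
#' @param plan A `kfm_merge_plan`.
#' @return A merged `kfm_index` with `n = n_A + n_B - #duplicates`.
#' @export
kfm_merge_apply <- function(A, B, plan) {
  stopifnot(inherits(plan, "kfm_merge_plan"))
  rec <- kfm_merge_apply_cpp(A$records, B$records, A$sigma,
                             plan$source_flags, plan$duplicate_flags,
                             plan$groupend_clear_flags)
  new_kfm_index(rec, A$k, A$alphabet, A$store$q, A$store$w)
}

#' Merge two kFM-indexes
#'
#' The merged index represents the union of the two k-mer sets and is
#' identical to an index built directly from the combined edge words. The
#' smaller index takes the role of A (only n_A lookups are needed), which
#' makes the operation commutative up to identical output.
#'
#' @param A,B Two `kfm_index` objects with identical k and alphabet.
#' @return A `kfm_index`.
#' @examples
#' a <- kfm_build("ACGT", k = 3, prune_policy = "never")
#' b <- kfm_build(c("ACG", "CGT", "CGA"), k = 3, prune_policy = "never")
#' kfm_merge(a, b)
#' @export
kfm_merge <- function(A, B) {
  stopifnot(inherits(A, "kfm_index"), inherits(B, "kfm_index"))
  if (A$n > B$n) {
    tmp <- A
    A <- B
    B <- tmp
  }
  kfm_merge_apply(A, B, kfm_merge_plan(A, B))
}
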