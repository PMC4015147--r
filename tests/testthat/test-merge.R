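# Merging two indexes must equal a direct build over the combined edge
# words; the plan's bit arrays have the exact documented sizes and the
# recursion respects the rho-call budget.

test_that("merge plan: duplicates, trivial cases, exact array sizes", {
  A <- kfm_build(TOY1, k = 3, prune_policy = "never")
  B <- kfm_build(TOY2, k = 3, prune_policy = "never")
  plan <- kfm_merge_plan(A, B)
  expect_length(plan$source_flags, A$n + B$n)
  expect_length(plan$duplicate_flags, A$n)
  expect_length(plan$groupend_clear_flags, A$n + B$n)
  # duplicates = A vertices whose strings occur in B (here: all of A,
  # pruned TOY1's 5 vertices; unpruned adds G$ which B also has)
  expect_identical(which(plan$duplicate_flags) - 1L,
                   which(all_vertex_strings(A) %in% all_vertex_strings(B)) - 1L)
  # plan(X, X): every vertex duplicated, merge is idempotent
  planXX <- kfm_merge_plan(B, B)
  expect_true(all(planXX$duplicate_flags))
  expect_identical(kfm_merge(B, B)$records, B$records)
  # trivial index: single duplicate at vertex 0
  triv <- kfm_build(character(0), k = 3)
  planT <- kfm_merge_plan(triv, B)
  expect_identical(which(planT$duplicate_flags), 1L)
  expect_identical(kfm_merge(triv, B)$records, B$records)
  expect_error(kfm_merge(A, kfm_build("ACGT", k = 4)), "different k")
})

test_that("merge equals the union build, is commutative and associative", {
  A <- kfm_build(TOY1, k = 3, prune_policy = "never")
  B <- kfm_build(TOY2, k = 3, prune_policy = "never")
  U <- kfm_build(c(TOY1, TOY2), k = 3, prune_policy = "never")
  expect_identical(kfm_merge(A, B)$records, U$records)
  expect_identical(kfm_merge(B, A)$records, U$records)

  set.seed(301)
  k <- 7L
  sets <- list(rand_strings(5, 25), rand_strings(7, 30), rand_strings(3, 40))
  ixs <- lapply(sets, kfm_build, k = k, prune_policy = "never")
  left <- kfm_merge(kfm_merge(ixs[[1]], ixs[[2]]), ixs[[3]])
  right <- kfm_merge(ixs[[1]], kfm_merge(ixs[[2]], ixs[[3]]))
  expect_identical(left$records, right$records)
  expect_identical(left$records,
                   kfm_build(unlist(sets), k = k,
                             prune_policy = "never")$records)
  # k-mer set of the merge is the union of the k-mer sets
  km <- naive_kmers(unlist(sets), k)
  expect_true(all(kfm_query(left, km)))
  expect_false(any(kfm_query(left, setdiff(rand_strings(150, k), km))))
  # pruned merge equals pruned union build
  expect_identical(kfm_prune(left)$records,
                   kfm_build(unlist(sets), k = k)$records)
})

test_that("disjoint-prefix inputs share only the final vertex", {
  # AA...-prefixed vs TT...-prefixed strings: no common (k-1)-mers except $$
  set.seed(302)
  sa <- paste0("AAAA", rand_strings(4, 20))
  sb <- paste0("TTTT", rand_strings(4, 20))
  A <- kfm_build(sa, k = 4, prune_policy = "never")
  B <- kfm_build(sb, k = 4, prune_policy = "never")
  shared <- intersect(all_vertex_strings(A), all_vertex_strings(B))
  M <- kfm_merge(A, B)
  expect_identical(M$n, A$n + B$n - length(shared))
})

test_that("merge work respects the O((nA+nB) k sigma) rho-call budget", {
  set.seed(303)
  A <- kfm_build(rand_strings(6, 40), k = 6, prune_policy = "never")
  B <- kfm_build(rand_strings(9, 45), k = 6, prune_policy = "never")
  plan <- kfm_merge_plan(A, B)
  expect_lte(plan$rho_calls, 4 * 4 * 6 * (A$n + B$n))
})

test_that("exactly one group-end flag survives per merged group", {
  set.seed(304)
  for (t in 1:5) {
    A <- kfm_build(rand_strings(4, 30), k = 5, prune_policy = "never")
    B <- kfm_build(rand_strings(4, 30), k = 5, prune_policy = "never")
    M <- kfm_merge(A, B)
    vs <- all_vertex_strings(M)
    fend <- vapply(0:(M$n - 1L), function(i)
      kfm_vertex_record(M, i)$group_end, NA)
    grp <- substr(vs, 1L, M$k - 2L)
    expect_identical(unname(fend),
                     c(grp[-1L] != grp[-M$n], TRUE))
  }
})
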