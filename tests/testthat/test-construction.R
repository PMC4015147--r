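# Edge-word enumeration, sorted-word construction, the previous-position
# store, and the partitioned build.

test_that("edge_words_from_string enumerates k-mers plus sentinel completions", {
  expect_setequal(kfm_edge_words("ACGT", 3), c("ACG", "CGT", "GT$", "T$$"))
  expect_setequal(kfm_edge_words("ACG", 3), c("ACG", "CG$", "G$$"))
  expect_setequal(kfm_edge_words("AC", 3), c("AC$", "C$$"))
  expect_warning(out <- kfm_edge_words("A", 3), "skipped")
  expect_identical(out, character(0))
  expect_error(kfm_edge_words("ACNG", 3), "not in the declared alphabet")
})

test_that("build_from_sorted_words emits the hand-derived tables", {
  toy1w <- sort(kfm_edge_words("ACGT", 3), method = "radix")
  # sort by (target, letter): radix order on whole word is (letter, target);
  # reorder properly
  ord <- order(substr(toy1w, 2, 3), substr(toy1w, 1, 1), method = "radix")
  ix <- kfm_build_from_sorted_words(toy1w[ord], 3)
  expect_identical(ix$n, 5L)
  expect_identical(all_vertex_strings(ix), c("$$", "AC", "CG", "GT", "T$"))
  got <- lapply(0:4, function(i) kfm_vertex_record(ix, i))
  expect_identical(lapply(got, `[[`, "letters"),
                   list("T", character(0), "A", "C", "G"))
  expect_true(all(vapply(got, `[[`, NA, "group_end")))

  words <- unique(unlist(lapply(TOY2, kfm_edge_words, k = 3)))
  ord <- order(substr(words, 2, 3), substr(words, 1, 1), method = "radix")
  ix2 <- kfm_build_from_sorted_words(words[ord], 3)
  expect_identical(ix2$records,
                   kfm_build(TOY2, k = 3, prune_policy = "never")$records)

  expect_identical(kfm_build_from_sorted_words(character(0), 3)$n, 1L)
  expect_error(kfm_build_from_sorted_words(rev(words[ord]), 3),
               "contract violation")
  expect_error(kfm_build_from_sorted_words(rep(words[ord][1], 2), 3),
               "contract violation")
})

test_that("the kappa store holds rho at stored positions, q >= n degenerates", {
  ix <- kfm_build(TOY2, k = 3) # pruned, n = 7
  i4 <- kfm_rebuild_store(ix, q = 4L)
  expect_identical(i4$store$zeta, 2L) # stored positions 0, 4, 7
  # kappa for letter A (codes block a=0): rho(A, 0), rho(A, 4), rho(A, 7)
  expect_identical(vapply(0:2, function(r) kappa_r(i4, r), 0), c(1, 3, 3))
  # round trip at stored positions for every letter
  for (a in 0:3)
    for (r in 0:2)
      expect_identical(as.double(kappa_r(i4, a * 2L + r)),
                       as.double(kfm_prev_position(ix, a, min(r * 4L, 7L))))
  big <- kfm_rebuild_store(ix, q = 100L)
  expect_identical(big$store$zeta, 1L) # endpoints {0, n} only
  expect_identical(kfm_prev_position(big, 0:3, rep(5L, 4)),
                   kfm_prev_position(ix, 0:3, rep(5L, 4)))
})

test_that("build is order-insensitive and partitioning does not change it", {
  set.seed(201)
  strings <- rand_strings(12, 30)
  k <- 6L
  ref <- kfm_build(strings, k = k)
  perm <- kfm_build(sample(strings), k = k)
  f1 <- tempfile(); f2 <- tempfile()
  kfm_serialize(ref, f1); kfm_serialize(perm, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  counts <- sum(kfmindex:::kfm_word_counts_cpp(strings, k))
  for (psize in c(counts %/% 8, counts %/% 3, 40)) {
    part <- kfm_build(strings, k = k, partition_size = psize)
    expect_identical(part$records, ref$records)
  }
  # with every_merge pruning as well
  part2 <- kfm_build(strings, k = k, partition_size = 40,
                     prune_policy = "every_merge")
  expect_identical(part2$records, ref$records)
  # unpruned partitioned == unpruned monolithic
  expect_identical(kfm_build(strings, k = k, partition_size = 40,
                             prune_policy = "never")$records,
                   kfm_build(strings, k = k, prune_policy = "never")$records)
})

test_that("build equals the naive k-mer set for random inputs", {
  set.seed(202)
  strings <- rand_strings(20, 50)
  ix <- kfm_build(strings, k = 23)
  km <- naive_kmers(strings, 23)
  expect_identical(kfm_n_edges(kfm_build(strings, k = 23,
                                         prune_policy = "never")) >=
                     length(km), TRUE)
  expect_true(all(kfm_query(ix, km)))
  expect_false(any(kfm_query(ix, setdiff(rand_strings(100, 23), km))))
})

test_that("degenerate and invalid inputs are handled", {
  expect_warning(ix <- kfm_build(c("ACGTAC", "AC"), k = 5), "skipped")
  expect_identical(kfm_build(character(0), k = 3)$n, 1L)
  expect_error(kfm_build("ACGNACGT", k = 3), "not in the declared alphabet")
  expect_error(kfm_build("ACGT", k = 2), "at least 3")
  expect_error(suppressWarnings(kfm_build("ACGTACGTACGTACGTACGTACGTACGTACGT", k = 31)), "k too large")
  # sentinel vertices without in-edges never survive pruning
  set.seed(203)
  ix <- kfm_build(rand_strings(5, 40), k = 8)
  vs <- all_vertex_strings(ix)
  sent <- which(grepl("$", vs, fixed = TRUE)) - 1L
  for (i in setdiff(sent, 0L))
    expect_gt(length(kfm_vertex_record(ix, i)$letters), 0L)
})
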