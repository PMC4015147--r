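# Core queries: rho, gamma, prefix intervals, membership, rho-inverse and
# vertex-string reconstruction, against the string-level oracle and the
# hand-derived TOY tables (TOY2 values were computed with the order-definition oracle
# on the explicit sorted vertex list and frozen below).

test_that("unpruned construction reproduces the explicit oracle table", {
  set.seed(101)
  cases <- list(list(TOY2, 3L), list(TOY1, 3L),
                list(rand_strings(6, 30), 5L),
                list(rand_strings(3, 15), 4L))
  for (cs in cases) {
    tab <- oracle_table(cs[[1]], cs[[2]])
    ix <- kfm_build(cs[[1]], k = cs[[2]], prune_policy = "never")
    expect_identical(ix$n, tab$n)
    expect_identical(all_vertex_strings(ix), tab$verts)
    for (i in seq_len(ix$n)) {
      r <- kfm_vertex_record(ix, i - 1L)
      expect_identical(r$letters, tab$edges[[i]])
      expect_identical(r$group_end, tab$fend[i])
    }
  }
})

test_that("rho matches the order-definition oracle everywhere, and TOY2 frozen values", {
  set.seed(102)
  for (strings in list(TOY2, rand_strings(5, 25))) {
    tab <- oracle_table(strings, 3L)
    ix <- kfm_build(strings, k = 3, prune_policy = "never")
    for (a in DNA)
      for (i in 0:ix$n)
        expect_identical(kfm_prev_position(ix, a, i), oracle_rho(tab, a, i))
  }
  # pruned TOY2 fixture (7 vertices $$ A$ AC CG GA GT T$)
  ix <- toy2_index()
  expect_identical(kfm_prev_position(ix, c("A", "A", "C", "G", "T"),
                                     c(0L, 3L, 4L, 6L, 0L)),
                   c(1L, 2L, 3L, 5L, 6L))
  expect_identical(kfm_prev_position(ix, "T", 7L), 7L) # rho(sigma-1, n) = n
  expect_identical(kfm_prev_position(ix, "A", 0L), 1L) # rho(0, 0) = 1, n > 1
  expect_error(kfm_prev_position(ix, "A", 8L), "out of range")
  expect_error(kfm_prev_position(ix, "N", 0L), "not in the alphabet")
})

test_that("tau counts vertex groups with an in-edge", {
  ix <- toy2_index()
  expect_identical(unname(kfm_letter_group_count(ix, "A")), 2L)
  expect_identical(unname(kfm_letter_group_count(ix, "C")), 1L)
  # tau(a) = c(a, n) = rho(a, n) - rho(a, 0)
  expect_identical(unname(kfm_letter_group_count(ix)),
                   vapply(0:3, function(a) kfm_prev_position(ix, a, ix$n) -
                                           kfm_prev_position(ix, a, 0L), 0L))
  triv <- kfm_build(character(0), k = 3)
  expect_identical(triv$n, 1L)
  expect_identical(unname(kfm_letter_group_count(triv)), rep(0L, 4))
})

test_that("gamma folds rho and matches frozen TOY2 values", {
  ix <- toy2_index()
  expect_identical(kfm_gamma(ix, "", 5L), 5L)
  expect_identical(kfm_gamma(ix, "CG", 0L), 3L)
  expect_identical(kfm_gamma(ix, "TC", 0L), 7L)
  expect_identical(kfm_gamma(ix, "TC", ix$n), 7L)
})

test_that("prefix_interval equals the brute-force prefix filter (exhaustive)", {
  set.seed(103)
  cases <- list(list(TOY2, 3L), list(rand_strings(8, 40), 5L),
                list(rand_strings(2, 85), 6L))
  for (cs in cases) {
    k <- cs[[2]]
    ix <- kfm_build(cs[[1]], k = k) # pruned; filter its own strings
    expect_lte(ix$n, 200L)
    vs <- all_vertex_strings(ix)
    prefixes <- unique(c(unlist(lapply(gsub("\\$", "", vs), function(v)
      substring(v, 1, 0:nchar(v)))),
      rand_strings(25, k - 1L), rand_strings(25, 2L)))
    prefixes <- prefixes[nchar(prefixes) <= k - 1L]
    for (x in prefixes) {
      iv <- kfm_prefix_interval(ix, x)
      hits <- which(startsWith(vs, x)) - 1L
      if (length(hits) == 0L) {
        expect_identical(iv$alpha, iv$beta)
      } else {
        expect_identical(hits, seq.int(iv$alpha, iv$beta - 1L))
      }
    }
  }
  expect_identical(unlist(kfm_prefix_interval(toy2_index(), ""),
                          use.names = FALSE), c(0L, 7L))
  expect_error(kfm_prefix_interval(toy2_index(), "ACG"), "longer than k-1")
})

test_that("contains_path agrees with the naive k-mer set, incl. negatives", {
  ix <- toy2_index()
  expect_true(kfm_contains(ix, "ACGA")$found)
  expect_true(kfm_contains(ix, "ACGT")$found)
  expect_false(kfm_contains(ix, "CGTC")$found)
  expect_false(kfm_contains(ix, "ACGTT")$found)
  expect_error(kfm_contains(ix, "AC"), "shorter than k")

  set.seed(104)
  strings <- rand_strings(40, 60)
  k <- 9L
  ix <- kfm_build(strings, k = k)
  km <- naive_kmers(strings, k)
  expect_true(all(kfm_query(ix, km)))
  neg <- setdiff(rand_strings(300, k), km)
  expect_false(any(kfm_query(ix, neg)))
  # longer paths: true windows and corrupted ones
  for (t in 1:30) {
    s <- strings[sample.int(length(strings), 1L)]
    at <- sample.int(nchar(s) - k - 3L, 1L)
    win <- substr(s, at, at + k + 3L)
    got <- kfm_contains(ix, win)
    expect_true(got$found)
    expect_identical(kfm_vertex_string(ix, got$vertex), substr(win, 1L, k - 1L))
    bad <- win
    substr(bad, 5L, 5L) <- setdiff(DNA, substr(win, 5L, 5L))[1L]
    expect_identical(kfm_contains(ix, bad)$found,
                     all(substring(bad, 1:5, k:(k + 4L)) %in% km))
  }
})

test_that("rho_inv inverts rho with a unit step; vertex strings round trip", {
  ix <- toy2_index()
  inv <- kfm_prev_position_inverse(ix, c(0L, 4L, 2L))
  expect_identical(inv$letter, c("$", "G", "A"))
  expect_identical(inv$j, c(0L, 2L, 3L))
  expect_identical(kfm_vertex_string(ix, c(0L, 4L, 6L)), c("$$", "GA", "T$"))

  set.seed(105)
  for (k in c(4L, 6L)) {
    ix <- kfm_build(rand_strings(6, 35), k = k, prune_policy = "never")
    vs <- all_vertex_strings(ix)
    # strictly increasing in C collation; sorting reproduces 0..n-1
    expect_identical(order(vs, method = "radix"), seq_len(ix$n))
    inv <- kfm_prev_position_inverse(ix, 1:(ix$n - 1L))
    # inverse consistency: rho(a, j) = i and rho(a, j+1) = i+1
    for (t in seq_len(nrow(inv))) {
      a <- inv$letter[t]
      j <- inv$j[t]
      expect_identical(kfm_prev_position(ix, a, j), t)
      expect_identical(kfm_prev_position(ix, a, j + 1L), t + 1L)
      expect_identical(substr(vs[t + 1L], 1L, 1L), a)
    }
    # edge-source law: v_{rho(a,i)} = a * v_i^[1..k-2]
    for (i in 0:(ix$n - 1L)) {
      r <- kfm_vertex_record(ix, i)
      for (a in r$letters)
        expect_identical(vs[kfm_prev_position(ix, a, i) + 1L],
                         paste0(a, substr(vs[i + 1L], 1L, k - 2L)))
    }
  }
})

test_that("rho as combined map is non-decreasing with fixed endpoints", {
  set.seed(106)
  ix <- kfm_build(rand_strings(5, 50), k = 5)
  vals <- unlist(lapply(0:3, function(a) kfm_prev_position(ix, a, 0:ix$n)))
  expect_true(all(diff(vals) >= 0))
  expect_identical(vals[1L], 1L)              # rho(0, 0) = 1 when n > 1
  expect_identical(vals[length(vals)], ix$n)  # rho(sigma-1, n) = n
})

test_that("the store is an accelerator: q in {1,16,32,64} gives identical rho", {
  set.seed(107)
  ix <- kfm_build(rand_strings(10, 45), k = 7)
  a <- sample(0:3, 400, replace = TRUE)
  i <- sample(0:ix$n, 400, replace = TRUE)
  ref <- kfm_prev_position(ix, a, i)
  for (q in c(1L, 16L, 64L)) {
    iq <- kfm_rebuild_store(ix, q)
    expect_identical(kfm_prev_position(iq, a, i), ref)
    expect_identical(kfm_vertex_string(iq, 0:(iq$n - 1L)),
                     kfm_vertex_string(ix, 0:(ix$n - 1L)))
  }
})

# Backward-search minimality. For |x| < k, gamma(x, 0) is exactly
# min{i | x <= v_i}. For |x| >= k the compatible-extension set form holds
# only one-sidedly (gamma is a lower bound; the recursion does not see
# whether the dominating in-edge exists), with equality whenever x is
# realizable as a path — which is what the eta checks of the membership
# algorithm rely on.
test_that("gamma(x, 0) satisfies the backward-search minimality properties", {
  set.seed(108)
  for (rep in 1:3) {
    strings <- rand_strings(4, 12)
    k <- 4L
    tab <- oracle_table(strings, k)
    ix <- kfm_build(strings, k = k, prune_policy = "never")
    expect_lte(ix$n, 60L)
    xs <- c(rand_strings(10, 2L), rand_strings(10, k - 1L),
            rand_strings(10, k), rand_strings(5, k + 2L),
            substring(strings[1], 1, c(2, k, k + 2)))
    for (x in xs) {
      g <- kfm_gamma(ix, x, 0L)
      # the whole fold agrees with the independent order-definition fold oracle
      expect_identical(g, oracle_gamma(tab, x, 0L))
      if (nchar(x) < k) {
        hit <- which(vapply(tab$verts, str_ge, NA, y = x, USE.NAMES = FALSE))
        expect_identical(g, if (length(hit)) hit[1L] - 1L else tab$n)
      } else {
        expect_lte(g, oracle_min_compatible(tab, x))
      }
    }
    # realizable strings: gamma lands exactly on the (k-1)-prefix vertex
    for (t in 1:10) {
      s <- strings[sample.int(length(strings), 1L)]
      at <- sample.int(nchar(s) - k, 1L)
      win <- substr(s, at, at + k)
      expect_identical(kfm_gamma(ix, win, 0L),
                       match(substr(win, 1L, k - 1L), tab$verts) - 1L)
      expect_identical(kfm_gamma(ix, win, 0L), oracle_min_compatible(tab, win))
    }
  }
})
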