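# Independent string-level oracle: builds the final-completed graph of a
# string set explicitly (character vertices, in-edge sets, group-end flags)
# and evaluates rho by its order-theoretic definition
# rho(a, i) = min{ j | v_j >= a * v_i^- or j = n }.
# Everything here works on R character vectors in C (byte) collation, fully
# independent of the package's bit-packed machinery.

DNA <- c("A", "C", "G", "T")

substrings_of <- function(s, l) {
  if (nchar(s) < l) return(character(0))
  substring(s, 1:(nchar(s) - l + 1L), l:nchar(s))
}

# C-locale lexicographic compare; '$' (0x24) sorts before A-Z
str_ge <- function(x, y) {
  a <- utf8ToInt(x)
  b <- utf8ToInt(y)
  l <- min(length(a), length(b))
  if (l > 0L) {
    d <- which(a[seq_len(l)] != b[seq_len(l)])
    if (length(d)) return(a[d[1L]] > b[d[1L]])
  }
  length(a) >= length(b)
}

oracle_table <- function(strings, k) {
  stopifnot(all(nchar(strings) >= k - 1L))
  vmers <- unlist(lapply(strings, substrings_of, k - 1L))
  sufs <- vapply(strings, function(s) substr(s, nchar(s) - k + 2L, nchar(s)), "")
  pads <- unlist(lapply(sufs, function(v) # v[j+1..]$^j, j = 1..k-2
    paste0(substring(v, 2:(k - 1L), k - 1L), strrep("$", 1:(k - 2L)))))
  verts <- sort(unique(c(vmers, pads, strrep("$", k - 1L))), method = "radix")
  words <- unlist(lapply(strings, function(s) {
    v <- substr(s, nchar(s) - k + 2L, nchar(s))
    c(substrings_of(s, k),
      paste0(substring(v, 1:(k - 1L), k - 1L), strrep("$", 1:(k - 1L))))
  }))
  words <- sort(unique(words), method = "radix")
  targets <- substr(words, 2L, k)
  inlets <- substr(words, 1L, 1L)
  edges <- lapply(verts, function(v) sort(inlets[targets == v]))
  prefix <- substr(verts, 1L, k - 2L)
  n <- length(verts)
  fend <- c(prefix[-1L] != prefix[-n], TRUE)
  list(k = k, n = n, verts = verts, edges = edges, fend = fend,
       words = words)
}

# order-definition rho on an explicit table; a is a letter, i in [0, n]
oracle_rho <- function(tab, a, i) {
  n <- tab$n
  if (i == n) {
    hit <- which(substr(tab$verts, 1L, 1L) > a)
    return(if (length(hit)) hit[1L] - 1L else n)
  }
  target <- paste0(a, substr(tab$verts[i + 1L], 1L, tab$k - 2L))
  for (j in seq_len(n)) if (str_ge(tab$verts[j], target)) return(j - 1L)
  n
}

oracle_gamma <- function(tab, x, i0) {
  cur <- i0
  for (a in rev(strsplit(x, "", fixed = TRUE)[[1L]]))
    cur <- oracle_rho(tab, a, cur)
  cur
}

# all k-substrings of a string set (the naive k-mer hash set)
naive_kmers <- function(strings, k) {
  unique(unlist(lapply(strings, substrings_of, k)))
}

rand_dna <- function(len) paste(sample(DNA, len, replace = TRUE), collapse = "")

rand_strings <- function(n, len) vapply(seq_len(n), function(i) rand_dna(len), "")

TOY1 <- "ACGT"
TOY2 <- c("ACG", "CGT", "CGA")

toy2_index <- function(...) kfm_build(TOY2, k = 3, ...)
toy1_index <- function(...) kfm_build(TOY1, k = 3, ...)

# decode one record of an index into (letters, f)
record_of <- function(ix, i) kfm_vertex_record(ix, i)

all_vertex_strings <- function(ix) kfm_vertex_string(ix, 0:(ix$n - 1L))

# reconstruct kappa(j) from the R-side store arrays (independent of the
# C++ reconstruction path)
kappa_r <- function(ix, j) {
  st <- ix$store
  base <- (j %/% st$w) * st$w
  U <- st$checkpoints[j %/% st$w + 1L]
  if (j > base) U <- U + sum(as.integer(st$delta[(base + 2L):(j + 1L)]))
  st$u[j + 1L] + st$q * U
}

# realizable-forward-extension oracle for backward-search minimality:
# x <= v_i z compatible with G? DFS over out-edges, capped at |x| letters.
oracle_exists_ge <- function(tab, i, x) {
  n <- tab$n
  v <- tab$verts[i + 1L]
  lx <- nchar(x)
  extend <- function(w) {
    if (str_ge(w, x)) return(TRUE)
    if (nchar(w) >= lx) return(FALSE)
    # next letters b such that the last k-1 symbols of wb form a vertex and
    # the k-word (last k-1 of w) + b is an edge
    tail_v <- substr(w, nchar(w) - tab$k + 2L, nchar(w))
    at <- match(tail_v, tab$verts)
    any(vapply(DNA, function(b) {
      nxt <- paste0(substr(tail_v, 2L, tab$k - 1L), b)
      j <- match(nxt, tab$verts)
      if (is.na(j)) return(FALSE)
      # edge tail_v -> nxt exists iff first letter of tail_v is an in-edge of nxt
      if (!(substr(tail_v, 1L, 1L) %in% tab$edges[[j]])) return(FALSE)
      extend(paste0(w, b))
    }, NA))
  }
  if (grepl("$", v, fixed = TRUE)) return(str_ge(v, x)) # no Sigma extension
  extend(v)
}

oracle_min_compatible <- function(tab, x) {
  for (i in 0:(tab$n - 1L))
    if (oracle_exists_ge(tab, i, x)) return(i)
  tab$n
}
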