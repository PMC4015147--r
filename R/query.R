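#' Previous vertex position rho(a, i)
#'
#' The FM-index-like map of the kFM-index: if vertex `v_i` has an in-edge
#' labelled `a`, that edge originates from vertex `rho(a, i)`. In general
#' `rho(a, i) = 1 + sum_{b<a} tau(b) + c(a, i)`, where `c(a, i)` counts the
#' vertex groups wholly before position `i` that contain an `a` in-edge.
#' The value is reconstructed from the nearest previous stored position in
#' at most `q` group scans.
#'
#' @param index A `kfm_index`.
#' @param a Letter(s) or 0-based letter code(s).
#' @param i Vertex position(s) in `[0, n]` (0-based; `i = n` is allowed and
#'   gives `rho(a, n)`, with `rho(sigma-1, n) = n`).
#' @return Integer vector of positions in `[0, n]`.
#' @examples
#' ix <- kfm_build(c("ACG", "CGT", "CGA"), k = 3)
#' kfm_prev_position(ix, "A", 0)  # origin of the A in-edge of $$
#' @export
kfm_prev_position <- function(index, a, i) {
  stopifnot(inherits(index, "kfm_index"))
  i <- as.integer(i)
  if (anyNA(i) || any(i < 0L | i > index$n))
    stop("vertex position out of range [0, n]")
  kfm_rho_cpp(index, letter_code(index, a), i)
}

#' Backward-search fold gamma(x, i0)
#'
#' Folds `rho` right-to-left over `x` starting from `i0`:
#' `gamma(ax, i) = rho(a, gamma(x, i))`, `gamma("", i) = i`. With `i0 = 0`
#' this is `alpha(x)` (the string is implicitly terminated by `$`), with
#' `i0 = n` it is `beta(x)` (implicit terminator after every letter).
#'
#' @param index A `kfm_index`.
#' @param x A string over the alphabet (no sentinels; the terminator is
#'   encoded by `i0`).
#' @param i0 Start position in `[0, n]`, default 0.
#' @return A position in `[0, n]`.
#' @export
kfm_gamma <- function(index, x, i0 = 0L) {
  stopifnot(inherits(index, "kfm_index"), length(x) == 1L)
  kfm_gamma_cpp(index, encode_string(x, index$alphabet), as.integer(i0))
}

#' All vertices with a given prefix
#'
#' Returns the half-open interval `[alpha(x), beta(x))` of lexicographic
#' vertex positions whose strings start with `x`. The two backward-search
#' folds share state: once the alpha- and beta-states coincide the remaining
#' steps are computed once.
#'
#' @param index A `kfm_index`.
#' @param x Prefix string with `nchar(x) <= k - 1`.
#' @return A list with elements `alpha` and `beta` (class `kfm_interval`);
#'   the interval is empty iff `alpha == beta`.
#' @examples
#' ix <- kfm_build(c("ACG", "CGT", "CGA"), k = 3)
#' kfm_prefix_interval(ix, "G")   # the two vertices GA, GT
#' @export
kfm_prefix_interval <- function(index, x) {
  stopifnot(inherits(index, "kfm_index"), length(x) == 1L)
  if (nchar(x) > index$k - 1L)
    stop("prefix longer than k-1; use kfm_contains() for full strings")
  ab <- kfm_interval_cpp(index, encode_string(x, index$alphabet))
  structure(list(alpha = ab[1L], beta = ab[2L]), class = "kfm_interval")
}

#' @export
print.kfm_interval <- function(x, ...) {
  cat("[", x$alpha, ", ", x$beta, ") — ", x$beta - x$alpha, " vertex(es)\n",
      sep = "")
  invisible(x)
}

#' k-mer path membership
#'
#' Tests whether every k-substring of `x` is an edge of the graph, i.e.
#' whether `x` can be realised as a path. Starts at the (k-1)-suffix vertex
#' and backtracks one in-edge per remaining letter, checking the in-edge
#' flag at each step.
#'
#' @param index A `kfm_index`.
#' @param x String with `nchar(x) >= k` (use [kfm_prefix_interval()] for
#'   shorter strings).
#' @return A list with `found` (logical) and, when found, `vertex`, the
#'   position of x's (k-1)-prefix vertex (otherwise `NA`).
#' @export
kfm_contains <- function(index, x) {
  stopifnot(inherits(index, "kfm_index"), length(x) == 1L)
  if (nchar(x) < index$k)
    stop("string shorter than k; use kfm_prefix_interval() instead")
  r <- kfm_contains_cpp(index, encode_string(x, index$alphabet))
  list(found = r[1L] == 1L, vertex = if (r[1L] == 1L) r[2L] else NA_integer_)
}

#' Vectorized membership query
#'
#' @param index A `kfm_index`.
#' @param x Character vector of strings, each of length >= k.
#' @return Logical vector.
#' @export
kfm_query <- function(index, x) {
  vapply(x, function(s) kfm_contains(index, s)$found, logical(1L),
         USE.NAMES = FALSE)
}

#' Inverse previous-position map
#'
#' `rho_inv(i) = (a, j)` such that `rho(a, j) = i` and
#' `rho(a, j + 1) = i + 1`; `a` is the first letter of `v_i` and `j` the
#' last vertex of the group sharing `v_i`'s (k-2)-suffix. Implemented as a
#' binary search over the stored kappa values followed by a stepwise scan.
#' `rho_inv(0)` is the sentinel pair `("$", 0)`.
#'
#' @param index A `kfm_index`.
#' @param i Vertex position(s) in `[0, n)`.
#' @return A data.frame with columns `letter` (character, `"$"` for vertex
#'   0) and `j` (integer).
#' @export
kfm_prev_position_inverse <- function(index, i) {
  stopifnot(inherits(index, "kfm_index"))
  m <- kfm_rho_inv_cpp(index, as.integer(i))
  data.frame(letter = c("$", index$alphabet$letters)[m[1L, ] + 2L],
             j = m[2L, ], stringsAsFactors = FALSE)
}

#' Reconstruct the string of a vertex
#'
#' Iterates the inverse previous-position map k-1 times, collecting first
#' letters; final-completing vertices render their padding as `$`.
#'
#' @param index A `kfm_index`.
#' @param i Vertex position(s) in `[0, n)`.
#' @return Character vector of (k-1)-symbol strings.
#' @examples
#' ix <- kfm_build(c("ACG", "CGT", "CGA"), k = 3)
#' kfm_vertex_string(ix, 0:(ix$n - 1))
#' @export
kfm_vertex_string <- function(index, i) {
  stopifnot(inherits(index, "kfm_index"))
  m <- kfm_vertex_codes_cpp(index, as.integer(i))
  syms <- c("$", index$alphabet$letters)
  apply(m, 2L, function(col) paste(syms[col + 2L], collapse = ""))
}
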