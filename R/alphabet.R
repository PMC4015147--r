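#' Ordered alphabet for a kFM-index
#'
#' Declares the ordered letter set of the index. Two implicit sentinels
#' frame the order: `$` sorts strictly before every letter and `Inf`
#' (printed as `oo`) strictly after. Letter codes are 0..sigma-1 in the
#' given order; the sentinel `$` is never stored in the in-edge flags, it
#' only arises in reconstructed strings of final-completing vertices.
#'
#' @param letters Character vector of distinct single-character letters in
#'   sort order. Default is the DNA alphabet A < C < G < T.
#' @param complements Optional character vector of the same length giving
#'   the complement of each letter (used for reverse-complement
#'   augmentation). Defaults to the Watson-Crick pairing for the DNA
#'   alphabet, `NULL` otherwise.
#' @return An object of class `kfm_alphabet`.
#' @examples
#' kfm_alphabet()                    # DNA
#' kfm_alphabet(c("0", "1"))         # binary, no complement defined
#' @export
kfm_alphabet <- function(letters = c("A", "C", "G", "T"), complements = NULL) {
  letters <- as.character(letters)
  if (length(letters) < 1L || length(letters) > 30L)
    stop("alphabet must contain between 1 and 30 letters")
  if (any(nchar(letters) != 1L) || anyDuplicated(letters) ||
      any(letters %in% c("$")))
    stop("letters must be distinct single characters, none of them '$'")
  if (is.null(complements) && identical(letters, c("A", "C", "G", "T")))
    complements <- c("T", "G", "C", "A")
  if (!is.null(complements)) {
    complements <- as.character(complements)
    if (length(complements) != length(letters) ||
        !all(complements %in% letters))
      stop("complements must map every letter onto the alphabet")
  }
  structure(
    list(letters = letters, sigma = length(letters),
         sentinel_low = "$", sentinel_high = "∞",
         complements = complements),
    class = "kfm_alphabet"
  )
}

#' @export
print.kfm_alphabet <- function(x, ...) {
  cat("kfm_alphabet: $ < ", paste(x$letters, collapse = " < "),
      " < oo (sigma = ", x$sigma, ")\n", sep = "")
  invisible(x)
}

# letters -> 0-based codes for one string; stops on foreign symbols
encode_string <- function(x, alphabet) {
  if (nchar(x) == 0L) return(integer(0))
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  codes <- match(ch, alphabet$letters) - 1L
  if (anyNA(codes))
    stop("symbol '", ch[which(is.na(codes))[1L]],
         "' is not in the declared alphabet")
  codes
}

# 0-based codes -> string; -1 renders the sentinel $
decode_codes <- function(codes, alphabet) {
  paste(c("$", alphabet$letters)[codes + 2L], collapse = "")
}

letters_string <- function(alphabet) paste(alphabet$letters, collapse = "")
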