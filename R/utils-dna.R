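# IUPAC nucleotide ambiguity alphabet, shared by the mining, primer-design and
# in-silico-PCR code paths.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# base-set (sorted, collapsed) -> single IUPAC code
.iupac_from_set <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  codes <- names(IUPAC_SETS)
  names(codes) <- keys
  codes
})

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x character vector of DNA strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTR")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# IUPAC pattern -> PCRE character-class regex (uppercase input assumed)
iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- which(!chars %in% IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code '", chars[bad[1]], "' at position ", bad[1])
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

# All start positions (0-based) of an IUPAC pattern in a plain sequence,
# overlapping matches included. 'N' in the subject never matches.
iupac_find_all <- function(pattern, subject) {
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  hits <- gregexpr(rx, subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# uniform random DNA with given GC content
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.assert_acgt <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(what, " contains non-ACGT character at position ", bad[i],
         " ('", substr(x[i], bad[i], bad[i]), "')")
  }
  invisible(x)
}
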