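#' Degeneracy of an IUPAC-coded primer
#'
#' The degeneracy is the number of distinct concrete sequences the pattern
#' represents: the product over positions of each code's cardinality
#' (A/C/G/T = 1; R/Y/S/W/K/M = 2; B/D/H/V = 3; N = 4). The combined
#' degeneracy of a primer pair is the product of the two primers'
#' degeneracies, e.g. 48 x 384 = 18,432.
#'
#' @param iupac character vector of IUPAC patterns.
#' @return integer (double for large products) vector of degeneracies.
#' @examples
#' iupac_degeneracy("NNNNNN")  # 4096
#' @export
iupac_degeneracy <- function(iupac) {
  card <- vapply(IUPAC_SETS, length, 0L)
  vapply(toupper(iupac), function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- which(!ch %in% IUPAC_CODES)
    if (length(bad))
      stop("invalid IUPAC code '", ch[bad[1]], "' at position ", bad[1])
    prod(card[ch])
  }, 0, USE.NAMES = FALSE)
}

#' Does a concrete sequence match an IUPAC pattern?
#'
#' Position-wise subset semantics: position i matches iff the base set of
#' `seq[i]` is contained in the base set of `iupac[i]`. For plain A/C/G/T
#' sequences this is the usual "base is among the code's bases" rule; an `N`
#' in the sequence only matches an `N` in the pattern.
#'
#' @param iupac IUPAC pattern.
#' @param seq sequence of equal length.
#' @return logical.
#' @export
iupac_matches <- function(iupac, seq) {
  iupac <- toupper(iupac); seq <- toupper(seq)
  if (nchar(iupac) != nchar(seq))
    stop("pattern and sequence lengths differ (", nchar(iupac), " vs ",
         nchar(seq), ")")
  pc <- strsplit(iupac, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  if (any(!pc %in% IUPAC_CODES)) stop("invalid IUPAC code in pattern")
  if (any(!sc %in% IUPAC_CODES)) stop("invalid IUPAC code in sequence")
  all(mapply(function(p, s) all(IUPAC_SETS[[s]] %in% IUPAC_SETS[[p]]),
             pc, sc))
}

#' All concrete expansions of an IUPAC pattern
#'
#' @param iupac IUPAC pattern.
#' @param max_degeneracy refuse to expand beyond this many sequences.
#' @return character vector of all matching A/C/G/T sequences.
#' @export
iupac_expand <- function(iupac, max_degeneracy = 65536) {
  d <- iupac_degeneracy(iupac)
  if (d > max_degeneracy)
    stop("degeneracy ", d, " exceeds max_degeneracy ", max_degeneracy)
  sets <- lapply(strsplit(toupper(iupac), "")[[1]], function(ch) IUPAC_SETS[[ch]])
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' Minimal degenerate consensus of a set of primers
#'
#' Builds the position-wise union of the input base sets and encodes each
#' union as a single IUPAC code — the tightest single degenerate primer that
#' matches every input. Note the union is per position, so the consensus can
#' over-cover: {"AC", "GT"} gives "RY" with degeneracy 4, which also matches
#' "AT" and "GC".
#'
#' @param primer_seqs character vector of equal-length sequences (IUPAC codes
#'   allowed in the inputs).
#' @return list with `iupac` and `degeneracy`.
#' @examples
#' consensus_degenerate(c("AA", "AC"))  # "AM", degeneracy 2
#' @export
consensus_degenerate <- function(primer_seqs) {
  stopifnot(length(primer_seqs) >= 1)
  primer_seqs <- toupper(primer_seqs)
  if (length(unique(nchar(primer_seqs))) != 1L)
    stop("primers must have equal lengths")
  mat <- do.call(rbind, strsplit(primer_seqs, ""))
  if (any(!mat %in% IUPAC_CODES)) stop("invalid IUPAC code in input")
  iupac <- paste(apply(mat, 2, function(col) {
    u <- sort(unique(unlist(IUPAC_SETS[col])))
    .iupac_from_set[[paste(u, collapse = "")]]
  }), collapse = "")
  list(iupac = iupac, degeneracy = iupac_degeneracy(iupac))
}
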