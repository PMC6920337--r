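# Fixed adapter/tail sequences of the two-step MRASeq PCR.

#' Adapter and tail constants
#'
#' `M13_TAIL` bridges PCR1 products to the barcoded PCR2 forward primer;
#' `TRP1B` is the Ion truncated P1B adapter used as the PCR1/PCR2 reverse
#' anchor; `ION_A` is the standard Ion-A sequencing adapter.
#' @format character scalars.
#' @export
M13_TAIL <- "GATGTAAAACGACGGCCAGTG"

#' @rdname M13_TAIL
#' @export
TRP1B <- "CCTCTCTATGGGCAGTCGGTGAT"

#' @rdname M13_TAIL
#' @export
ION_A <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"

#' Assemble the two-step-PCR fusion primers
#'
#' PCR1 forward = M13 tail + 6--10 nt spacer + PstI site (CTGCAG);
#' PCR1 reverse = trP1B + 6--12 nt spacer + MspI site (CCGG);
#' PCR2 forward = Ion-A + 10--12 nt barcode + M13 tail;
#' PCR2 reverse = trP1B. Spacers may be specific (sMRASeq) or IUPAC
#' degenerate (dMRASeq); degenerate codes are carried through verbatim.
#'
#' @param spacer_a forward spacer, 6--10 nt (IUPAC allowed).
#' @param spacer_b reverse spacer, 6--12 nt (IUPAC allowed).
#' @param barcode optional PCR2 barcode, 10--12 nt.
#' @param site_a,site_b 3' recognition anchors (defaults CTGCAG / CCGG).
#' @return data frame `role`, `sequence`, `length`, with per-primer part
#'   lists in the `parts` attribute.
#' @examples
#' build_fusion_primers("AAAAAA", "NNNNNN", barcode = "CTAAGGTAAC")
#' @export
build_fusion_primers <- function(spacer_a, spacer_b, barcode = NULL,
                                 site_a = "CTGCAG", site_b = "CCGG") {
  spacer_a <- toupper(spacer_a); spacer_b <- toupper(spacer_b)
  iupac_to_regex(spacer_a); iupac_to_regex(spacer_b)
  if (nchar(spacer_a) < 6 || nchar(spacer_a) > 10)
    stop("forward spacer must be 6-10 nt, got ", nchar(spacer_a))
  if (nchar(spacer_b) < 6 || nchar(spacer_b) > 12)
    stop("reverse spacer must be 6-12 nt, got ", nchar(spacer_b))
  parts <- list(
    `PCR1-forward` = c(tail = M13_TAIL, spacer = spacer_a, site = site_a),
    `PCR1-reverse` = c(adapter = TRP1B, spacer = spacer_b, site = site_b))
  if (!is.null(barcode)) {
    barcode <- toupper(barcode)
    if (nchar(barcode) < 10 || nchar(barcode) > 12)
      stop("barcode must be 10-12 nt, got ", nchar(barcode))
    parts$`PCR2-forward` <- c(adapter = ION_A, barcode = barcode,
                              tail = M13_TAIL)
  }
  parts$`PCR2-reverse` <- c(adapter = TRP1B)
  seqs <- vapply(parts, paste, "", collapse = "")
  out <- data.frame(role = names(parts), sequence = unname(seqs),
                    length = unname(nchar(seqs)), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, parts = parts)
}

#' Primer-pool naming ("KK-NN")
#'
#' The convention names a pool by the A-side (PstI) primer length and the
#' total number of primers it contains: `16-14` is a pool of seven pairs of
#' 16-mer primers (14 primers in all). An en-dash is accepted on parse.
#'
#' @param k A-primer length.
#' @param n_pairs number of primer pairs in the pool.
#' @return `pool_name`: the name string. `parse_pool_name`: a list with
#'   `k`, `n_primers`, `n_pairs`.
#' @examples
#' pool_name(16, 7)
#' parse_pool_name("16-14")
#' @export
pool_name <- function(k, n_pairs) sprintf("%d-%d", k, 2L * n_pairs)

#' @rdname pool_name
#' @param name a pool name such as `"16-14"`.
#' @export
parse_pool_name <- function(name) {
  m <- regmatches(name, regexec("^([0-9]+)[-–]([0-9]+)$", name))[[1]]
  if (length(m) != 3) stop("cannot parse pool name '", name, "'")
  n_primers <- as.integer(m[3])
  if (n_primers %% 2L != 0L)
    stop("pool '", name, "' has odd primer count ", n_primers)
  list(k = as.integer(m[2]), n_primers = n_primers,
       n_pairs = n_primers %/% 2L)
}
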