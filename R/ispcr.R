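#' Primer sets for in-silico PCR
#'
#' A primer set is either a pool of specific pairs (sMRASeq) or a single
#' degenerate pair (dMRASeq). Members are always stored with the A primer on
#' the A-enzyme (PstI) side.
#'
#' @param pairs data frame with columns `a_primer`, `b_primer` (e.g. from
#'   [top_pairs()]).
#' @return an object of class `mra_primer_set`.
#' @export
primer_pool <- function(pairs) {
  pairs <- as.data.frame(pairs)[, c("a_primer", "b_primer")]
  if (nrow(pairs) == 0L) stop("empty primer pool")
  if (length(unique(nchar(pairs$a_primer))) != 1L ||
      length(unique(nchar(pairs$b_primer))) != 1L)
    stop("all pool members must share primer lengths per side")
  structure(list(kind = "specific-pool", pairs = pairs,
                 kA = nchar(pairs$a_primer[1]), kB = nchar(pairs$b_primer[1])),
            class = "mra_primer_set")
}

#' @rdname primer_pool
#' @param a_iupac,b_iupac degenerate primer sequences (IUPAC), each ending
#'   3' in its recognition site.
#' @export
degenerate_pair <- function(a_iupac, b_iupac) {
  a_iupac <- toupper(a_iupac); b_iupac <- toupper(b_iupac)
  iupac_to_regex(a_iupac); iupac_to_regex(b_iupac)
  structure(list(kind = "degenerate-pair",
                 a_iupac = a_iupac, b_iupac = b_iupac,
                 kA = nchar(a_iupac), kB = nchar(b_iupac),
                 degeneracy = iupac_degeneracy(a_iupac) *
                   iupac_degeneracy(b_iupac)),
            class = "mra_primer_set")
}

#' @export
print.mra_primer_set <- function(x, ...) {
  if (x$kind == "specific-pool")
    cat("specific pool of", nrow(x$pairs), "pairs (",
        pool_name(x$kA, nrow(x$pairs)), ")\n")
  else
    cat("degenerate pair", x$a_iupac, "/", x$b_iupac,
        "combined degeneracy", format(x$degeneracy, big.mark = ","), "\n")
  invisible(x)
}

#' Predict which amplicon targets a primer set amplifies
#'
#' Matching is anchored: only the k bases ending at each restriction site are
#' compared — exact equality against pool members for specific pools,
#' IUPAC containment for degenerate pairs. No internal mismatches or off-site
#' binding are modeled. Predictions are always a subset of
#' [find_amplicons()] at the same length range.
#'
#' @param g an [genome()] object.
#' @param primer_set a [primer_pool()] or [degenerate_pair()].
#' @param insert_range insert-length bounds (default `c(77, 202)`).
#' @param enzymeA,enzymeB enzymes (default PstI/MspI).
#' @param tm_anchors optional minimum-Tm anchors (see [tm_threshold()]);
#'   `NULL` (default) disables the Tm screen.
#' @param params [thermo_params()].
#' @return the matching amplicon rows plus `a_primer`, `b_primer` (the
#'   concrete genomic flank primers that matched), `a_tm`, `b_tm`.
#' @export
predict_amplicons <- function(g, primer_set, insert_range = c(77L, 202L),
                              enzymeA = PstI(), enzymeB = MspI(),
                              tm_anchors = NULL, params = thermo_params()) {
  stopifnot(inherits(primer_set, "mra_primer_set"))
  amp <- find_amplicons(g, enzymeA, enzymeB,
                        min_len = insert_range[1], max_len = insert_range[2])
  fl <- .extract_flanks(g, amp, primer_set$kA, primer_set$kB,
                        enzymeA, enzymeB)
  ok <- !is.na(fl$a_primer) & !is.na(fl$b_primer)
  if (primer_set$kind == "specific-pool") {
    key <- paste(fl$a_primer, fl$b_primer, sep = "\t")
    pool_key <- paste(primer_set$pairs$a_primer, primer_set$pairs$b_primer,
                      sep = "\t")
    ok <- ok & key %in% pool_key
  } else {
    ok <- ok &
      grepl(paste0("^", iupac_to_regex(primer_set$a_iupac), "$"), fl$a_primer) &
      grepl(paste0("^", iupac_to_regex(primer_set$b_iupac), "$"), fl$b_primer)
  }
  out <- cbind(as.data.frame(amp)[ok, , drop = FALSE],
               fl[ok, , drop = FALSE])
  if (!is.null(tm_anchors) && nrow(out)) {
    keep <- nn_tm(out$a_primer, params) >=
      tm_threshold(primer_set$kA, tm_anchors) &
      nn_tm(out$b_primer, params) >= tm_threshold(primer_set$kB, tm_anchors)
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out)) {
    out$a_tm <- nn_tm(out$a_primer, params)
    out$b_tm <- nn_tm(out$b_primer, params)
  } else {
    out$a_tm <- numeric(0); out$b_tm <- numeric(0)
  }
  rownames(out) <- NULL
  out
}
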