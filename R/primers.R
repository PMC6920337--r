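# Restriction-anchored primer extraction and genome-wide pair counting.
#
# A primer candidate is the k bases that end 3' in the recognition site and
# point into the insert: on the left flank it is read off the forward strand,
# on the right flank off the reverse strand. For the pair key the A primer is
# always the A-enzyme-side (PstI-side) sequence, regardless of which site
# comes first on the forward strand.

# vectorized flank extraction for a whole amplicon table; returns NA where a
# flank runs off the contig
.extract_flanks <- function(g, amp, kA, kB, enzymeA, enzymeB) {
  lenA <- nchar(enzymeA$recognition)
  lenB <- nchar(enzymeB$recognition)
  seqs <- unclass(g)[amp$chrom]
  clen <- nchar(seqs)
  afirst <- amp$orientation == "A-first"

  # forward-strand coordinate window of each primer (0-based half-open)
  a_lo <- ifelse(afirst, amp$insert_start - kA, amp$insert_end)
  a_hi <- ifelse(afirst, amp$insert_start, amp$insert_end + kA)
  b_lo <- ifelse(afirst, amp$insert_end, amp$insert_start - kB)
  b_hi <- ifelse(afirst, amp$insert_end + kB, amp$insert_start)

  ok_a <- a_lo >= 0 & a_hi <= clen
  ok_b <- b_lo >= 0 & b_hi <= clen
  a_seq <- ifelse(ok_a, substring(seqs, a_lo + 1L, a_hi), NA_character_)
  b_seq <- ifelse(ok_b, substring(seqs, b_lo + 1L, b_hi), NA_character_)
  # right-flank primers read on the reverse strand
  a_seq[!afirst & ok_a] <- revcomp(a_seq[!afirst & ok_a])
  b_seq[afirst & ok_b] <- revcomp(b_seq[afirst & ok_b])
  a_seq[!is.na(a_seq) & grepl("[^ACGT]", a_seq)] <- NA_character_
  b_seq[!is.na(b_seq) & grepl("[^ACGT]", b_seq)] <- NA_character_
  data.frame(a_primer = a_seq, b_primer = b_seq, stringsAsFactors = FALSE)
}

#' Extract the restriction-anchored primer pair of one amplicon
#'
#' @param g an [genome()] object.
#' @param amplicon one row of a [find_amplicons()] table.
#' @param kA,kB total primer lengths (recognition site included), 12--18 nt.
#' @param enzymeA,enzymeB the enzymes used for mining.
#' @param params [thermo_params()] for the reported Tms.
#' @return a list with elements `A` and `B` (`side`, `k`, `sequence`, `tm`),
#'   or `NULL` when either flank runs off the contig or contains a base
#'   outside A/C/G/T.
#' @export
extract_primer_pair <- function(g, amplicon, kA, kB,
                                enzymeA = PstI(), enzymeB = MspI(),
                                params = thermo_params()) {
  stopifnot(kA >= 12, kA <= 18, kB >= 12, kB <= 18)
  fl <- .extract_flanks(g, amplicon, kA, kB, enzymeA, enzymeB)
  if (is.na(fl$a_primer[1]) || is.na(fl$b_primer[1])) return(NULL)
  list(A = list(side = "A", k = kA, sequence = fl$a_primer[1],
                tm = nn_tm(fl$a_primer[1], params)),
       B = list(side = "B", k = kB, sequence = fl$b_primer[1],
                tm = nn_tm(fl$b_primer[1], params)))
}

#' Minimum-Tm threshold as a function of primer length
#'
#' Thresholds are anchored at 38 degC for 12-mers and 50 degC for 16-mers;
#' lengths in between are linearly interpolated and lengths above 16 use the
#' 16-mer threshold. Both anchors are configurable.
#'
#' @param k primer length(s) in nt.
#' @param anchors named numeric vector, names are anchor lengths.
#' @return numeric threshold(s) in degC.
#' @export
tm_threshold <- function(k, anchors = c(`12` = 38, `16` = 50)) {
  ks <- as.numeric(names(anchors))
  stopifnot(length(anchors) >= 1)
  o <- order(ks)
  ks <- ks[o]; vals <- unname(anchors[o])
  stats::approx(ks, vals, xout = pmin(pmax(k, min(ks)), max(ks)),
                rule = 2, ties = "ordered")$y
}

#' Count genome-wide amplicons per specific primer pair
#'
#' Mines (or reuses) amplicon targets in the given insert-length range,
#' extracts both k-mer primers for each, screens each primer against the
#' length-dependent minimum Tm, and tallies one count per distinct
#' (A-primer, B-primer) pair over the qualifying amplicons. Counts conserve:
#' their sum equals the number of qualifying amplicons. Pairs are ranked by
#' count (descending) with a lexicographic (A, B) tie-break.
#'
#' @param g an [genome()] object.
#' @param kA,kB primer lengths (site included), 12--18.
#' @param enzymeA,enzymeB enzymes (default PstI/MspI).
#' @param insert_range insert-length bounds used for pair counting
#'   (default `c(77, 202)`, a tighter window than mining's 60--250).
#' @param tm_anchors minimum-Tm anchors passed to [tm_threshold()]; set to
#'   `NULL` to disable the Tm screen.
#' @param params [thermo_params()].
#' @param amplicons optional pre-mined table (it is re-filtered to
#'   `insert_range`).
#' @return data frame of class `mra_paircounts`: `a_primer`, `b_primer`,
#'   `count`, `rank`, `cum_count`, `cum_share`. Attributes:
#'   `total_amplicons` (number of qualifying amplicons), `kA`, `kB`,
#'   `assignments` (per-qualifying-amplicon pair key, for cross-checking
#'   against in-silico PCR predictions).
#' @export
count_primer_pairs <- function(g, kA = 12L, kB = 12L,
                               enzymeA = PstI(), enzymeB = MspI(),
                               insert_range = c(77L, 202L),
                               tm_anchors = c(`12` = 38, `16` = 50),
                               params = thermo_params(),
                               amplicons = NULL) {
  if (is.null(amplicons))
    amplicons <- find_amplicons(g, enzymeA, enzymeB,
                                min_len = insert_range[1],
                                max_len = insert_range[2])
  amp <- amplicons[amplicons$insert_len >= insert_range[1] &
                     amplicons$insert_len <= insert_range[2], , drop = FALSE]
  fl <- .extract_flanks(g, amp, kA, kB, enzymeA, enzymeB)
  keep <- !is.na(fl$a_primer) & !is.na(fl$b_primer)
  if (!is.null(tm_anchors) && any(keep)) {
    thrA <- tm_threshold(kA, tm_anchors)
    thrB <- tm_threshold(kB, tm_anchors)
    ua <- unique(fl$a_primer[keep]); ub <- unique(fl$b_primer[keep])
    tma <- stats::setNames(nn_tm(ua, params), ua)
    tmb <- stats::setNames(nn_tm(ub, params), ub)
    keep <- keep & !is.na(fl$a_primer) & !is.na(fl$b_primer)
    keep[keep] <- tma[fl$a_primer[keep]] >= thrA &
      tmb[fl$b_primer[keep]] >= thrB
  }
  qual <- fl[keep, , drop = FALSE]
  if (nrow(qual)) {
    key <- paste(qual$a_primer, qual$b_primer, sep = "\t")
    tab <- table(key)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    pc <- data.frame(a_primer = vapply(parts, `[`, "", 1),
                     b_primer = vapply(parts, `[`, "", 2),
                     count = as.integer(tab), stringsAsFactors = FALSE)
    pc <- pc[order(-pc$count, pc$a_primer, pc$b_primer), , drop = FALSE]
  } else {
    pc <- data.frame(a_primer = character(0), b_primer = character(0),
                     count = integer(0))
  }
  pc$rank <- seq_len(nrow(pc))
  pc$cum_count <- cumsum(pc$count)
  tot <- sum(pc$count)
  pc$cum_share <- if (tot > 0) pc$cum_count / tot else numeric(nrow(pc))
  rownames(pc) <- NULL
  assignments <- cbind(amp[keep, c("chrom", "insert_start", "insert_end",
                                   "orientation"), drop = FALSE], qual)
  rownames(assignments) <- NULL
  structure(pc, total_amplicons = tot, kA = kA, kB = kB,
            assignments = assignments,
            class = c("mra_paircounts", "data.frame"))
}

#' Top-n primer pairs with cumulative amplicon share
#'
#' @param paircounts a [count_primer_pairs()] table.
#' @param n number of top pairs (the whole table when `n` exceeds its size).
#' @return the first `n` rows with `cum_count`/`cum_share` relative to all
#'   qualifying amplicons.
#' @export
top_pairs <- function(paircounts, n) {
  stopifnot(n >= 1)
  utils::head(as.data.frame(paircounts), n)
}

#' Write a ranked pair-count table as TSV
#' @param paircounts a [count_primer_pairs()] table.
#' @param path output file.
#' @export
write_paircounts <- function(paircounts, path) {
  utils::write.table(as.data.frame(paircounts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
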