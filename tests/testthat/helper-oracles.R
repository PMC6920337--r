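# Independent oracles used across the suite. They deliberately avoid the
# package's scanning/mining code paths: motif occurrences come from
# Biostrings::matchPattern and amplicon enumeration is a naive all-pairs
# check of the three criteria.

oracle_sites <- function(seq, motif) {
  subj <- Biostrings::DNAString(seq)
  pats <- unique(c(motif, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))))
  sort(unique(unlist(lapply(pats, function(p)
    Biostrings::start(Biostrings::matchPattern(p, subj, fixed = "subject"))
  )))) - 1L  # 0-based
}

# naive all-ordered-pairs amplicon enumeration; every (A-site, B-site) pair
# is tested for order, flank overlap, length window and intervening sites.
# Returns a sorted key vector.
oracle_amplicons <- function(g, recA = "CTGCAG", recB = "CCGG",
                             min_len = 60, max_len = 250) {
  keys <- character(0)
  for (ch in names(g)) {
    s <- unclass(g)[[ch]]
    a <- oracle_sites(s, recA)
    b <- oracle_sites(s, recB)
    if (!length(a) || !length(b)) next
    st <- c(a, b); en <- c(a + nchar(recA), b + nchar(recB))
    ty <- rep(c("A", "B"), c(length(a), length(b)))
    n <- length(st)
    pair <- which(outer(ty, ty, "!=") &            # opposite types
                    outer(en, st, function(e, s2) s2 >= e) &  # ordered, no overlap
                    outer(en, st, function(e, s2) s2 - e >= min_len) &
                    outer(en, st, function(e, s2) s2 - e <= max_len),
                  arr.ind = TRUE)
    for (r in seq_len(nrow(pair))) {
      i <- pair[r, 1]; j <- pair[r, 2]
      ins_s <- en[i]; ins_e <- st[j]
      other <- st < ins_e & en > ins_s
      other[c(i, j)] <- FALSE
      if (any(other)) next
      ori <- if (ty[i] == "A") "A-first" else "B-first"
      keys <- c(keys, paste(ch, ins_s, ins_e, ori, sep = ":"))
    }
  }
  sort(unique(keys))
}

amplicon_keys <- function(amp) {
  sort(paste(amp$chrom, amp$insert_start, amp$insert_end, amp$orientation,
             sep = ":"))
}

# random genome WITH motifs allowed in the background
random_genome <- function(len, n_chrom = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  genome(stats::setNames(seqs, sprintf("chr%d", seq_len(n_chrom))))
}
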