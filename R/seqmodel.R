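#' Genome container
#'
#' A light container for an ordered set of named nucleotide sequences, the
#' substrate for amplicon mining. Bases are stored uppercase; `N` (and other
#' IUPAC ambiguity codes) are permitted on input, since real references carry
#' assembly gaps, but recognition sites containing `N` never match during
#' mining.
#'
#' @param sequences named character vector of sequences (A/C/G/T/N plus IUPAC
#'   ambiguity codes; lowercase accepted and normalized).
#' @return an object of class `mra_genome`: a named uppercase character vector.
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT"))
#' seq_lengths(g)
#' @export
genome <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  x <- toupper(sequences)
  if (any(nchar(x) == 0L)) stop("empty sequence: ", names(x)[nchar(x) == 0L][1])
  bad <- regexpr(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"), x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("sequence '", names(x)[i], "' has non-IUPAC character '",
         substr(x[i], bad[i], bad[i]), "' at offset ", bad[i] - 1L)
  }
  structure(x, class = "mra_genome")
}

#' @rdname genome
#' @param x an `mra_genome`.
#' @export
seq_lengths <- function(x) nchar(unclass(x))

#' @export
print.mra_genome <- function(x, ...) {
  cat("mra_genome with", length(x), "sequence(s),",
      format(sum(seq_lengths(x)), big.mark = ","), "bp total\n")
  n <- utils::head(seq_along(x), 6)
  for (i in n) cat("  ", names(x)[i], ": ", seq_lengths(x)[i], " bp\n", sep = "")
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Read and write FASTA
#'
#' Reading normalizes bases to uppercase and keeps the full header line as the
#' sequence name; writing wraps at 60 columns. Writing then reading is the
#' identity on (name, bases).
#'
#' @param path file path (plain or gzipped for reading).
#' @return `read_fasta`: an [genome()] object.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) stop("no FASTA records in ", path)
  genome(stats::setNames(as.character(x), names(x)))
}

#' @rdname read_fasta
#' @param x an `mra_genome` (or named character vector).
#' @export
write_fasta <- function(x, path) {
  x <- genome(unclass(x))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(unclass(x)), path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read records: id + bases + Sanger (Phred+33) quality
#'
#' The core invariant — `nchar(bases) == nchar(quality)` for every read — is
#' enforced at construction and re-checked after every editing step in the
#' preprocessing pipeline.
#'
#' @param id,bases,quality character vectors of equal length.
#' @return a `data.frame` with columns `id`, `bases`, `quality`.
#' @export
read_records <- function(id, bases, quality) {
  stopifnot(length(id) == length(bases), length(bases) == length(quality))
  bad <- nchar(bases) != nchar(quality)
  if (any(bad))
    stop("bases/quality length mismatch for read '", id[which(bad)[1]], "'")
  data.frame(id = as.character(id), bases = as.character(bases),
             quality = as.character(quality), stringsAsFactors = FALSE)
}

#' Read and write 4-line Sanger FASTQ
#'
#' @param path file path (plain or gzipped).
#' @return `read_fastq`: a [read_records()] data frame.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  read_records(names(x), as.character(x), q)
}

#' @rdname read_fastq
#' @param reads a [read_records()] data frame.
#' @export
write_fastq <- function(reads, path) {
  reads <- read_records(reads$id, reads$bases, reads$quality)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$bases,
                               "+", reads$quality)), con)
  invisible(path)
}

# Rejection-sample a motif-free stretch: regenerate any window that matches a
# recognition motif (either strand) until the stretch is clean.
.motif_free_dna <- function(n, gc, motifs, max_rounds = 200L) {
  if (n == 0L) return("")
  s <- random_dna(n, gc)
  pats <- unique(c(motifs, revcomp(motifs)))
  for (round in seq_len(max_rounds)) {
    hits <- lapply(pats, function(p) {
      h <- iupac_find_all(p, s)
      if (length(h)) cbind(h, nchar(p)) else NULL
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(hits))) {
      w <- (hits[i, 1] + 1):(hits[i, 1] + hits[i, 2])
      ch[w] <- strsplit(random_dna(length(w), gc), "")[[1]]
    }
    s <- paste(ch, collapse = "")
  }
  stop("could not generate motif-free background after ", max_rounds, " rounds")
}

#' Generate a synthetic genome with planted amplicon targets
#'
#' Builds chromosomes whose background is free of both recognition motifs on
#' both strands (per-window rejection sampling), then plants
#' `siteA + insert + siteB` constructs at recorded coordinates. Because the
#' background and the inserts are motif-free, the planted sites are provably
#' the only motif occurrences, so mining can be tested for exact recovery
#' against the returned truth table.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome in bp.
#' @param gc GC content of the background (0..1).
#' @param planted list of plants, each `list(insert_len =, orientation =)` with
#'   orientation `"A-first"` or `"B-first"`; or an integer vector of insert
#'   lengths (all A-first). Plants are assigned to chromosomes round-robin.
#' @param seed integer seed; identical seeds give identical output.
#' @param enzymes list of two [restriction_enzyme()] objects (A then B);
#'   default PstI + MspI.
#' @param margin minimum motif-free background before the first and after the
#'   last construct on a chromosome (default 30 bp, enough for 18-mer primer
#'   flanks).
#' @param min_gap minimum background between consecutive constructs (default
#'   260 bp). Keeping this above the default mining window (250 bp inserts)
#'   guarantees that the spacing between two plants can never itself qualify
#'   as an amplicon, so the truth table is exactly the minable set.
#' @return `list(genome =, truth =)` where `truth` is a data frame with one
#'   row per plant: `chrom`, `insert_start`, `insert_end` (0-based half-open,
#'   sites excluded), `orientation`, `insert_len`, `insert_seq`, `left_site`,
#'   `right_site`.
#' @export
generate_genome <- function(n_chrom = 1L, chrom_len = 10000L, gc = 0.45,
                            planted = list(), seed = 1L,
                            enzymes = list(PstI(), MspI()), margin = 30L,
                            min_gap = 260L) {
  stopifnot(n_chrom >= 1L, chrom_len >= 2L * margin)
  if (is.numeric(planted))
    planted <- lapply(planted, function(l) list(insert_len = l, orientation = "A-first"))
  set.seed(seed)
  motifs <- vapply(enzymes, function(e) e$recognition, "")
  names(motifs) <- vapply(enzymes, function(e) e$name, "")
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))

  # round-robin assignment of plants to chromosomes
  assign_chrom <- if (length(planted))
    rep_len(seq_len(n_chrom), length(planted)) else integer(0)

  seqs <- character(n_chrom)
  truth <- vector("list", length(planted))
  for (ci in seq_len(n_chrom)) {
    idx <- which(assign_chrom == ci)
    cons <- lapply(idx, function(i) {
      p <- planted[[i]]
      stopifnot(p$insert_len >= 1L)
      ins <- .motif_free_dna(p$insert_len, gc, motifs)
      ord <- if (identical(p$orientation, "B-first")) c(2L, 1L) else c(1L, 2L)
      list(seq = paste0(motifs[ord[1]], ins, motifs[ord[2]]),
           insert_seq = ins, insert_len = p$insert_len,
           orientation = if (identical(p$orientation, "B-first")) "B-first" else "A-first",
           left_site = names(motifs)[ord[1]], right_site = names(motifs)[ord[2]],
           left_len = nchar(motifs[ord[1]]), right_len = nchar(motifs[ord[2]]))
    })
    base_gaps <- if (length(cons)) c(margin, rep(min_gap, max(0L, length(cons) - 1L)),
                                     margin) else margin
    need <- sum(vapply(cons, function(x) nchar(x$seq), 0)) + sum(base_gaps)
    if (need > chrom_len)
      stop("infeasible packing: chromosome ", chrom_names[ci], " needs ",
           need, " bp for ", length(cons), " plants but has ", chrom_len)
    # minimum gap sizes, plus leftover split uniformly at random
    gaps <- base_gaps
    extra <- chrom_len - need
    if (extra > 0 && length(gaps) > 0) {
      add <- tabulate(sample.int(length(gaps), extra, replace = TRUE),
                      nbins = length(gaps))
      gaps <- gaps + add
    }
    parts <- character(0)
    pos <- 0L
    for (j in seq_along(cons)) {
      bg <- .motif_free_dna(gaps[j], gc, motifs)
      parts <- c(parts, bg, cons[[j]]$seq)
      pos <- pos + nchar(bg)
      site_start <- pos
      ins_start <- pos + cons[[j]]$left_len
      truth[[idx[j]]] <- data.frame(
        chrom = chrom_names[ci],
        insert_start = ins_start,
        insert_end = ins_start + cons[[j]]$insert_len,
        orientation = cons[[j]]$orientation,
        insert_len = cons[[j]]$insert_len,
        insert_seq = cons[[j]]$insert_seq,
        left_site = cons[[j]]$left_site,
        right_site = cons[[j]]$right_site,
        stringsAsFactors = FALSE)
      pos <- pos + nchar(cons[[j]]$seq)
    }
    parts <- c(parts, .motif_free_dna(gaps[length(gaps)], gc, motifs))
    s <- paste(parts, collapse = "")
    # junctions between background and construct cannot create new motifs:
    # verify, and patch background windows if a boundary-spanning hit appears
    s <- .patch_junctions(s, motifs, truth[idx], gc)
    seqs[ci] <- s
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), insert_start = integer(0),
               insert_end = integer(0), orientation = character(0),
               insert_len = integer(0), insert_seq = character(0),
               left_site = character(0), right_site = character(0))
  truth <- truth[order(truth$chrom, truth$insert_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome(stats::setNames(seqs, chrom_names)), truth = truth)
}

# Remove motif occurrences that span a construct/background junction by
# re-randomizing the background bases they cover; planted site intervals are
# left untouched.
.patch_junctions <- function(s, motifs, truth_rows, gc, max_rounds = 50L) {
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  planted_iv <- if (!is.null(truth) && nrow(truth)) {
    site_len <- function(nm) nchar(motifs[nm])
    rbind(
      cbind(truth$insert_start - site_len(truth$left_site), truth$insert_start),
      cbind(truth$insert_end, truth$insert_end + site_len(truth$right_site)))
  } else matrix(numeric(0), ncol = 2)
  construct_iv <- if (!is.null(truth) && nrow(truth)) {
    cbind(truth$insert_start - nchar(motifs[truth$left_site]),
          truth$insert_end + nchar(motifs[truth$right_site]))
  } else matrix(numeric(0), ncol = 2)
  pats <- unique(c(motifs, revcomp(motifs)))
  for (round in seq_len(max_rounds)) {
    occ <- do.call(rbind, lapply(pats, function(p)
      if (length(h <- iupac_find_all(p, s))) cbind(h, h + nchar(p)) else NULL))
    expected <- planted_iv
    unexpected <- if (is.null(occ)) NULL else
      occ[!(occ[, 1] * 1e9 + occ[, 2]) %in%
            (expected[, 1] * 1e9 + expected[, 2]), , drop = FALSE]
    if (is.null(unexpected) || nrow(unexpected) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(unexpected))) {
      w <- (unexpected[i, 1] + 1):(unexpected[i, 2])  # 1-based positions
      # never touch bases inside a planted construct
      inside <- rep(FALSE, length(w))
      if (nrow(construct_iv))
        for (k in seq_len(nrow(construct_iv)))
          inside <- inside | (w > construct_iv[k, 1] & w <= construct_iv[k, 2])
      free <- w[!inside]
      if (!length(free))
        stop("motif occurrence entirely inside a planted construct; ",
             "insert generation failed")
      ch[free] <- strsplit(random_dna(length(free), gc), "")[[1]]
    }
    s <- paste(ch, collapse = "")
  }
  stop("could not remove junction-spanning motifs after ", max_rounds, " rounds")
}

#' Substitute bases at random to derive a mutated genome
#'
#' Used to emulate parents of a biparental cross: the reference plus a mutated
#' copy differ only by recorded SNPs. With `protect_sites = TRUE`, no
#' substitution lands inside any occurrence of the given recognition motifs,
#' so mining results are preserved.
#'
#' @param g an [genome()] object.
#' @param substitution_rate per-base substitution probability in [0, 0.1].
#' @param seed integer seed.
#' @param protect_sites if TRUE, mask recognition-site occurrences.
#' @param enzymes enzymes whose sites are protected (default PstI + MspI).
#' @return `list(genome =, variants =)`; `variants` has `chrom`, `pos`
#'   (0-based), `ref`, `alt`.
#' @export
mutate_genome <- function(g, substitution_rate, seed = 1L,
                          protect_sites = TRUE,
                          enzymes = list(PstI(), MspI())) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.1)
  set.seed(seed)
  motifs <- unique(unlist(lapply(enzymes, function(e)
    c(e$recognition, revcomp(e$recognition)))))
  out <- unclass(g)
  vars <- list()
  for (ci in seq_along(out)) {
    s <- out[ci]
    n <- nchar(s)
    mask <- rep(FALSE, n)
    if (protect_sites) {
      for (p in motifs) {
        h <- iupac_find_all(p, s)
        for (st in h) mask[(st + 1):(st + nchar(p))] <- TRUE
      }
    }
    ch <- strsplit(s, "")[[1]]
    mask <- mask | !(ch %in% c("A", "C", "G", "T"))
    hit <- which(stats::runif(n) < substitution_rate & !mask)
    if (length(hit)) {
      ref <- ch[hit]
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      ch[hit] <- alt
      out[ci] <- paste(ch, collapse = "")
      vars[[length(vars) + 1L]] <- data.frame(
        chrom = names(out)[ci], pos = hit - 1L, ref = ref, alt = alt,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  variants <- if (length(vars)) do.call(rbind, vars) else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  list(genome = genome(out), variants = variants)
}
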