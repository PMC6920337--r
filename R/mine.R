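#' Find all occurrences of a recognition motif in a genome
#'
#' Scans every chromosome for the enzyme's IUPAC recognition pattern and for
#' its reverse complement, merging the two hit lists so a palindromic site is
#' counted once per locus. Subject bases outside A/C/G/T (e.g. assembly-gap
#' `N`) never match.
#'
#' @param g an [genome()] object.
#' @param enzyme a [restriction_enzyme()].
#' @return named list (per chromosome) of sorted 0-based start positions.
#' @export
find_sites <- function(g, enzyme) {
  pats <- unique(c(enzyme$recognition, revcomp(enzyme$recognition)))
  lapply(stats::setNames(as.list(unclass(g)), names(g)), function(s) {
    sort(unique(unlist(lapply(pats, iupac_find_all, subject = s))))
  })
}

#' Mine restriction-delimited amplicon targets
#'
#' Finds every genomic segment that (1) is flanked by one site of each
#' enzyme, (2) has an insert length (sites excluded) within
#' `[min_len, max_len]`, and (3) contains no intervening occurrence of either
#' recognition motif; segments qualify in either orientation (A-site first or
#' B-site first on the forward strand). Opposite-type site occurrences whose
#' intervals overlap each other are not a valid flanking pair; they are
#' skipped and tallied in the `skipped_overlap` attribute.
#'
#' @param g an [genome()] object.
#' @param enzymeA,enzymeB two distinct [restriction_enzyme()] objects
#'   (default PstI and MspI).
#' @param min_len,max_len insert length bounds in bp, restriction sites
#'   excluded (defaults 60 and 250).
#' @return a data frame of class `mra_amplicons`, sorted by
#'   (chrom, insert_start), with columns `chrom`, `insert_start`,
#'   `insert_end` (0-based half-open, sites excluded), `orientation`
#'   (`"A-first"`/`"B-first"`), `insert_len`, `left_site`, `right_site`.
#'   Attributes: `enzymes`, `skipped_overlap`.
#' @examples
#' g <- genome(c(chr = paste0(strrep("A", 10), "CTGCAG", strrep("T", 70),
#'                            "CCGG", strrep("A", 10))))
#' find_amplicons(g)
#' @export
find_amplicons <- function(g, enzymeA = PstI(), enzymeB = MspI(),
                           min_len = 60L, max_len = 250L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  if (identical(enzymeA$recognition, enzymeB$recognition))
    stop("enzymes must be distinct")
  lenA <- nchar(enzymeA$recognition)
  lenB <- nchar(enzymeB$recognition)
  sitesA <- find_sites(g, enzymeA)
  sitesB <- find_sites(g, enzymeB)
  skipped <- 0L
  out <- vector("list", length(g))
  for (ci in seq_along(g)) {
    a <- sitesA[[ci]]; b <- sitesB[[ci]]
    if (!length(a) || !length(b)) next
    st <- c(a, b)
    en <- c(a + lenA, b + lenB)
    ty <- c(rep("A", length(a)), rep("B", length(b)))
    o <- order(st, en)
    st <- st[o]; en <- en[o]; ty <- ty[o]
    n <- length(st)
    rows <- list()
    for (i in seq_len(n - 1L)) {
      # right partner must start within max_len of this site's end
      jmax <- i
      while (jmax < n && st[jmax + 1L] <= en[i] + max_len) jmax <- jmax + 1L
      if (jmax == i) next
      for (j in (i + 1L):jmax) {
        if (ty[j] == ty[i]) next
        if (st[j] < en[i]) {            # overlapping opposite-type sites
          skipped <- skipped + 1L
          next
        }
        ins_start <- en[i]; ins_end <- st[j]
        len <- ins_end - ins_start
        if (len < min_len || len > max_len) next
        # criterion: no other site interval intersects the insert
        inter <- st < ins_end & en > ins_start
        inter[c(i, j)] <- FALSE
        if (any(inter)) next
        rows[[length(rows) + 1L]] <- c(ins_start, ins_end,
                                       if (ty[i] == "A") 1L else 2L)
      }
    }
    if (length(rows)) {
      m <- do.call(rbind, rows)
      out[[ci]] <- data.frame(
        chrom = names(g)[ci],
        insert_start = m[, 1], insert_end = m[, 2],
        orientation = ifelse(m[, 3] == 1L, "A-first", "B-first"),
        insert_len = m[, 2] - m[, 1],
        left_site = ifelse(m[, 3] == 1L, enzymeA$name, enzymeB$name),
        right_site = ifelse(m[, 3] == 1L, enzymeB$name, enzymeA$name),
        stringsAsFactors = FALSE)
    }
  }
  amp <- if (any(!vapply(out, is.null, TRUE)))
    do.call(rbind, out[!vapply(out, is.null, TRUE)]) else
    data.frame(chrom = character(0), insert_start = integer(0),
               insert_end = integer(0), orientation = character(0),
               insert_len = integer(0), left_site = character(0),
               right_site = character(0))
  amp <- amp[order(amp$chrom, amp$insert_start), , drop = FALSE]
  rownames(amp) <- NULL
  structure(amp, enzymes = list(A = enzymeA, B = enzymeB),
            skipped_overlap = skipped,
            class = c("mra_amplicons", "data.frame"))
}

#' Start-to-start spacing statistics of mined amplicons
#'
#' Distances are measured between insert starts of consecutive amplicons on
#' the same chromosome. Chromosomes with fewer than two amplicons have no
#' defined spacing and are reported with `NA` statistics.
#'
#' @param amplicons a [find_amplicons()] table.
#' @return data frame with one row per chromosome: `chrom`, `n`, `mean_gap`,
#'   `sd_gap`, `max_gap`.
#' @export
gap_stats <- function(amplicons) {
  sp <- split(amplicons$insert_start, amplicons$chrom)
  out <- lapply(names(sp), function(ch) {
    s <- sort(sp[[ch]])
    if (length(s) < 2L)
      return(data.frame(chrom = ch, n = length(s), mean_gap = NA_real_,
                        sd_gap = NA_real_, max_gap = NA_real_))
    d <- diff(s)
    data.frame(chrom = ch, n = length(s), mean_gap = mean(d),
               sd_gap = stats::sd(d), max_gap = max(d))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Amplicon (or marker) density per fixed-size bin
#'
#' Counts features per half-open bin `[i*bin_size, (i+1)*bin_size)` along
#' each chromosome, reporting empty bins as zero up to the chromosome end.
#' The bin counts always sum to the number of features (conservation).
#'
#' @param chrom,pos character/numeric vectors: feature chromosome and
#'   position (0-based bp).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 1e6, i.e. per-Mb density).
#' @return data frame `chrom`, `bin_start`, `bin_end`, `count`.
#' @export
density_track <- function(chrom, pos, chrom_lengths, bin_size = 1e6) {
  stopifnot(bin_size >= 1)
  bad <- !(chrom %in% names(chrom_lengths))
  if (any(bad)) stop("unknown chromosome: ", chrom[bad][1])
  over <- pos >= chrom_lengths[chrom] | pos < 0
  if (any(over))
    stop("position ", pos[over][1], " outside chromosome ", chrom[over][1])
  out <- lapply(names(chrom_lengths), function(ch) {
    nbin <- max(1L, ceiling(chrom_lengths[[ch]] / bin_size))
    p <- pos[chrom == ch]
    cnt <- tabulate(floor(p / bin_size) + 1L, nbins = nbin)
    data.frame(chrom = ch, bin_start = (seq_len(nbin) - 1) * bin_size,
               bin_end = pmin(seq_len(nbin) * bin_size, chrom_lengths[[ch]]),
               count = cnt)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @rdname density_track
#' @param amplicons a [find_amplicons()] table.
#' @param g the genome the amplicons were mined from.
#' @export
amplicon_density <- function(amplicons, g, bin_size = 1e6) {
  density_track(amplicons$chrom, amplicons$insert_start,
                seq_lengths(g), bin_size)
}

#' Insert-length spectrum with optional linear trend fit
#'
#' Tabulates one count per integer insert length over the observed (or given)
#' range, and optionally fits ordinary least squares of count against length
#' to quantify any bias towards shorter or longer amplicons.
#'
#' @param amplicons a [find_amplicons()] table.
#' @param fit if TRUE, regress count on length.
#' @param range integer length range to tabulate over; defaults to the
#'   observed min..max.
#' @return list with `spectrum` (data frame `insert_len`, `count`) and, when
#'   fitted, `slope`, `intercept`, `r_squared` (NA when the fit is
#'   degenerate, e.g. a single distinct length).
#' @export
length_spectrum <- function(amplicons, fit = TRUE, range = NULL) {
  len <- amplicons$insert_len
  if (is.null(range)) {
    if (!length(len)) stop("no amplicons and no explicit range")
    range <- c(min(len), max(len))
  }
  lens <- seq.int(range[1], range[2])
  cnt <- tabulate(len - range[1] + 1L, nbins = length(lens))
  spec <- data.frame(insert_len = lens, count = cnt)
  out <- list(spectrum = spec)
  if (fit) {
    if (length(unique(lens)) < 2L) {
      out$slope <- out$intercept <- out$r_squared <- NA_real_
    } else {
      m <- stats::lm(count ~ insert_len, data = spec)
      out$slope <- unname(stats::coef(m)[2])
      out$intercept <- unname(stats::coef(m)[1])
      # r2 as squared correlation; a flat spectrum has no explainable
      # variance and reports 0
      out$r_squared <- if (stats::sd(cnt) == 0) 0 else
        stats::cor(spec$insert_len, spec$count)^2
    }
  }
  out
}

#' Export mined amplicons as TSV or BED
#'
#' @param amplicons a [find_amplicons()] table.
#' @param path output file.
#' @export
write_amplicons <- function(amplicons, path) {
  utils::write.table(as.data.frame(amplicons), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplicons
#' @export
write_amplicons_bed <- function(amplicons, path) {
  bed <- data.frame(chrom = amplicons$chrom, start = amplicons$insert_start,
                    end = amplicons$insert_end,
                    name = sprintf("%s_%d", amplicons$chrom,
                                   amplicons$insert_start),
                    score = amplicons$insert_len,
                    strand = ifelse(amplicons$orientation == "A-first",
                                    "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
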