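#' Preprocessing configuration for MRASeq reads
#'
#' Describes the expected read layout (barcode + tail + spacer + full
#' recognition site + genomic insert) and how to rewrite it into the
#' GBS/TASSEL layout (barcode + remnant site + insert).
#'
#' @param barcodes character vector of sample barcodes (unique, non-empty).
#' @param tail tail sequence between barcode and spacer (default M13).
#' @param spacer spacer specification: an exact or IUPAC pattern of fixed
#'   length, or `NULL` to accept any spacer of `spacer_range` length whose
#'   next bases are the full recognition site.
#' @param spacer_range allowed spacer lengths when `spacer` is `NULL`
#'   (default 6--10).
#' @param site full recognition site expected after the spacer
#'   (default CTGCAG).
#' @param remnant remnant retained after the barcode in the output (default
#'   `"TGCAG"`, the TASSEL PstI convention; set to the full site to keep all
#'   six bases).
#' @param polya_n number of poly-A bases appended by [pad_polya()]
#'   (default 80).
#' @param polya_qual quality character for the padding (default `"!"`,
#'   Phred 0).
#' @param on_unmatched `"drop"` (default) or `"pass"` reads that do not match
#'   the expected layout.
#' @return a list of class `prep_config`.
#' @export
prep_config <- function(barcodes, tail = M13_TAIL, spacer = NULL,
                        spacer_range = c(6L, 10L), site = "CTGCAG",
                        remnant = "TGCAG", polya_n = 80L, polya_qual = "!",
                        on_unmatched = c("drop", "pass")) {
  barcodes <- toupper(barcodes)
  if (!length(barcodes) || any(!nzchar(barcodes)))
    stop("barcodes must be non-empty")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  site <- toupper(site)
  remnant <- toupper(remnant)
  if (!endsWith(site, remnant))
    stop("remnant must be a suffix of the recognition site")
  stopifnot(polya_n >= 0, nchar(polya_qual) == 1L)
  if (!is.null(spacer)) iupac_to_regex(spacer)
  structure(list(barcodes = barcodes, tail = toupper(tail), spacer = spacer,
                 spacer_range = as.integer(spacer_range), site = site,
                 remnant = remnant, polya_n = as.integer(polya_n),
                 polya_qual = polya_qual,
                 on_unmatched = match.arg(on_unmatched)),
            class = "prep_config")
}

#' Excise tail and spacer so reads start barcode + remnant site
#'
#' For every read beginning with a known barcode followed by
#' `tail + spacer + full recognition site`, rewrites it to
#' `barcode + remnant + rest-of-read`. The quality string is co-edited at the
#' same offsets (the remnant keeps the quality characters of the site bases
#' it derives from), so `nchar(bases) == nchar(quality)` always holds.
#' Barcode matching is exact, longest barcode first. Reads that do not match
#' the layout are dropped or passed through unchanged according to the
#' configuration; every input read is accounted for in the report.
#'
#' @param reads a [read_records()] frame.
#' @param config a [prep_config()].
#' @return `list(reads =, report =)`; the report is a data frame of
#'   per-disposition counts (`edited`, `already` for reads that are in
#'   barcode + remnant form on input, `passed`, `dropped`) by barcode
#'   (`"?"` for reads without a recognized barcode).
#' @export
strip_intervening <- function(reads, config) {
  reads <- read_records(reads$id, reads$bases, reads$quality)
  bcs <- config$barcodes[order(-nchar(config$barcodes))]
  site_len <- nchar(config$site)
  tail_len <- nchar(config$tail)
  rem_len <- nchar(config$remnant)
  # quality offset of the remnant inside the site
  rem_off <- site_len - rem_len

  n <- nrow(reads)
  barcode <- rep("?", n)
  new_bases <- reads$bases
  new_quals <- reads$quality
  disposition <- rep("unmatched", n)

  bases <- reads$bases
  for (b in bcs) {
    hit <- disposition == "unmatched" & barcode == "?" &
      startsWith(bases, b)
    barcode[hit] <- b
  }
  cand <- which(barcode != "?")
  for (i in cand) {
    b_len <- nchar(barcode[i])
    rest <- substring(bases[i], b_len + 1L)
    if (!startsWith(rest, config$tail)) next
    after_tail <- substring(rest, tail_len + 1L)
    sp_lens <- if (!is.null(config$spacer)) nchar(config$spacer) else
      seq.int(config$spacer_range[1], config$spacer_range[2])
    for (sl in sp_lens) {
      spacer <- substr(after_tail, 1L, sl)
      if (nchar(spacer) < sl) next
      if (!is.null(config$spacer) &&
          !grepl(paste0("^", iupac_to_regex(config$spacer), "$"), spacer))
        next
      if (substr(after_tail, sl + 1L, sl + site_len) != config$site) next
      # rewrite: barcode + remnant + remainder; qualities at same offsets
      cut_start <- b_len + tail_len + sl            # 0-based, after barcode
      q <- reads$quality[i]
      new_bases[i] <- paste0(barcode[i], config$remnant,
                             substring(bases[i],
                                       cut_start + site_len + 1L))
      new_quals[i] <- paste0(substr(q, 1L, b_len),
                             substr(q, cut_start + rem_off + 1L,
                                    cut_start + site_len),
                             substring(q, cut_start + site_len + 1L))
      disposition[i] <- "edited"
      break
    }
  }
  # reads already in barcode + remnant layout are conforming output; keeping
  # them makes the transform idempotent
  for (i in which(disposition == "unmatched" & barcode != "?")) {
    rest <- substring(bases[i], nchar(barcode[i]) + 1L)
    if (startsWith(rest, config$remnant)) disposition[i] <- "already"
  }
  unmatched <- disposition == "unmatched"
  if (config$on_unmatched == "drop") {
    disposition[unmatched] <- "dropped"
  } else {
    disposition[unmatched] <- "passed"
  }
  keep <- disposition != "dropped"
  out <- read_records(reads$id[keep], new_bases[keep], new_quals[keep])
  report <- as.data.frame(table(barcode = barcode,
                                disposition = disposition),
                          stringsAsFactors = FALSE)
  report <- report[report$Freq > 0, , drop = FALSE]
  names(report)[3] <- "count"
  rownames(report) <- NULL
  stopifnot(sum(report$count) == n)  # conservation: emitted + dropped == input
  list(reads = out, report = report)
}

#' Append poly-A padding to every read
#'
#' GBS-style SNP callers discard reads shorter than their k-mer window;
#' padding every read with `n` 3' A bases (quality `qual_char`) lets short
#' amplicon reads through. The base/quality length invariant is preserved.
#'
#' @param reads a [read_records()] frame.
#' @param n number of A bases (default 80).
#' @param qual_char quality character for the padding (default `"!"`).
#' @return the padded [read_records()] frame.
#' @export
pad_polya <- function(reads, n = 80L, qual_char = "!") {
  stopifnot(n >= 0, nchar(qual_char) == 1L)
  reads <- read_records(reads$id, reads$bases, reads$quality)
  if (n == 0L) return(reads)
  read_records(reads$id,
               paste0(reads$bases, strrep("A", n)),
               paste0(reads$quality, strrep(qual_char, n)))
}

#' Write a TASSEL-GBS-style barcode key file
#'
#' @param samples,barcodes equal-length character vectors.
#' @param path output TSV.
#' @param flowcell,lane constant columns for the key file.
#' @export
write_key_file <- function(samples, barcodes, path,
                           flowcell = "SIM", lane = 1L) {
  stopifnot(length(samples) == length(barcodes))
  utils::write.table(
    data.frame(Flowcell = flowcell, Lane = lane, Barcode = barcodes,
               FullSampleName = samples),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_key_file
#' @export
read_key_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
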