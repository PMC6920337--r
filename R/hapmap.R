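# Genotype-matrix import/export in the HapMap TSV dialect that TASSEL
# exports, plus a minimal VCF (GT-only) importer.

.HMP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
               "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

#' Read and write HapMap-format genotype tables
#'
#' The HapMap dialect stores one marker per row with eleven metadata columns
#' followed by one single-letter genotype column per sample: the allele
#' letter for homozygotes, the two-allele IUPAC code for heterozygotes and
#' `N` for missing. Positions are 1-based on file and converted to the
#' package's 0-based convention. Rows whose `alleles` field is not two
#' distinct single bases (multi-allelic or indel rows) are dropped and
#' tallied in the `dropped` attribute.
#'
#' @param path file path.
#' @return `read_hapmap`: a [genotype_matrix()] with attribute `dropped`.
#' @export
read_hapmap <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) <= length(.HMP_META)) stop("no sample columns in ", path)
  alleles <- strsplit(raw$alleles, "/", fixed = TRUE)
  ok <- vapply(alleles, function(a)
    length(a) == 2L && all(a %in% c("A", "C", "G", "T")) && a[1] != a[2],
    TRUE)
  dropped <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  alleles <- alleles[ok]
  smp <- as.matrix(raw[, -seq_along(.HMP_META), drop = FALSE])
  a1 <- vapply(alleles, `[`, "", 1)
  a2 <- vapply(alleles, `[`, "", 2)
  het <- mapply(function(x, y)
    .iupac_from_set[[paste(sort(c(x, y)), collapse = "")]], a1, a2)
  calls <- matrix(NA_character_, nrow(smp), ncol(smp),
                  dimnames = dimnames(smp))
  calls[smp == a1] <- "A"
  calls[smp == a2] <- "B"
  calls[smp == het] <- "H"
  markers <- data.frame(id = raw[["rs#"]], chrom = as.character(raw$chrom),
                        pos = raw$pos - 1, alleles = raw$alleles,
                        stringsAsFactors = FALSE)
  structure(genotype_matrix(calls, markers), dropped = dropped)
}

#' @rdname read_hapmap
#' @param geno a [genotype_matrix()].
#' @export
write_hapmap <- function(geno, path) {
  mk <- geno$markers
  al <- strsplit(mk$alleles, "/", fixed = TRUE)
  a1 <- vapply(al, `[`, "", 1)
  a2 <- vapply(al, `[`, "", 2)
  het <- mapply(function(x, y)
    .iupac_from_set[[paste(sort(c(x, y)), collapse = "")]], a1, a2)
  m <- geno$calls
  out <- matrix("N", nrow(m), ncol(m), dimnames = dimnames(m))
  for (code in c("A", "B", "H")) {
    idx <- which(m == code)
    src <- switch(code, A = a1, B = a2, H = het)
    out[idx] <- src[row(m)[idx]]
  }
  meta <- data.frame(mk$id, mk$alleles, mk$chrom, mk$pos + 1, "+",
                     "NA", "NA", "NA", "NA", "NA", "NA",
                     stringsAsFactors = FALSE)
  names(meta) <- .HMP_META
  tab <- cbind(meta, as.data.frame(out, stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Minimal VCF import (GT field only)
#'
#' Reads biallelic SNP rows from a VCF and converts the GT subfield to
#' A/B/H/NA calls (0 = REF = allele A, 1 = ALT = allele B). Rows with
#' multi-allelic ALT or non-SNP alleles are dropped and tallied. Requires the
#' `vcfR` package.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [genotype_matrix()] with attribute `dropped`.
#' @export
read_vcf_gt <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_gt requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ok <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  dropped <- sum(!ok)
  fix <- fix[ok, , drop = FALSE]
  gt <- gt[ok, , drop = FALSE]
  norm <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  calls[norm == "0/0"] <- "A"
  calls[norm == "1/1"] <- "B"
  calls[norm %in% c("0/1", "1/0")] <- "H"
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, "_", fix$POS), fix$ID)
  markers <- data.frame(id = id, chrom = fix$CHROM,
                        pos = as.numeric(fix$POS) - 1,
                        alleles = paste0(fix$REF, "/", fix$ALT),
                        stringsAsFactors = FALSE)
  structure(genotype_matrix(calls, markers), dropped = dropped)
}
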