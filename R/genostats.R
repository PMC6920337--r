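#' Genotype matrix (markers x samples)
#'
#' Calls are stored as a character matrix with values `"A"` (homozygous for
#' the first allele), `"B"` (homozygous for the second), `"H"`
#' (heterozygous) and `NA` (missing). Markers are biallelic after import
#' normalization.
#'
#' @param calls character matrix markers x samples with values
#'   A/B/H/NA; rownames are marker ids.
#' @param markers data frame with columns `id`, `chrom`, `pos` (0-based bp),
#'   `alleles` (e.g. `"A/G"`); row order matches `calls`.
#' @return a list of class `mra_geno`.
#' @export
genotype_matrix <- function(calls, markers) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c("A", "B", "H") | is.na(calls)))
    stop("calls must be A, B, H or NA")
  if (nrow(calls) != nrow(markers)) stop("markers/calls row mismatch")
  if (any(markers$pos < 0)) stop("negative marker position")
  rownames(calls) <- markers$id
  structure(list(calls = calls, markers = as.data.frame(markers)),
            class = "mra_geno")
}

#' @export
print.mra_geno <- function(x, ...) {
  cat("genotype matrix:", nrow(x$calls), "markers x", ncol(x$calls),
      "samples\n")
  invisible(x)
}

#' Per-marker call rate, minor allele frequency and heterozygosity
#'
#' Call rate is the fraction of samples with a non-missing call. Allele
#' counting over non-missing calls is standard biallelic: each homozygote
#' contributes two copies of its allele, each heterozygote one of each; MAF
#' is the smaller allele frequency. Heterozygosity is the fraction of
#' non-missing calls that are `H`. Markers with no calls get `NA` for MAF
#' and heterozygosity.
#'
#' @param geno a [genotype_matrix()].
#' @return data frame `id`, `call_rate`, `maf`, `het_rate`.
#' @export
marker_stats <- function(geno) {
  m <- geno$calls
  ns <- ncol(m)
  nA <- rowSums(m == "A", na.rm = TRUE)
  nB <- rowSums(m == "B", na.rm = TRUE)
  nH <- rowSums(m == "H", na.rm = TRUE)
  nonmiss <- nA + nB + nH
  a <- 2 * nA + nH
  b <- 2 * nB + nH
  maf <- ifelse(nonmiss > 0, pmin(a, b) / (a + b), NA_real_)
  het <- ifelse(nonmiss > 0, nH / nonmiss, NA_real_)
  data.frame(id = geno$markers$id, call_rate = nonmiss / ns,
             maf = maf, het_rate = het, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter markers on call rate, MAF and heterozygosity
#'
#' Keeps markers with `call_rate >= mcr_min`, `maf >= maf_min` and
#' `het_rate <= het_max` (the thresholds used downstream of GBS-style SNP
#' calling: MAF 0.2 for biparental or 0.05 for natural populations, at most
#' 10% heterozygous calls, and a minimum call rate of 20/50/80%). The report
#' attributes each removed marker to the first criterion it fails, in the
#' order MCR, MAF, heterozygosity; markers with undefined MAF/het (no calls)
#' fail MCR whenever `mcr_min > 0`.
#'
#' @param geno a [genotype_matrix()].
#' @param mcr_min minimum call rate in [0,1].
#' @param maf_min minimum minor allele frequency in [0,1].
#' @param het_max maximum heterozygous fraction in [0,1].
#' @return `list(geno =, report =)`; the report gives `kept` and per-criterion
#'   removal counts.
#' @export
filter_markers <- function(geno, mcr_min = 0.2, maf_min = 0.2,
                           het_max = 0.1) {
  stopifnot(mcr_min >= 0, mcr_min <= 1, maf_min >= 0, maf_min <= 1,
            het_max >= 0, het_max <= 1)
  st <- marker_stats(geno)
  fail_mcr <- st$call_rate < mcr_min
  fail_maf <- !fail_mcr & (is.na(st$maf) | st$maf < maf_min)
  fail_het <- !fail_mcr & !fail_maf &
    (is.na(st$het_rate) | st$het_rate > het_max)
  keep <- !(fail_mcr | fail_maf | fail_het)
  out <- genotype_matrix(geno$calls[keep, , drop = FALSE],
                         geno$markers[keep, , drop = FALSE])
  report <- data.frame(kept = sum(keep), removed_mcr = sum(fail_mcr),
                       removed_maf = sum(fail_maf),
                       removed_het = sum(fail_het))
  list(geno = out, report = report)
}

#' Marker density per physical bin
#'
#' Reuses the amplicon binning contract: per-bin marker counts over half-open
#' bins, empty bins reported, counts conserved.
#'
#' @param geno a [genotype_matrix()].
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 1e6).
#' @return a [density_track()] data frame.
#' @export
marker_density_map <- function(geno, chrom_lengths, bin_size = 1e6) {
  density_track(geno$markers$chrom, geno$markers$pos, chrom_lengths,
                bin_size)
}

#' Simulate a biparental RIL genotype matrix
#'
#' Stands in for a recombinant-inbred-line population: per marker, calls are
#' heterozygous with probability `het_rate` (residual heterozygosity of an
#' advanced selfing generation), otherwise split between the two parental
#' homozygotes so the expected minor allele frequency matches a draw from
#' `maf_sampler`; calls are then masked missing at `missing_rate`. Linkage
#' is not modeled — markers are independent.
#'
#' @param n_markers,n_samples matrix dimensions.
#' @param missing_rate per-call missing probability in [0,1).
#' @param het_rate per-call heterozygosity in [0,1).
#' @param maf_sampler function(n) returning target MAFs (default: uniform on
#'   [0.2, 0.5], typical of segregating biparental markers).
#' @param seed integer seed.
#' @param chrom_lengths named chromosome lengths used to place markers
#'   uniformly (default one 100-Mb chromosome).
#' @return a [genotype_matrix()].
#' @export
simulate_ril_matrix <- function(n_markers, n_samples, missing_rate = 0.2,
                                het_rate = 0.03,
                                maf_sampler = function(n) stats::runif(n, 0.2, 0.5),
                                seed = 1L,
                                chrom_lengths = c(chr1 = 1e8)) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            het_rate >= 0, het_rate < 1)
  set.seed(seed)
  maf <- maf_sampler(n_markers)
  # P(B hom) chosen so allele-B frequency hits the target MAF given het_rate
  pB <- pmin(pmax((maf - het_rate / 2) / (1 - het_rate), 0), 1)
  calls <- matrix(NA_character_, n_markers, n_samples)
  for (i in seq_len(n_markers)) {
    u <- stats::runif(n_samples)
    g <- ifelse(u < het_rate, "H",
                ifelse(u < het_rate + (1 - het_rate) * pB[i], "B", "A"))
    g[stats::runif(n_samples) < missing_rate] <- NA
    calls[i, ] <- g
  }
  chrom <- sample(names(chrom_lengths), n_markers, replace = TRUE)
  pos <- floor(stats::runif(n_markers) * chrom_lengths[chrom])
  markers <- data.frame(id = sprintf("M%05d", seq_len(n_markers)),
                        chrom = chrom, pos = as.numeric(pos),
                        alleles = "A/B", stringsAsFactors = FALSE)
  o <- order(markers$chrom, markers$pos)
  genotype_matrix(calls[o, , drop = FALSE], markers[o, , drop = FALSE])
}
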