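#' Simulate a barcoded MRASeq sequencing library
#'
#' For each sample genome, predicts the amplicons its primer set amplifies,
#' then emits reads with the two-step-PCR product structure:
#' `barcode + M13 tail + A-spacer + CTGCAG + insert + CCGG +
#' rev-comp(B-spacer) + rev-comp(trP1B)`, where the spacers are the concrete
#' genomic flank bases the primers annealed to, and the insert is presented
#' A-site-first (reverse-complemented for B-first loci). Per-amplicon read
#' counts follow a negative-binomial depth model, read lengths a truncated
#' normal, and sequencing noise is substitution-only.
#'
#' @param genomes_by_sample named list of [genome()] objects, one per sample.
#' @param primer_set a [primer_pool()] or [degenerate_pair()].
#' @param barcodes_by_sample named character vector sample -> barcode
#'   (unique, 10--12 nt); every sample must have one.
#' @param depth_mean mean reads per predicted amplicon per sample.
#' @param depth_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); `0` gives a fixed depth of `depth_mean`.
#' @param read_len_mean,read_len_sd,read_len_min truncated-normal read-length
#'   model; reads are clipped to the construct length, never padded.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed; output is byte-deterministic given the seed.
#' @param insert_range,enzymeA,enzymeB,tm_anchors,params passed to
#'   [predict_amplicons()].
#' @param base_qual,error_qual quality characters for correct/error bases.
#' @return `list(reads =, truth =)`: `reads` is a [read_records()] frame;
#'   `truth` maps each read id to its sample and source amplicon.
#' @export
simulate_library <- function(genomes_by_sample, primer_set,
                             barcodes_by_sample,
                             depth_mean = 5, depth_dispersion = 0.3,
                             read_len_mean = 200, read_len_sd = 40,
                             read_len_min = 25,
                             error_rate = 0.002, seed = 1L,
                             insert_range = c(77L, 202L),
                             enzymeA = PstI(), enzymeB = MspI(),
                             tm_anchors = NULL, params = thermo_params(),
                             base_qual = "I", error_qual = "#") {
  samples <- names(genomes_by_sample)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("genomes_by_sample must be a named list")
  miss <- setdiff(samples, names(barcodes_by_sample))
  if (length(miss)) stop("no barcode for sample: ", miss[1])
  bc <- toupper(barcodes_by_sample[samples])
  if (anyDuplicated(bc)) stop("barcodes must be unique")
  if (any(nchar(bc) < 10 | nchar(bc) > 12)) stop("barcodes must be 10-12 nt")
  set.seed(seed)
  site_a_len <- nchar(enzymeA$recognition)
  all_reads <- list(); all_truth <- list()
  for (si in seq_along(samples)) {
    g <- genomes_by_sample[[si]]
    pred <- predict_amplicons(g, primer_set, insert_range,
                              enzymeA, enzymeB, tm_anchors, params)
    if (!nrow(pred)) next
    depth <- if (depth_dispersion == 0) rep(round(depth_mean), nrow(pred))
      else stats::rnbinom(nrow(pred), mu = depth_mean,
                          size = 1 / depth_dispersion)
    keep <- depth > 0
    if (!any(keep)) next
    seqs <- unclass(g)[pred$chrom]
    insert <- substring(seqs, pred$insert_start + 1L, pred$insert_end)
    bfirst <- pred$orientation == "B-first"
    insert[bfirst] <- revcomp(insert[bfirst])
    spacer_a <- substr(pred$a_primer, 1L, primer_set$kA - site_a_len)
    # rev-comp of the B primer: site + genomic continuation past the site
    after_b <- revcomp(pred$b_primer)
    construct <- paste0(bc[si], M13_TAIL, spacer_a, enzymeA$recognition,
                        insert, after_b, revcomp(TRP1B))
    for (ai in which(keep)) {
      n_reads <- depth[ai]
      lens <- pmax(read_len_min,
                   round(stats::rnorm(n_reads, read_len_mean, read_len_sd)))
      lens <- pmin(lens, nchar(construct[ai]))
      ids <- sprintf("%s_%s_%d_r%d", samples[si], pred$chrom[ai],
                     pred$insert_start[ai], seq_len(n_reads))
      bases <- substring(construct[ai], 1L, lens)
      quals <- strrep(base_qual, lens)
      if (error_rate > 0) {
        for (ri in seq_len(n_reads)) {
          ch <- strsplit(bases[ri], "")[[1]]
          hit <- which(stats::runif(length(ch)) < error_rate)
          if (length(hit)) {
            ch[hit] <- vapply(ch[hit], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
            bases[ri] <- paste(ch, collapse = "")
            q <- strsplit(quals[ri], "")[[1]]
            q[hit] <- error_qual
            quals[ri] <- paste(q, collapse = "")
          }
        }
      }
      all_reads[[length(all_reads) + 1L]] <-
        read_records(ids, bases, quals)
      all_truth[[length(all_truth) + 1L]] <- data.frame(
        read_id = ids, sample = samples[si], chrom = pred$chrom[ai],
        insert_start = pred$insert_start[ai],
        insert_end = pred$insert_end[ai],
        orientation = pred$orientation[ai], stringsAsFactors = FALSE)
    }
  }
  reads <- if (length(all_reads)) do.call(rbind, all_reads) else
    read_records(character(0), character(0), character(0))
  truth <- if (length(all_truth)) do.call(rbind, all_truth) else
    data.frame(read_id = character(0), sample = character(0),
               chrom = character(0), insert_start = integer(0),
               insert_end = integer(0), orientation = character(0))
  rownames(reads) <- rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}
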