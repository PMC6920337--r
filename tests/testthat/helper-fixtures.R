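# Hand-laid-out toy genomes with known amplicon content.

TOY1 <- genome(c(chr = paste0(strrep("A", 10), "CTGCAG", strrep("T", 70),
                              "CCGG", strrep("A", 10))))
TOY2 <- genome(c(chr = paste0(strrep("T", 4), "CCGG", strrep("A", 65),
                              "CTGCAG", "TT")))
TOY3 <- genome(c(chr = paste0(strrep("A", 4), "CTGCAG", strrep("T", 30),
                              "CCGG", strrep("T", 30), "CCGG")))

# 6-marker, 10-sample matrix: m1/m2 pass (MCR .8, MAF .2, het .1);
# m3, m4 fail call rate; m5 fails MAF; m6 fails heterozygosity
filter_fixture <- function() {
  calls <- rbind(
    m1 = c("A","A","A","A","A","B","B","B","B","H"),
    m2 = c("A","A","A","A","B","B","B","B",NA, NA),
    m3 = c("A","A","A","B","B","B","H",NA, NA, NA),
    m4 = c("A","A","B","B","B",NA, NA, NA, NA, NA),
    m5 = c("A","A","A","A","A","A","A","A","A","B"),
    m6 = c("A","A","A","A","B","B","B","B","H","H"))
  markers <- data.frame(id = rownames(calls), chrom = "chr1",
                        pos = seq(0, by = 1000, length.out = 6),
                        alleles = "A/G", stringsAsFactors = FALSE)
  genotype_matrix(calls, markers)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

sim_barcodes <- function(samples) {
  pool <- c("CTAAGGTAAC", "TAAGGAGAAC", "AAGAGGATTC", "TACCAAGATC",
            "CAGAAGGAAC", "CTGCAAGTTC", "TTCGTGATTC", "TTCCGATAAC")
  stats::setNames(pool[seq_along(samples)], samples)
}
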