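test_that("marker statistics follow standard biallelic accounting", {
  gm <- filter_fixture()
  st <- marker_stats(gm)
  expect_equal(st$call_rate[st$id == "m2"], 0.8)
  # 4 homA + 4 homB + 2 het over 10: 10 A and 10 B alleles
  calls <- rbind(mx = c(rep("A", 4), rep("B", 4), "H", "H"))
  g1 <- genotype_matrix(calls, data.frame(id = "mx", chrom = "c", pos = 0,
                                          alleles = "A/G"))
  s1 <- marker_stats(g1)
  expect_equal(s1$maf, 0.5)
  expect_equal(s1$het_rate, 0.2)

  allhet <- genotype_matrix(rbind(m = rep("H", 10)),
                            data.frame(id = "m", chrom = "c", pos = 0,
                                       alleles = "A/G"))
  expect_equal(marker_stats(allhet)$maf, 0.5)
  expect_equal(marker_stats(allhet)$het_rate, 1.0)

  allmiss <- genotype_matrix(rbind(m = rep(NA_character_, 10)),
                             data.frame(id = "m", chrom = "c", pos = 0,
                                        alleles = "A/G"))
  sm <- marker_stats(allmiss)
  expect_equal(sm$call_rate, 0)
  expect_true(is.na(sm$maf) && is.na(sm$het_rate))
})

test_that("marker stats equal a naive per-marker recount", {
  gm <- simulate_ril_matrix(200, 40, missing_rate = 0.25, het_rate = 0.05,
                            seed = 7)
  st <- marker_stats(gm)
  for (i in sample(200, 20)) {
    calls <- gm$calls[i, ]
    nm <- sum(!is.na(calls))
    a <- 2 * sum(calls == "A", na.rm = TRUE) + sum(calls == "H", na.rm = TRUE)
    b <- 2 * sum(calls == "B", na.rm = TRUE) + sum(calls == "H", na.rm = TRUE)
    expect_equal(st$call_rate[i], nm / 40)
    if (nm > 0) {
      expect_equal(st$maf[i], min(a, b) / (a + b))
      expect_equal(st$het_rate[i], sum(calls == "H", na.rm = TRUE) / nm)
    }
  }
})

test_that("the hand-built matrix filters to exactly two markers", {
  res <- filter_markers(filter_fixture(), mcr_min = 0.8, maf_min = 0.2,
                        het_max = 0.1)
  expect_equal(res$report$kept, 2L)
  expect_equal(res$report$removed_mcr, 2L)
  expect_equal(res$report$removed_maf, 1L)
  expect_equal(res$report$removed_het, 1L)
  expect_equal(rownames(res$geno$calls), c("m1", "m2"))

  ident <- filter_markers(filter_fixture(), 0, 0, 1)
  expect_equal(nrow(ident$geno$calls), 6L)
})

test_that("filtering is monotone in every threshold", {
  gm <- simulate_ril_matrix(300, 30, missing_rate = 0.3, het_rate = 0.1,
                            seed = 17)
  kept <- function(mcr, maf, het)
    filter_markers(gm, mcr, maf, het)$report$kept
  for (mcr in c(0, 0.2, 0.5, 0.8, 1)) {
    k <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(m) kept(m, 0.2, 0.1), 0)
    expect_true(all(diff(k) <= 0))
  }
  expect_true(all(diff(vapply(c(0, 0.1, 0.3, 0.5),
                              function(m) kept(0.2, m, 0.1), 0)) <= 0))
  expect_true(all(diff(vapply(c(0, 0.05, 0.2, 1),
                              function(h) kept(0.2, 0.2, h), 0)) >= 0))
})

test_that("marker density reuses the binning contract and conserves", {
  gm <- genotype_matrix(
    rbind(a = "A", b = "B", c = "H", d = "A"),
    data.frame(id = c("a", "b", "c", "d"), chrom = "c1",
               pos = c(1e5, 5e5, 9e5, 2.5e6), alleles = "A/G"))
  dt <- marker_density_map(gm, c(c1 = 3e6))
  expect_equal(dt$count, c(3, 0, 1))

  empty <- genotype_matrix(matrix(character(0), 0, 0),
                           data.frame(id = character(0), chrom = character(0),
                                      pos = numeric(0), alleles = character(0)))
  expect_equal(sum(marker_density_map(empty, c(c1 = 3e6))$count), 0)

  expect_error(marker_density_map(
    genotype_matrix(rbind(a = "A"),
                    data.frame(id = "a", chrom = "c1", pos = 5e6,
                               alleles = "A/G")), c(c1 = 3e6)), "outside")
})

test_that("the RIL simulator hits its target rates and is reproducible", {
  g0 <- simulate_ril_matrix(100, 20, missing_rate = 0, het_rate = 0, seed = 3)
  expect_true(all(marker_stats(g0)$call_rate == 1))

  gh <- simulate_ril_matrix(50, 10000, missing_rate = 0.1, het_rate = 0.06,
                            seed = 5)
  expect_lt(abs(mean(marker_stats(gh)$het_rate) - 0.06), 0.005)

  a <- simulate_ril_matrix(50, 30, seed = 11)
  b <- simulate_ril_matrix(50, 30, seed = 11)
  expect_identical(a, b)
})

test_that("HapMap round trip preserves calls and positions", {
  gm <- simulate_ril_matrix(40, 12, missing_rate = 0.2, het_rate = 0.1,
                            seed = 23,
                            maf_sampler = function(n) runif(n, 0.25, 0.5))
  gm$markers$alleles <- rep(c("A/G", "C/T", "A/C", "G/T"), 10)
  colnames(gm$calls) <- sprintf("S%02d", 1:12)
  f <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap(gm, f)
  back <- read_hapmap(f)
  expect_equal(back$calls, gm$calls)
  expect_equal(back$markers$pos, gm$markers$pos)
  expect_equal(attr(back, "dropped"), 0L)
})

test_that("the minimal VCF reader extracts GT calls", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t101\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "chr1\t201\tsnp2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|0\t1/1",
    "chr1\t301\tsnp3\tC\tCT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0"), f)
  gm <- read_vcf_gt(f)
  expect_equal(attr(gm, "dropped"), 1L)  # the indel row
  expect_equal(unname(gm$calls["snp1", ]), c("A", "B", "H"))
  expect_equal(unname(gm$calls["snp2", ]), c(NA, "A", "B"))
  expect_equal(gm$markers$pos, c(100, 200))
})
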