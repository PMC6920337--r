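test_that("tail and spacer are excised to barcode + remnant, qualities co-edited", {
  bc <- "CTAAGGTAAC"
  insert <- strrep("GATC", 20)
  raw_bases <- paste0(bc, M13_TAIL, "AAAAAA", "CTGCAG", insert)
  raw_qual <- paste(rep(c("I", "5"), length.out = nchar(raw_bases)),
                    collapse = "")
  reads <- read_records("r1", raw_bases, raw_qual)
  cfg <- prep_config(barcodes = bc, spacer = "AAAAAA")
  out <- strip_intervening(reads, cfg)

  expect_equal(out$reads$bases, paste0(bc, "TGCAG", insert))
  # removed tail(21) + spacer(6) + site(6), reinserted 5-nt remnant: net -28
  expect_equal(nchar(out$reads$bases), nchar(raw_bases) - 28L)
  expect_equal(nchar(out$reads$quality), nchar(out$reads$bases))
  # the remnant keeps the quality of the site bases it derives from
  site_at <- nchar(bc) + 21 + 6   # 0-based offset of CTGCAG in the raw read
  expect_equal(substr(out$reads$quality, nchar(bc) + 1, nchar(bc) + 5),
               substr(raw_qual, site_at + 2, site_at + 6))
  expect_equal(substring(out$reads$quality, nchar(bc) + 6),
               substring(raw_qual, site_at + 7))
})

test_that("unmatched reads are dropped (or passed) and accounted for", {
  bc <- "CTAAGGTAAC"
  good <- paste0(bc, M13_TAIL, "ACGTAC", "CTGCAG", strrep("A", 30))
  nobc <- paste0("GGGGGGGGGG", M13_TAIL, "ACGTAC", "CTGCAG", strrep("A", 30))
  notail <- paste0(bc, strrep("T", 40))
  reads <- read_records(c("g", "n", "t"), c(good, nobc, notail),
                        strrep("I", nchar(c(good, nobc, notail))))
  cfg <- prep_config(barcodes = bc)
  out <- strip_intervening(reads, cfg)
  expect_equal(out$reads$id, "g")
  expect_equal(sum(out$report$count), 3L)  # emitted + dropped == input
  expect_equal(sum(out$report$count[out$report$disposition == "dropped"]), 2L)

  cfg_pass <- prep_config(barcodes = bc, on_unmatched = "pass")
  out2 <- strip_intervening(reads, cfg_pass)
  expect_equal(nrow(out2$reads), 3L)
  expect_equal(out2$reads$bases[out2$reads$id == "n"], nobc)
})

test_that("a degenerate spacer pattern matches what an exact spacer does", {
  gen <- generate_genome(1, 6000, planted = c(100, 120), seed = 81)
  pool <- primer_pool(data.frame(
    a_primer = vapply(seq_len(2), function(i) {
      amp <- find_amplicons(gen$genome, min_len = 77, max_len = 202)
      extract_primer_pair(gen$genome, amp[i, ], 12, 12)$A$sequence
    }, ""),
    b_primer = vapply(seq_len(2), function(i) {
      amp <- find_amplicons(gen$genome, min_len = 77, max_len = 202)
      extract_primer_pair(gen$genome, amp[i, ], 12, 12)$B$sequence
    }, "")))
  bc <- sim_barcodes("s1")
  lib <- simulate_library(list(s1 = gen$genome), pool, bc, depth_mean = 2,
                          depth_dispersion = 0, error_rate = 0, seed = 5,
                          insert_range = c(77, 202))
  cfg_n <- prep_config(barcodes = bc, spacer = "NNNNNN")
  cfg_free <- prep_config(barcodes = bc, spacer = NULL,
                          spacer_range = c(6, 10))
  out_n <- strip_intervening(lib$reads, cfg_n)
  out_free <- strip_intervening(lib$reads, cfg_free)
  expect_identical(out_n$reads, out_free$reads)
  expect_equal(nrow(out_n$reads), nrow(lib$reads))
})

test_that("poly-A padding extends bases and qualities together", {
  reads <- read_records(c("a", "b"), c(strrep("G", 40), strrep("C", 10)),
                        c(strrep("I", 40), strrep("I", 10)))
  out <- pad_polya(reads, 80)
  expect_equal(nchar(out$bases), c(120, 90))
  expect_true(all(endsWith(out$bases, strrep("A", 80))))
  expect_true(all(endsWith(out$quality, strrep("!", 80))))
  expect_equal(nchar(out$bases), nchar(out$quality))
  expect_identical(pad_polya(reads, 0), reads)
})

test_that("stripping is idempotent and conserves reads end to end", {
  gen <- generate_genome(2, 8000, planted = c(90, 110, 130, 150), seed = 91)
  ds <- degenerate_pair(paste0(strrep("N", 6), "CTGCAG"),
                        paste0(strrep("N", 8), "CCGG"))
  bc <- sim_barcodes(c("s1", "s2"))
  mut <- mutate_genome(gen$genome, 0.005, seed = 92)
  lib <- simulate_library(list(s1 = gen$genome, s2 = mut$genome), ds, bc,
                          depth_mean = 3, depth_dispersion = 0,
                          read_len_mean = 400, read_len_sd = 0,
                          error_rate = 0, seed = 93,
                          insert_range = c(77, 202))
  cfg <- prep_config(barcodes = unname(bc))
  once <- strip_intervening(lib$reads, cfg)
  expect_equal(nrow(once$reads), nrow(lib$reads))  # zero drops
  ok <- vapply(seq_len(nrow(once$reads)), function(i) {
    b <- bc[startsWith(once$reads$bases[i], bc)]
    length(b) == 1 &&
      startsWith(substring(once$reads$bases[i], nchar(b) + 1), "TGCAG")
  }, TRUE)
  expect_true(all(ok))  # every read begins barcode + remnant

  twice <- strip_intervening(once$reads, cfg)
  expect_identical(twice$reads, once$reads)
})
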