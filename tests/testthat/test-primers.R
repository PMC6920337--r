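test_that("primer pairs are extracted anchored on the restriction sites", {
  amp <- find_amplicons(TOY1)
  pp <- extract_primer_pair(TOY1, amp[1, ], 12, 12)
  expect_equal(pp$A$sequence, "AAAAAACTGCAG")
  expect_equal(pp$B$sequence, "TTTTTTTTCCGG")
  expect_true(endsWith(pp$A$sequence, "CTGCAG"))
  expect_true(endsWith(pp$B$sequence, "CCGG"))

  # B-first amplicons mirror through the reverse complement
  g2 <- genome(c(chr = paste0(strrep("T", 12), "CCGG", strrep("A", 65),
                              "CTGCAG", strrep("T", 12))))
  amp2 <- find_amplicons(g2)
  expect_equal(amp2$orientation, "B-first")
  pp2 <- extract_primer_pair(g2, amp2[1, ], 12, 12)
  expect_equal(pp2$A$sequence, "AAAAAACTGCAG")   # read on the reverse strand
  expect_equal(pp2$B$sequence, "TTTTTTTTCCGG")
})

test_that("flanks off the contig or containing N yield no primer pair", {
  g <- genome(c(chr = paste0("AAAA", "CTGCAG", strrep("T", 70), "CCGG",
                             strrep("A", 10))))
  amp <- find_amplicons(g)
  expect_null(extract_primer_pair(g, amp[1, ], 12, 12))

  gn <- genome(c(chr = paste0("AANAAA", "CTGCAG", strrep("T", 70), "CCGG",
                              strrep("A", 10))))
  ampn <- find_amplicons(gn)
  expect_null(extract_primer_pair(gn, ampn[1, ], 12, 12))
})

test_that("the Tm threshold interpolates between the 12- and 16-mer anchors", {
  expect_equal(tm_threshold(12), 38)
  expect_equal(tm_threshold(16), 50)
  expect_equal(tm_threshold(14), 44)
  expect_equal(tm_threshold(18), 50)
})

test_that("pair counting conserves amplicons and honors the screens", {
  # three plants sharing identical 12-nt flank contexts
  flank_a <- "GGCGGC"          # strong GC flank so Tm passes
  flank_b <- "CCGCCGCC"
  seg <- function(ins) paste0(flank_a, "CTGCAG", ins, "CCGG",
                              revcomp(flank_b))
  n_hits <- function(s, p) length(gregexpr(paste0("(?=", p, ")"), s,
                                           perl = TRUE)[[1]][
                                             gregexpr(paste0("(?=", p, ")"),
                                                      s, perl = TRUE)[[1]] > 0])
  mk <- function(ins_len, seed) {
    set.seed(seed)
    repeat {  # insert whose whole segment has exactly one site of each type
      core <- rand_seq(ins_len)
      s <- seg(core)
      if (n_hits(s, "CTGCAG") == 1L && n_hits(s, "CCGG") == 1L) return(core)
    }
  }
  spacer <- strrep("T", 40)
  g <- genome(c(chr = paste0(spacer, seg(mk(100, 1)), spacer,
                             seg(mk(100, 2)), spacer, seg(mk(100, 3)),
                             spacer)))
  pc <- count_primer_pairs(g, 12, 12)
  expect_equal(attr(pc, "total_amplicons"), 3L)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$count, 3L)
  expect_equal(pc$a_primer, paste0(flank_a, "CTGCAG"))
  expect_equal(pc$b_primer, paste0(flank_b, "CCGG"))

  # insert below the 77-bp counting window is mined at (60,250) but excluded
  g2 <- genome(c(chr = paste0(spacer, seg(mk(60, 4)), spacer)))
  expect_equal(nrow(find_amplicons(g2)), 1L)
  expect_equal(attr(count_primer_pairs(g2, 12, 12), "total_amplicons"), 0L)

  # AT-only flank fails the 16-mer 50 degC screen
  g3 <- genome(c(chr = paste0(strrep("T", 30), "ATATATATAT", "CTGCAG",
                              mk(100, 5), "CCGG", revcomp(flank_b),
                              strrep("T", 30))))
  pc3 <- count_primer_pairs(g3, 16, 12)
  expect_equal(attr(pc3, "total_amplicons"), 0L)
  expect_lt(nn_tm(paste0("ATATATATAT", "CTGCAG")), 50)
  pc3_off <- count_primer_pairs(g3, 16, 12, tm_anchors = NULL)
  expect_equal(attr(pc3_off, "total_amplicons"), 1L)
})

test_that("pair counts conserve on random genomes and rank deterministically", {
  for (seed in c(3, 17)) {
    g <- random_genome(60000, seed = seed)
    amp <- find_amplicons(g, min_len = 77, max_len = 202)
    pc <- count_primer_pairs(g, 12, 12)
    expect_equal(sum(pc$count), attr(pc, "total_amplicons"))
    expect_true(all(diff(pc$count) <= 0))
    pc2 <- count_primer_pairs(g, 12, 12)
    expect_identical(as.data.frame(pc), as.data.frame(pc2))
    # qualifying amplicons can never exceed the mined set
    expect_lte(attr(pc, "total_amplicons"), nrow(amp))
  }
})

test_that("top_pairs reports cumulative shares against all amplicons", {
  pc <- structure(
    data.frame(a_primer = c("AAAAAACTGCAG", "CCCCCCCTGCAG", "GGGGGGCTGCAG"),
               b_primer = rep("TTTTTTTTCCGG", 3),
               count = c(10L, 5L, 5L), rank = 1:3,
               cum_count = c(10L, 15L, 20L),
               cum_share = c(0.5, 0.75, 1.0)),
    total_amplicons = 20L, class = c("mra_paircounts", "data.frame"))
  expect_equal(top_pairs(pc, 1)$cum_share, 0.5)
  expect_equal(utils::tail(top_pairs(pc, 3)$cum_share, 1), 1.0)
  expect_equal(nrow(top_pairs(pc, 99)), 3L)

  # sort-and-sum oracle on a random table
  set.seed(9)
  g <- random_genome(60000, seed = 55)
  pcr <- count_primer_pairs(g, 12, 12)
  if (nrow(pcr) >= 3) {
    n <- 3
    oracle_cum <- sum(sort(pcr$count, decreasing = TRUE)[1:n])
    expect_equal(top_pairs(pcr, n)$cum_count[n], oracle_cum)
    expect_equal(top_pairs(pcr, n)$cum_share[n],
                 oracle_cum / sum(pcr$count))
  }
})
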