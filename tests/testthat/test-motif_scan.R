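test_that("TRANSFAC parsing recovers consensus and applies the pseudocount rule", {
  txt <- paste(
    "AC  M00001", "XX", "ID  V$TEST_01", "XX",
    "P0      A      C      G      T",
    "01      8      0      0      0",
    "02      0      8      0      0",
    "03      8      0      0      0",
    "04      0      0      8      0",
    "05      0      0      0      8",
    "06      0      0      8      0",
    "//", sep = "\n")
  mats <- parse_transfac(txt, pseudocount = 0)
  expect_length(mats, 1)
  expect_equal(mats[[1]]$id, "M00001-V$TEST_01")
  expect_equal(consensus(mats[[1]]), "ACAGTG")

  # pseudocount 0.01 distributed by uniform background 0.25 each
  mats2 <- parse_transfac(txt, pseudocount = 0.01, bg = rep(0.25, 4))
  expect_equal(unname(mats2[[1]]$freqs[1, "A"]), (8 + 0.0025) / 8.01)
  expect_equal(unname(rowSums(mats2[[1]]$freqs)), rep(1, 6))

  expect_equal(parse_transfac(""), list())
  ragged <- sub("02      0      8      0      0", "02      0      8", txt)
  expect_error(parse_transfac(ragged), "line 7")
})

test_that("JASPAR PFM parsing handles bracketed rows and rejects ragged blocks", {
  txt <- paste(
    ">MA0001.1 TEST",
    "A  [ 4 19  0  0 ]",
    "C  [16  0 20  0 ]",
    "G  [ 0  1  0 20 ]",
    "T  [ 0  0  0  0 ]", sep = "\n")
  mats <- parse_jaspar_pfm(txt, pseudocount = 0)
  expect_length(mats, 1)
  expect_equal(mats[[1]]$width, 4)
  expect_equal(consensus(mats[[1]]), "CACG")

  ragged <- paste(">M1", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]",
                  "T [ 1 2 ]", sep = "\n")
  expect_error(parse_jaspar_pfm(ragged), "ragged")
})

test_that("consensus scanning finds exactly the canonical E-box matches", {
  # printed example sites: one with the canonical E-box, one with only the
  # non-canonical CACATG variant
  p <- make_promoters(c(eif4b = "TAATCACGTGATTG", fads2 = "CACCACATGGGA"))
  hits <- scan_consensus(p, "CACGTG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gene_id, "eif4b")
  expect_equal(hits$offset, 4)
  expect_equal(hits$site_seq, "CACGTG")

  # palindrome: forward-only and both-strand scans agree
  fwd <- scan_consensus(p, "CACGTG", strands = "forward")
  expect_equal(fwd$offset, hits$offset)

  # IUPAC expansion and N exclusion
  iupac <- scan_consensus(make_promoters(c(x = "GGCACATGGG")), "CANNTG")
  expect_equal(iupac$offset, 2)
  expect_equal(nrow(scan_consensus(make_promoters(c(x = "GGCACNTGGG")),
                                   "CANNTG")), 0)
  expect_error(scan_consensus(p, "CACGTZ"), "IUPAC")

  # non-palindromic pattern: minus-strand hit at the first-base offset
  rev_hit <- scan_consensus(make_promoters(c(y = "GGATCCCG")), "GGGATC")
  expect_equal(rev_hit$strand, "-")
  expect_equal(rev_hit$offset, 1)
  expect_equal(rev_hit$site_seq, "GGGATC")
})

test_that("degenerate point-mass PWM reproduces the consensus hit set", {
  counts <- diag(4)[match(strsplit("CACGTG", "")[[1]],
                          c("A", "C", "G", "T")), ] * 20
  mm <- motif_matrix("ebox", counts, pseudocount = 1e-6)
  prom <- random_promoters(30, 400, seed = 11)
  pwm_hits <- scan_pwm(prom, mm, uniform_bg(), prior = 0.1)
  cons_hits <- scan_consensus(prom, "CACGTG")
  expect_equal(pwm_hits[, c("gene_id", "offset", "strand")],
               cons_hits[, c("gene_id", "offset", "strand")],
               ignore_attr = TRUE)
})

test_that("PWM scanning equals the brute-force window-enumeration oracle", {
  mm <- random_motif(7, seed = 21)
  prom <- random_promoters(25, 250, seed = 22)
  # inject Ns to exercise the skip rule
  substr(prom$seq[1], 10, 12) <- "NNN"
  got <- scan_pwm(prom, mm, uniform_bg(), prior = 0.3)
  want <- oracle_pwm_scan(prom, mm, rep(0.25, 4), prior = 0.3)
  got <- got[order(got$gene_id, got$offset, got$strand), ]
  expect_equal(got$offset, want$offset)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-12)
})

test_that("raising the prior lowers the threshold and grows the hit set monotonically", {
  mm <- random_motif(6, seed = 31)
  prom <- random_promoters(15, 300, seed = 32)
  keys <- lapply(c(0.01, 0.1, 0.5), function(pr) {
    h <- scan_pwm(prom, mm, uniform_bg(), prior = pr)
    paste(h$gene_id, h$offset, h$strand)
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))

  # a prior so small that the threshold exceeds the maximum log-odds
  max_lo <- sum(log(apply(mm$freqs, 1, max)) - log(0.25))
  tiny_prior <- 1 / (1 + exp(max_lo + 1))
  expect_equal(nrow(scan_pwm(prom, mm, uniform_bg(), prior = tiny_prior)), 0)
})

test_that("hit counting sums instances, is order-invariant, and keeps schema", {
  counts <- diag(4)[match(strsplit("CACGTG", "")[[1]],
                          c("A", "C", "G", "T")), ] * 20
  mm <- motif_matrix("M00119-V$MAX_01", counts, pseudocount = 1e-6)
  two <- make_promoters(c(a = "TTCACGTGTTTTTTCACGTGTT"))
  tab <- count_feature_hits(two, list(mm), uniform_bg())
  expect_equal(tab$matrix_id, "M00119-V$MAX_01")
  expect_equal(tab$n, 2)
  expect_equal(tab$genes_hit, 1)

  prom <- random_promoters(12, 300, seed = 41)
  t1 <- count_feature_hits(prom, list(mm), uniform_bg())
  t2 <- count_feature_hits(prom[sample(nrow(prom)), ], list(mm), uniform_bg())
  expect_equal(t1, t2)

  empty <- prom[0, ]
  class(empty) <- c("promoter_set", "data.frame")
  expect_equal(count_feature_hits(empty, list(mm), uniform_bg())$n, 0)
})

test_that("hit offsets track genomic position when the window shifts", {
  gen <- sim_genome_tss(10, chrom_len = 1e5, seed = 51,
                        margin_up = 2000, margin_down = 500)
  small <- extract_promoters(gen$genome, gen$tss, 800, 200)
  big <- extract_promoters(gen$genome, gen$tss, 1500, 200)
  h_small <- scan_consensus(small, "CACGTG")
  h_big <- scan_consensus(big, "CACGTG")
  keep <- h_big$offset >= -800
  expect_equal(paste(h_big$gene_id[keep], h_big$offset[keep]),
               paste(h_small$gene_id, h_small$offset))
})

test_that("bundled synthetic TRANSFAC matrices parse and written hits round-trip", {
  path <- system.file("extdata", "synthetic_matrices.transfac",
                      package = "regscan")
  mats <- parse_transfac(path)
  expect_length(mats, 2)
  expect_equal(mats[[1]]$id, "SYN001-V$EBOX_SYN")
  expect_equal(consensus(mats[[1]]), "CACGTG")
  expect_equal(mats[[2]]$width, 8)

  gen <- sim_genome_tss(40, chrom_len = 3e5, seed = 61,
                        margin_up = 1500, margin_down = 500)
  prom <- extract_promoters(gen$genome, gen$tss, 1500, 500)
  hits <- scan_consensus(prom, "CACGTG")
  expect_gt(nrow(hits), 0)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, tmp, tss = gen$tss)
  back <- utils::read.delim(tmp)
  expect_equal(back$offset, hits$offset)
  bed <- utils::read.delim(sub("\\.tsv$", ".bed", tmp), header = FALSE)
  expect_equal(nrow(bed), nrow(hits))
  # genomic site sequence at the BED interval is the E-box (or its
  # reverse complement on minus-strand genes)
  for (i in seq_len(nrow(bed))) {
    gseq <- substr(gen$genome[[bed$V1[i]]], bed$V2[i] + 1, bed$V3[i])
    expect_true(gseq %in% c("CACGTG", revcomp("CACGTG")))
  }
})
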