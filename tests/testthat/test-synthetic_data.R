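test_that("genome simulation is deterministic, validated, and handles the empty case", {
  gen0 <- sim_genome_tss(0, chrom_len = 5000, seed = 1)
  expect_equal(nrow(gen0$tss), 0)
  expect_equal(nchar(gen0$genome[["chr1"]]), 5000)

  a <- sim_genome_tss(50, chrom_len = 500000, strand_fraction = 0.5,
                      bg_freqs = rep(0.25, 4), seed = 1)
  b <- sim_genome_tss(50, chrom_len = 500000, strand_fraction = 0.5,
                      bg_freqs = rep(0.25, 4), seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$tss), 50)
  expect_false(anyDuplicated(a$tss$gene_id) > 0)

  expect_error(sim_genome_tss(10, chrom_len = 1e5,
                              bg_freqs = c(0.5, 0.5, 0.5, 0.5), seed = 1),
               "sum to 1")
  expect_error(sim_genome_tss(1e5, chrom_len = 10000, seed = 1), "capacity")
})

test_that("simulated genome base frequencies converge to bg_freqs", {
  gen <- sim_genome_tss(0, chrom_len = 4e6, bg_freqs = rep(0.25, 4),
                        seed = 2)
  obs <- table(strsplit(gen$genome[["chr1"]], "")[[1]]) / 4e6
  expect_true(all(abs(obs - 0.25) < 0.005))
})

test_that("motif planting honours rate, boundaries and the positional model", {
  prom <- random_promoters(40, 300, seed = 4, tss_offset = -250L)
  none <- plant_motifs(prom, "CACGTG", 0, seed = 1)
  expect_identical(none$promoters, prom)
  expect_equal(nrow(none$truth), 0)

  all_at <- plant_motifs(prom, "CACGTG", 1,
                         positional = list(mode = "tss_peaked",
                                           peak_offset = -50, spread = 0),
                         seed = 2)
  expect_equal(nrow(all_at$truth), 40)
  expect_true(all(all_at$truth$offset == -50))
  hits <- scan_consensus(all_at$promoters, "CACGTG")
  found <- unique(hits$gene_id[hits$offset == -50])
  expect_setequal(found, prom$gene_id)

  # planted positions always lie inside the window
  peaked <- plant_motifs(prom, "CACGTG", 1,
                         positional = list(mode = "uniform"), seed = 3)
  expect_true(all(peaked$truth$offset >= -250 & peaked$truth$offset <= 44))

  # an unplaceable positional model fails after bounded retries
  expect_error(
    plant_motifs(prom, "CACGTG", 1,
                 positional = list(mode = "tss_peaked", peak_offset = 5000,
                                   spread = 1),
                 seed = 4, max_retry = 10),
    "could not place")
})

test_that("tss-peaked planting recovers the peak location", {
  gen <- sim_genome_tss(500, chrom_len = 4e6, seed = 7)
  prom <- extract_promoters(gen$genome, gen$tss, 3000, 500)
  planted <- plant_motifs(prom, "CACGTG", 1,
                          positional = list(mode = "tss_peaked",
                                            peak_offset = -50, spread = 30),
                          seed = 7)
  expect_equal(mean(planted$truth$offset), -50, tolerance = 5 / 50)
  # planted-equals-found: every truth site is recovered by the scanner
  hits <- scan_consensus(planted$promoters, "CACGTG")
  key_hits <- paste(hits$gene_id, hits$offset)
  key_truth <- paste(planted$truth$gene_id, planted$truth$offset)
  expect_true(all(key_truth %in% key_hits))
})

test_that("expression simulation plants exact shifts and validates inputs", {
  genes <- sprintf("g%03d", 1:20)
  clean <- sim_expression(genes, n_reps = 3, de_fraction = 0,
                          noise_sd = 0, seed = 1)
  expect_equal(rowMeans(clean$mat[, 1:3]), rowMeans(clean$mat[, 4:6]))

  one <- sim_expression(genes, n_reps = 3, de_fraction = 1 / 20,
                        lfc_magnitude = 1, noise_sd = 0, seed = 2)
  g <- names(one$truth)
  fc <- 2^(mean(one$mat[g, 4:6]) - mean(one$mat[g, 1:3]))
  expect_equal(fc, if (one$truth[[1]] > 0) 2 else 0.5)

  expect_error(sim_expression(genes, n_reps = 1, seed = 1), "n_reps")
})

test_that("target catalog: paper-scale cluster sizes, disjointness, planted overlap", {
  universe <- sprintf("g%05d", 1:20000)
  set.seed(42)
  resp <- sample(universe, 1900)
  cat5 <- sim_target_catalog(universe,
                             cluster_sizes = c(1712, 1643, 616, 178, 30),
                             responsive = resp, enrichment_factor = 1,
                             seed = 1)
  sizes <- lengths(cat5$catalog$clusters)
  expect_equal(unname(sizes), c(1712, 1643, 616, 178, 30))
  members <- unlist(cat5$catalog$clusters)
  expect_equal(anyDuplicated(members), 0)

  # null catalog: overlap within 3 hypergeometric SDs of expectation
  K <- sum(sizes); N <- length(universe); n <- length(resp)
  expect_exp <- n * K / N
  sd_hyp <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
  expect_lt(abs(length(cat5$truth$overlap_genes) - expect_exp), 3 * sd_hyp)

  # exclusion and infeasibility
  none <- sim_target_catalog(universe, cluster_sizes = c(100, 50),
                             responsive = resp, enrichment_factor = 0,
                             seed = 2)
  expect_equal(length(none$truth$overlap_genes), 0)
  expect_error(
    sim_target_catalog(universe[1:100], cluster_sizes = c(60, 30),
                       responsive = universe[1:50], enrichment_factor = 5,
                       seed = 3),
    "infeasible")
})

test_that("pathway simulation validates sizes and reruns byte-identically", {
  universe <- sprintf("g%04d", 1:500)
  expect_error(sim_pathways(universe, 5, size_range = c(0, 10), seed = 1),
               ">= 1")
  expect_error(sim_pathways(universe, 5, size_range = c(10, 600), seed = 1),
               "universe")

  f1 <- withr::local_tempfile(fileext = ".gmt")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sim_pathways(universe, 30, c(5, 40), seed = 9)$pathways, f1)
  write_gmt(sim_pathways(universe, 30, c(5, 40), seed = 9)$pathways, f2)
  expect_identical(readLines(f1), readLines(f2))

  hub <- sim_pathways(universe, 20, c(5, 40), n_enriched = 6,
                      sig_set = universe[1:40], seed = 4,
                      hub_gene = "g0001")
  in_enriched <- vapply(hub$pathways[hub$truth$enriched],
                        function(p) "g0001" %in% p, logical(1))
  expect_true(all(in_enriched))
})

test_that("generators leave the session RNG state untouched", {
  set.seed(99)
  expected_draw <- local({ x <- runif(1); set.seed(99); x })
  set.seed(99)
  invisible(sim_genome_tss(5, chrom_len = 50000, seed = 3,
                           margin_up = 100, margin_down = 50))
  expect_identical(runif(1), expected_draw)
})
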