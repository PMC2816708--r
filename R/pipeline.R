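# End-to-end pipeline over synthetic data: simulate -> extract -> scan ->
# enrich -> E-box profile -> DE -> cross-compare -> overlap -> pathways.
# Every stage is an exported function runnable standalone on the files
# another stage wrote; run_pipeline() chains them and writes a manifest
# (parameters + output checksums, no timestamps) so reruns with the same
# config are byte-identical.

#' Build and validate a pipeline configuration
#'
#' @param seed RNG seed (mandatory; every stochastic stage derives its
#'   stream from it).
#' @param outdir Output directory.
#' @param n_genes,chrom_len,strand_fraction,bg_freqs Genome simulation.
#' @param window_narrow,window_wide The two (up, down) promoter presets;
#'   defaults c(1000, 200) for motif enrichment and c(3000, 500) for the
#'   E-box profile.
#' @param prior,pseudocount Scan parameters.
#' @param n_decoys Decoy matrices in the scanning library.
#' @param plant_rate Fraction of responsive-gene promoters receiving a
#'   planted E-box.
#' @param n_reps,de_fraction,lfc,noise_sd Expression simulation (per cell
#'   line).
#' @param cluster_sizes,overlap_enrichment Target-catalog simulation.
#' @param n_pathways,pathway_sizes,n_enriched_pathways Pathway simulation.
#' @param fc_min,p_raw_max,q_max,pathway_p Filter thresholds.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(seed, outdir = "regscan_run",
                       n_genes = 400, chrom_len = 2e6,
                       strand_fraction = 0.5, bg_freqs = rep(0.25, 4),
                       window_narrow = c(1000, 200),
                       window_wide = c(3000, 500),
                       prior = 0.1, pseudocount = 0.01, n_decoys = 20,
                       plant_rate = 0.8,
                       n_reps = 3, de_fraction = 0.05, lfc = 1,
                       noise_sd = 0.25,
                       cluster_sizes = c(1712, 1643, 616, 178, 30),
                       overlap_enrichment = 2,
                       n_pathways = 60, pathway_sizes = c(10, 60),
                       n_enriched_pathways = 5,
                       fc_min = 1.2, p_raw_max = 0.01, q_max = 0.05,
                       pathway_p = 0.05) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (fc_min < 1) stop("'fc_min' must be >= 1", call. = FALSE)
  if (!(prior > 0 && prior < 1)) stop("'prior' must be in (0, 1)", call. = FALSE)
  for (th in c(p_raw_max, q_max, pathway_p)) {
    if (th <= 0 || th > 1) stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  bg_freqs <- stopifnot_prob_vector(bg_freqs)
  cfg <- list(seed = as.integer(seed), outdir = outdir, n_genes = n_genes,
              chrom_len = chrom_len, strand_fraction = strand_fraction,
              bg_freqs = bg_freqs, window_narrow = window_narrow,
              window_wide = window_wide, prior = prior,
              pseudocount = pseudocount, n_decoys = n_decoys,
              plant_rate = plant_rate, n_reps = n_reps,
              de_fraction = de_fraction, lfc = lfc, noise_sd = noise_sd,
              cluster_sizes = cluster_sizes,
              overlap_enrichment = overlap_enrichment,
              n_pathways = n_pathways, pathway_sizes = pathway_sizes,
              n_enriched_pathways = n_enriched_pathways, fc_min = fc_min,
              p_raw_max = p_raw_max, q_max = q_max, pathway_p = pathway_p)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return Validated `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Run the full synthetic-data pipeline
#'
#' Simulates every input with planted ground truth, runs each analysis
#' stage, writes all inputs and outputs under `config$outdir`, and
#' returns a manifest of parameters, stage summaries and output file
#' checksums. Deterministic: two runs with the same config produce
#' identical manifests.
#'
#' @param config A `run_config`.
#' @return List of class `run_manifest`: config, files (named md5 vector),
#'   results (per-stage key numbers), truth.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + 0:9  # one derived stream per stochastic stage

  # --- simulate genome + promoters -------------------------------------
  gen <- sim_genome_tss(config$n_genes, config$chrom_len,
                        config$strand_fraction, config$bg_freqs,
                        seed = seeds[1])
  write_fasta(gen$genome, file.path(out, "genome.fa"))
  write_tss_bed(gen$tss, file.path(out, "tss.bed"))
  prom_narrow <- extract_promoters(gen$genome, gen$tss,
                                   config$window_narrow[1],
                                   config$window_narrow[2])
  prom_wide <- extract_promoters(gen$genome, gen$tss,
                                 config$window_wide[1],
                                 config$window_wide[2])

  # --- simulate expression (two cell lines, shared planted genes) ------
  expr_a <- sim_expression(gen$tss$gene_id, config$n_reps,
                           config$de_fraction, config$lfc, config$noise_sd,
                           seed = seeds[2])
  expr_b <- sim_expression(gen$tss$gene_id, config$n_reps,
                           config$de_fraction, config$lfc, config$noise_sd,
                           seed = seeds[3])
  write_expression_tsv(expr_a$mat, file.path(out, "expression_a.tsv"))
  write_expression_tsv(expr_b$mat, file.path(out, "expression_b.tsv"))
  de_a <- call_de(expr_a$mat, expr_a$condition, config$fc_min,
                  config$p_raw_max, config$q_max)
  de_b <- call_de(expr_b$mat, expr_b$condition, config$fc_min,
                  config$p_raw_max, config$q_max)
  utils::write.table(de_a, file.path(out, "de_a.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de_b, file.path(out, "de_b.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cc <- cross_compare(de_a, de_b)
  write_cross_comparison(cc, out)

  # --- plant an E-box motif into responsive-gene promoters -------------
  ebox_mat <- motif_matrix("ebox-CACGTG",
                           diag(4)[match(strsplit("CACGTG", "")[[1]],
                                         DNA_BASES), ] * 20,
                           pseudocount = config$pseudocount)
  planted_genes <- names(expr_a$truth)
  fg_idx <- prom_narrow$gene_id %in% planted_genes
  planted_narrow <- plant_motifs(prom_narrow[fg_idx, ], "CACGTG",
                                 config$plant_rate,
                                 positional = list(mode = "tss_peaked",
                                                   peak_offset = -50,
                                                   spread = 30),
                                 seed = seeds[4])
  planted_wide <- plant_motifs(prom_wide[fg_idx, ], "CACGTG",
                               config$plant_rate,
                               positional = list(mode = "tss_peaked",
                                                 peak_offset = -50,
                                                 spread = 30),
                               seed = seeds[5])
  fg_prom <- rbind(planted_narrow$promoters, prom_narrow[!fg_idx, ])
  fg_prom <- fg_prom[order(fg_prom$gene_id), ]
  class(fg_prom) <- c("promoter_set", "data.frame")
  wide_prom <- rbind(planted_wide$promoters, prom_wide[!fg_idx, ])
  wide_prom <- wide_prom[order(wide_prom$gene_id), ]
  class(wide_prom) <- c("promoter_set", "data.frame")
  write_promoters(fg_prom, file.path(out, "promoters_narrow.fa"))
  write_promoters(wide_prom, file.path(out, "promoters_wide.fa"))

  # --- motif enrichment ------------------------------------------------
  bg_model <- background_model(config$bg_freqs, "simulated order-0")
  decoys <- sim_motif_library(config$n_decoys, width = 8, seed = seeds[6])
  matrices <- c(list(ebox_mat), decoys)
  expected <- estimate_expected_freq(fg_prom, matrices, bg_model,
                                     config$prior,
                                     source_label = "all promoters")
  responsive_a <- de_a$gene_id[de_a$direction != "ns"]
  fg_set <- fg_prom[fg_prom$gene_id %in% responsive_a, ]
  enrich <- enrich_table(fg_set, matrices, expected, bg_model, config$prior)
  utils::write.table(enrich, file.path(out, "motif_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- E-box positional profile ----------------------------------------
  dirs <- de_a$direction[de_a$direction != "ns"]
  names(dirs) <- de_a$gene_id[de_a$direction != "ns"]
  profile <- ebox_profile(wide_prom[wide_prom$gene_id %in% names(dirs), ],
                          groups = dirs)
  write_ebox_profile(profile, out)

  # --- target-catalog overlap ------------------------------------------
  cat_sim <- sim_target_catalog(gen$tss$gene_id,
                                scale_cluster_sizes(config$cluster_sizes,
                                                    config$n_genes),
                                responsive = responsive_a,
                                enrichment_factor = config$overlap_enrichment,
                                seed = seeds[7])
  overlap <- overlap_analysis(de_a, cat_sim$catalog)
  utils::write.table(overlap, file.path(out, "overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- pathways + bipartite network ------------------------------------
  path_sim <- sim_pathways(gen$tss$gene_id, config$n_pathways,
                           config$pathway_sizes,
                           n_enriched = config$n_enriched_pathways,
                           sig_set = responsive_a, seed = seeds[8])
  write_gmt(path_sim$pathways, file.path(out, "pathways.gmt"))
  penr <- pathway_enrich(de_a, path_sim$pathways, gen$tss$gene_id)
  utils::write.table(penr, file.path(out, "pathway_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  net <- build_bipartite(penr, path_sim$pathways, de_a, config$pathway_p)
  write_network(net, file.path(out, "network_edges.tsv"),
                file.path(out, "network.graphml"))
  crit <- critical_genes(net, k = 2)
  utils::write.table(crit, file.path(out, "critical_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- list.files(out, full.names = TRUE)
  files <- files[!dir.exists(files)]
  manifest <- list(
    config = unclass(config),
    results = list(
      n_responsive_a = length(responsive_a),
      n_responsive_b = sum(de_b$direction != "ns"),
      cross_comparison = as.list(cc$counts),
      top_motif = enrich$matrix_id[1],
      top_motif_probability = enrich$probability[1],
      overlap_total_observed = overlap$observed[overlap$scope == "total"],
      overlap_total_expected = overlap$expected[overlap$scope == "total"],
      overlap_total_p = overlap$p[overlap$scope == "total"],
      n_significant_pathways = sum(penr$p_raw <= config$pathway_p),
      critical_genes = crit$gene_id
    ),
    truth = list(
      de_genes_a = sort(names(expr_a$truth)),
      de_genes_b = sort(names(expr_b$truth)),
      planted_ebox_narrow = planted_narrow$truth,
      planted_ebox_wide = planted_wide$truth,
      overlap_genes = sort(cat_sim$truth$overlap_genes),
      enriched_pathways = path_sim$truth$enriched
    ),
    files = as.list(tools::md5sum(sort(files)))
  )
  class(manifest) <- "run_manifest"
  jsonlite::write_json(manifest_for_json(manifest),
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# scale the default catalog cluster sizes down to a small simulated
# universe, keeping proportions and at least 1 gene per cluster
scale_cluster_sizes <- function(sizes, n_genes) {
  if (sum(sizes) <= n_genes * 0.5) return(sizes)
  f <- n_genes * 0.4 / sum(sizes)
  pmax(1L, as.integer(round(sizes * f)))
}

manifest_for_json <- function(m) {
  m <- unclass(m)
  m$truth$planted_ebox_narrow <- NULL
  m$truth$planted_ebox_wide <- NULL
  m
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run manifest\n")
  cat("  outdir:", x$config$outdir, " seed:", x$config$seed, "\n")
  cat("  responsive genes (A/B):", x$results$n_responsive_a, "/",
      x$results$n_responsive_b, "\n")
  cat("  top motif:", x$results$top_motif,
      sprintf("(p = %.3g)", x$results$top_motif_probability), "\n")
  cat(sprintf("  overlap: observed %d vs expected %.1f (p = %.3g)\n",
              x$results$overlap_total_observed,
              x$results$overlap_total_expected,
              x$results$overlap_total_p))
  cat("  critical genes:", paste(x$results$critical_genes, collapse = ", "),
      "\n")
  invisible(x)
}
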