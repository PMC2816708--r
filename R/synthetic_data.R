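# Seeded synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of (parameters, seed): the RNG state
# is set locally and restored, so identical calls are byte-identical and
# generators never interact through global state. Background sequence is
# order-0 i.i.d. from the supplied base frequencies, matching the order-0
# expected-frequency model used by the scanners downstream. Motif planting
# overwrites bases (never inserts), so genomic coordinates never shift.

#' Simulate a genome and TSS annotation
#'
#' One chromosome of i.i.d. bases plus `n_genes` TSSs placed so that every
#' gene admits an unclipped -3000/+500 promoter window on either strand.
#'
#' @param n_genes Number of genes (>= 0).
#' @param chrom_len Chromosome length in bp.
#' @param strand_fraction Proportion of genes on the minus strand
#'   (deterministic count, random assignment).
#' @param bg_freqs Base probabilities (A, C, G, T), summing to 1.
#' @param seed RNG seed (required).
#' @param margin_up,margin_down Window sizes every gene must admit
#'   (defaults 3000/500).
#' @return List with `genome` (named character vector) and `tss`
#'   (data.frame: gene_id, chrom, tss, strand — the format
#'   [read_tss_bed()] produces).
#' @export
sim_genome_tss <- function(n_genes, chrom_len = 1e6, strand_fraction = 0.5,
                           bg_freqs = rep(0.25, 4), seed,
                           margin_up = 3000, margin_down = 500) {
  bg_freqs <- stopifnot_prob_vector(bg_freqs)
  if (n_genes < 0) stop("'n_genes' must be >= 0", call. = FALSE)
  with_seed(seed, {
    genome <- c(chr1 = paste(sample(DNA_BASES, chrom_len, replace = TRUE,
                                    prob = bg_freqs), collapse = ""))
    lo <- margin_up
    hi <- chrom_len - margin_up - 1
    if (hi < lo && n_genes > 0) {
      stop("chromosome too short to place any gene", call. = FALSE)
    }
    capacity <- max(hi - lo + 1, 0)
    if (n_genes > capacity) {
      stop(sprintf("cannot place %d genes: capacity %d", n_genes, capacity),
           call. = FALSE)
    }
    if (n_genes == 0) {
      tss <- data.frame(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    } else {
      pos <- sort(sample(lo:hi, n_genes, replace = FALSE))
      n_minus <- round(strand_fraction * n_genes)
      strand <- rep("+", n_genes)
      strand[sample(n_genes, n_minus)] <- "-"
      tss <- data.frame(
        gene_id = sprintf("g%04d", seq_len(n_genes)),
        chrom = "chr1", tss = as.integer(pos), strand = strand,
        stringsAsFactors = FALSE)
    }
    list(genome = genome, tss = tss)
  })
}

#' Write a TSS table as BED6
#'
#' The TSS base is written as a 1-bp feature (`start = tss`,
#' `end = tss + 1`).
#'
#' @param tss TSS data.frame (gene_id, chrom, tss, strand).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- data.frame(tss$chrom, tss$tss, tss$tss + 1L, tss$gene_id, 0L,
                    tss$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plant motif instances into promoters
#'
#' A fraction `foreground_rate` of promoters (deterministic count, random
#' subset) receives one planted instance by overwriting bases at a sampled
#' offset. Offsets are sampled uniformly over the window or from a
#' TSS-peaked Gaussian (`round(rnorm(peak_offset, spread))`), re-sampled
#' up to `max_retry` times if the instance would cross the window
#' boundary. Strand is drawn uniformly; minus-strand instances plant the
#' reverse complement.
#'
#' @param promoters A `promoter_set`.
#' @param motif A `motif_matrix` (instance bases drawn per position from
#'   its frequencies) or a consensus string (IUPAC letters resolved
#'   uniformly).
#' @param foreground_rate Proportion of promoters to modify, in `[0, 1]`.
#' @param positional List: `mode` (`"uniform"` or `"tss_peaked"`),
#'   `peak_offset` and `spread` (bp; used by the peaked mode).
#' @param seed RNG seed.
#' @param max_retry Resampling budget per promoter before failing.
#' @return List with `promoters` (modified set) and `truth` (data.frame:
#'   gene_id, offset of the planted first base relative to the TSS,
#'   strand, site).
#' @export
plant_motifs <- function(promoters, motif, foreground_rate,
                         positional = list(mode = "tss_peaked",
                                           peak_offset = -50, spread = 30),
                         seed, max_retry = 100) {
  if (foreground_rate < 0 || foreground_rate > 1) {
    stop("'foreground_rate' must be in [0, 1]", call. = FALSE)
  }
  width <- if (inherits(motif, "motif_matrix")) motif$width else nchar(motif)
  if (any(nchar(promoters$seq) < width)) {
    stop("motif longer than a promoter window", call. = FALSE)
  }
  empty_truth <- data.frame(gene_id = character(), offset = integer(),
                            strand = character(), site = character(),
                            stringsAsFactors = FALSE)
  n_fg <- round(foreground_rate * nrow(promoters))
  if (n_fg == 0) return(list(promoters = promoters, truth = empty_truth))
  with_seed(seed, {
    chosen <- sort(sample(nrow(promoters), n_fg))
    truth <- vector("list", length(chosen))
    for (j in seq_along(chosen)) {
      i <- chosen[j]
      L <- nchar(promoters$seq[i])
      first <- promoters$tss_offset[i]
      ok_lo <- first                 # lowest valid first-base offset
      ok_hi <- first + L - width     # highest valid first-base offset
      offset <- NA_integer_
      for (trial in seq_len(max_retry)) {
        cand <- if (identical(positional$mode, "uniform")) {
          sample(ok_lo:ok_hi, 1L)
        } else {
          as.integer(round(stats::rnorm(1, positional$peak_offset,
                                        positional$spread)))
        }
        if (cand >= ok_lo && cand <= ok_hi) { offset <- cand; break }
      }
      if (is.na(offset)) {
        stop("could not place motif within the window after ", max_retry,
             " tries (gene ", promoters$gene_id[i], ")", call. = FALSE)
      }
      site <- draw_site(motif)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") site else revcomp(site)
      pos <- offset - first + 1L
      substr(promoters$seq[i], pos, pos + width - 1L) <- planted
      truth[[j]] <- data.frame(gene_id = promoters$gene_id[i],
                               offset = offset, strand = strand,
                               site = site, stringsAsFactors = FALSE)
    }
    list(promoters = promoters, truth = do.call(rbind, truth))
  })
}

# Draw one concrete site: per-position sample from a matrix's frequencies,
# or resolve IUPAC letters of a consensus uniformly.
draw_site <- function(motif) {
  if (inherits(motif, "motif_matrix")) {
    paste(apply(motif$freqs, 1, function(f) sample(DNA_BASES, 1L, prob = f)),
          collapse = "")
  } else {
    letters_m <- strsplit(toupper(motif), "")[[1]]
    bad <- setdiff(letters_m, names(IUPAC_MAP))
    if (length(bad)) {
      stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    paste(vapply(letters_m, function(l) {
      opts <- IUPAC_MAP[[l]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
  }
}

#' Simulate a two-condition expression matrix with planted fold changes
#'
#' Log2-scale genes x (2 * n_reps) matrix: per-gene baseline plus i.i.d.
#' Gaussian noise; a fraction `de_fraction` of genes (deterministic count,
#' the first genes after a random permutation) is shifted by
#' `±lfc_magnitude` in the treated condition with random sign.
#'
#' @param universe Character vector of gene ids.
#' @param n_reps Replicates per condition (>= 2; the t-test is undefined
#'   below that).
#' @param de_fraction Proportion of genes shifted.
#' @param lfc_magnitude Absolute shift in log2 units.
#' @param noise_sd Per-observation noise SD in log2 units.
#' @param seed RNG seed.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @return List with `mat` (rownames = gene ids, colnames
#'   `control_i`/`treated_i`), `condition`, and `truth` (named numeric
#'   vector of signed log2 shifts for the planted genes).
#' @export
sim_expression <- function(universe, n_reps = 3, de_fraction = 0.05,
                           lfc_magnitude = 1, noise_sd = 0.25, seed,
                           baseline_mean = 8, baseline_sd = 1.5) {
  if (n_reps < 2) stop("'n_reps' must be >= 2 (t-test undefined)", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("'de_fraction' must be in [0, 1]", call. = FALSE)
  }
  n <- length(universe)
  with_seed(seed, {
    base <- stats::rnorm(n, baseline_mean, baseline_sd)
    mat <- matrix(stats::rnorm(n * 2 * n_reps, 0, noise_sd), n, 2 * n_reps) +
      base
    n_de <- round(de_fraction * n)
    truth <- numeric(0)
    if (n_de > 0) {
      idx <- sample(n, n_de)
      shift <- sample(c(-1, 1), n_de, replace = TRUE) * lfc_magnitude
      mat[idx, (n_reps + 1):(2 * n_reps)] <-
        mat[idx, (n_reps + 1):(2 * n_reps)] + shift
      truth <- stats::setNames(shift, universe[idx])
    }
    rownames(mat) <- universe
    colnames(mat) <- c(paste0("control_", seq_len(n_reps)),
                       paste0("treated_", seq_len(n_reps)))
    list(mat = mat,
         condition = rep(c("control", "treated"), each = n_reps),
         truth = truth)
  })
}

#' Simulate a clustered target-gene catalog with planted overlap enrichment
#'
#' Disjoint clusters are drawn without replacement, in cluster order, with
#' per-gene weight `enrichment_factor` for genes in `responsive` and 1
#' otherwise, so responsive genes join the catalog at roughly
#' `enrichment_factor` times the baseline rate (1 = null, 0 = excluded).
#'
#' @param universe Character vector of gene ids.
#' @param cluster_sizes Integer vector of cluster sizes, in order; defaults
#'   to the five temporal-cluster sizes of the catalog this generator
#'   emulates (1712, 1643, 616, 178, 30).
#' @param responsive Character vector of responsive gene ids (may be
#'   empty).
#' @param enrichment_factor Weight ratio (>= 0).
#' @param seed RNG seed.
#' @return List with `catalog` (a `target_catalog`) and `truth`
#'   (list: overlap_genes, per-cluster realized overlap counts).
#' @export
sim_target_catalog <- function(universe, cluster_sizes = c(1712, 1643, 616,
                                                           178, 30),
                               responsive = character(), enrichment_factor = 1,
                               seed) {
  if (enrichment_factor < 0) stop("'enrichment_factor' must be >= 0", call. = FALSE)
  if (any(cluster_sizes < 0)) stop("cluster sizes must be >= 0", call. = FALSE)
  n <- length(universe)
  k <- sum(cluster_sizes)
  if (k > n) stop("sum of cluster sizes exceeds universe size", call. = FALSE)
  if (enrichment_factor * k / n > 1) {
    stop("infeasible enrichment: implied membership probability > 1",
         call. = FALSE)
  }
  responsive <- intersect(responsive, universe)
  if (enrichment_factor == 0 && n - length(responsive) < k) {
    stop("cannot exclude responsive genes: too few non-responsive genes",
         call. = FALSE)
  }
  with_seed(seed, {
    w <- rep(1, n)
    w[universe %in% responsive] <- enrichment_factor
    picked <- sample(universe, k, replace = FALSE, prob = w)
    clusters <- split(picked, rep(seq_along(cluster_sizes), cluster_sizes))
    names(clusters) <- paste0("cluster", seq_along(cluster_sizes))
    catalog <- target_catalog(clusters, universe)
    overlap <- intersect(picked, responsive)
    per_cluster <- vapply(clusters, function(cl)
      length(intersect(cl, responsive)), integer(1))
    list(catalog = catalog,
         truth = list(overlap_genes = overlap,
                      per_cluster_overlap = per_cluster))
  })
}

#' Simulate a pathway catalog with planted enrichment
#'
#' Pathway sizes are uniform over `size_range`; the first
#' `n_enriched` pathways oversample `sig_set` genes with weight
#' `enrich_weight`, the rest draw uniformly from the universe.
#'
#' @param universe Character vector of gene ids.
#' @param n_pathways Number of pathways.
#' @param size_range Length-2 integer range of pathway sizes (min >= 1).
#' @param n_enriched Number of enriched pathways (may be 0).
#' @param sig_set Genes the enriched pathways oversample.
#' @param seed RNG seed.
#' @param enrich_weight Sampling weight for `sig_set` genes in enriched
#'   pathways (default 5).
#' @param hub_gene Optional gene id planted as a member of every enriched
#'   pathway (a known network hub for recovery studies).
#' @return List with `pathways` (named list, GMT-representable) and
#'   `truth` (list: enriched pathway ids, hub gene).
#' @export
sim_pathways <- function(universe, n_pathways = 400, size_range = c(10, 100),
                         n_enriched = 0, sig_set = character(), seed,
                         enrich_weight = 5, hub_gene = NULL) {
  if (size_range[1] < 1) {
    stop("pathway sizes must be >= 1", call. = FALSE)
  }
  if (size_range[2] > length(universe)) {
    stop("'size_range' exceeds universe size", call. = FALSE)
  }
  if (n_enriched > n_pathways) stop("n_enriched > n_pathways", call. = FALSE)
  if (!is.null(hub_gene) && !hub_gene %in% universe) {
    stop("'hub_gene' must belong to the universe", call. = FALSE)
  }
  with_seed(seed, {
    w_enr <- rep(1, length(universe))
    w_enr[universe %in% sig_set] <- enrich_weight
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    ids <- sprintf("path%04d", seq_len(n_pathways))
    pathways <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      w <- if (i <= n_enriched) w_enr else NULL
      members <- sample(universe, sizes[i], replace = FALSE, prob = w)
      if (i <= n_enriched && !is.null(hub_gene) &&
          !hub_gene %in% members) {
        members[1] <- hub_gene
      }
      members <- sort(members)
      attr(members, "description") <-
        if (i <= n_enriched) "enriched pathway" else "background pathway"
      pathways[[i]] <- members
    }
    names(pathways) <- ids
    list(pathways = pathways,
         truth = list(enriched = ids[seq_len(n_enriched)],
                      hub_gene = hub_gene))
  })
}

#' Generate a library of random motif matrices
#'
#' Draws sharp random position frequency matrices (per-position counts
#' from a multinomial over Dirichlet-like base weights) for use as decoy
#' scanning libraries in power and calibration studies.
#'
#' @param n Number of matrices.
#' @param width Motif width.
#' @param seed RNG seed.
#' @param depth Count depth per position (default 50).
#' @param sharpness Gamma shape controlling per-position base skew
#'   (default 0.1; smaller = sharper). The default yields
#'   information-rich matrices whose promoter hit rates are of order one
#'   per kilobase, like curated transcription-factor matrices; soft
#'   matrices with tens of hits per promoter are not useful decoys.
#' @return List of `motif_matrix` objects with ids `dec0001`...
#' @export
sim_motif_library <- function(n, width = 8, seed, depth = 50,
                              sharpness = 0.1) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      counts <- t(vapply(seq_len(width), function(j) {
        p <- stats::rgamma(4, sharpness)
        as.numeric(stats::rmultinom(1, depth, p / sum(p)))
      }, numeric(4)))
      motif_matrix(sprintf("dec%04d", i), counts)
    })
  })
}
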