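# Shared fixture builders. Everything is generated in code; no binary or
# stored data.

# a promoter_set built directly from sequences (tss_offset defaults to 0:
# the first base IS the TSS base)
make_promoters <- function(seqs, tss_offset = 0L,
                           window_up = abs(tss_offset),
                           window_down = nchar(seqs) - abs(tss_offset)) {
  ids <- names(seqs) %||% sprintf("p%03d", seq_along(seqs))
  out <- data.frame(gene_id = ids, seq = unname(toupper(seqs)),
                    tss_offset = as.integer(tss_offset),
                    window_up = as.integer(window_up),
                    window_down = as.integer(window_down),
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# random uniform-base promoters of a given length
random_promoters <- function(n, len, seed, tss_offset = -round(len * 0.8)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("r%04d", seq_len(n))
  make_promoters(seqs, tss_offset = tss_offset, window_up = -tss_offset,
                 window_down = len + tss_offset)
}

# a random count matrix wrapped as motif_matrix
random_motif <- function(width, seed, id = "rnd") {
  set.seed(seed)
  counts <- t(vapply(seq_len(width), function(j) {
    as.numeric(stats::rmultinom(1, 20, prob = stats::rgamma(4, 0.5)))
  }, numeric(4)))
  motif_matrix(id, counts)
}

uniform_bg <- function() background_model(rep(0.25, 4), "uniform")

# independent brute-force PWM scan oracle: enumerate every window on both
# strands, score with plain prod()/log(), apply the posterior-odds rule
oracle_pwm_scan <- function(promoters, motif, bg_freqs, prior) {
  thr <- log((1 - prior) / prior)
  w <- motif$width
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$seq[i]
    L <- nchar(s)
    if (L < w) next
    for (p in seq_len(L - w + 1)) {
      win <- substr(s, p, p + w - 1)
      idx <- match(strsplit(win, "")[[1]], bases)
      if (anyNA(idx)) next
      sc_f <- sum(log(motif$freqs[cbind(seq_len(w), idx)]) -
                    log(bg_freqs[idx]))
      ridx <- rev(5 - idx)
      sc_r <- sum(log(motif$freqs[cbind(seq_len(w), ridx)]) -
                    log(bg_freqs[ridx]))
      palin <- all(idx == ridx)
      if (sc_f > thr) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = promoters$gene_id[i],
          offset = promoters$tss_offset[i] + p - 1L, strand = "+",
          score = sc_f, stringsAsFactors = FALSE)
      }
      if (sc_r > thr && !(palin && sc_f > thr)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = promoters$gene_id[i],
          offset = promoters$tss_offset[i] + p - 1L, strand = "-",
          score = sc_r, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), offset = integer(),
                      strand = character(), score = numeric())
  }
  out[order(out$gene_id, out$offset, out$strand), , drop = FALSE]
}

# exhaustive two-sided Fisher p for a 2x2 table: sum of probabilities of
# all tables with the same margins whose probability <= observed
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive one-sided (upper) Fisher p: P(X >= a) by direct summation
oracle_fisher_upper <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  hi <- min(r1, c1)
  if (a > hi) return(0)
  sum(vapply(a:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1)))
}
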