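# Motif over-representation against a background frequency model.
#
# The statistic mirrors the classic promoter-set workflow: an expected
# per-promoter hit rate is estimated on a background promoter set, the
# observed instance count in the foreground is tested against an exact
# binomial upper tail, and the reported "significance" is
# -log10(p * n_matrices) so that positive values mean the
# Bonferroni-corrected p is below 1.

#' Estimate expected per-promoter hit rates on a background promoter set
#'
#' The rate is total hit instances divided by the number of background
#' promoters. The background window length is recorded so the rate can be
#' rescaled per-bp when foreground windows differ in length.
#'
#' @param background A `promoter_set` of background promoters (non-empty).
#' @param matrices List of `motif_matrix` objects.
#' @param bg A `background_model`.
#' @param prior,strands Scan parameters (see [scan_pwm()]).
#' @param source_label Provenance label stored with each rate.
#' @return data.frame of class `expected_freq`: matrix_id, rate, window_bp,
#'   source_label.
#' @export
estimate_expected_freq <- function(background, matrices, bg, prior = 0.1,
                                   strands = "both",
                                   source_label = "background promoters") {
  if (nrow(background) == 0L) {
    stop("background promoter set is empty", call. = FALSE)
  }
  counts <- count_feature_hits(background, matrices, bg, prior, strands)
  out <- data.frame(matrix_id = counts$matrix_id,
                    rate = counts$n / nrow(background),
                    window_bp = as.integer(stats::median(nchar(background$seq))),
                    source_label = source_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("expected_freq", "data.frame")
  out
}

#' Exact binomial upper-tail over-representation probability
#'
#' Models the total instance count over `g` foreground promoters as
#' `X ~ Binomial(g * windows, rate / windows)` where `windows` is the
#' number of scannable windows per promoter, and returns `P(X >= n)` by
#' exact summation. When `g * windows` exceeds 1e6 a Poisson tail with
#' `lambda = g * rate` is used instead (documented fallback; the two agree
#' to well within reporting precision at that scale).
#'
#' @param n Observed hit instances in the foreground (>= 0).
#' @param g Number of foreground promoters (>= 1).
#' @param rate Expected hit instances per promoter.
#' @param windows Scannable windows per promoter (e.g.
#'   `2 * (window_bp - width + 1)` for a both-strand scan). Default 1000.
#' @return Upper-tail probability `P(X >= n)`.
#' @export
binomial_overrep <- function(n, g, rate, windows = 1000) {
  if (n < 0 || g < 1 || rate < 0) {
    stop("need n >= 0, g >= 1, rate >= 0", call. = FALSE)
  }
  if (n == 0) return(1)
  q <- rate / windows
  if (q > 1) {
    stop("rate implies per-window probability > 1", call. = FALSE)
  }
  size <- g * windows
  if (size <= 1e6) {
    stats::pbinom(n - 1, size = round(size), prob = q, lower.tail = FALSE)
  } else {
    stats::ppois(n - 1, lambda = g * rate, lower.tail = FALSE)
  }
}

#' Bonferroni-style significance score
#'
#' `score = -log10(probability * n_matrices_tested)`; positive scores mean
#' the corrected p-value is below 1. A probability of exactly 0 is capped
#' at `cap` with a warning.
#'
#' @param probability Upper-tail p-value(s) in (0, 1].
#' @param n_matrices_tested Number of matrices scanned in the run (>= 1).
#' @param cap Score cap used when probability underflows to 0 (default 300,
#'   the double-precision decade limit).
#' @return Numeric score(s).
#' @export
significance_score <- function(probability, n_matrices_tested, cap = 300) {
  if (n_matrices_tested < 1) stop("n_matrices_tested must be >= 1", call. = FALSE)
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- -log10(probability * n_matrices_tested)
  if (any(probability == 0, na.rm = TRUE)) {
    warning("probability of 0 capped at score ", cap)
    out[probability == 0] <- cap
  }
  out
}

#' Motif over-representation table for a foreground promoter set
#'
#' One row per matrix: observed instance count, binomial upper-tail
#' probability against the expected rate (rescaled per-bp when the
#' foreground window length differs from the background's), and the
#' significance score with multiplier equal to the number of matrices in
#' the run. Rows with probability < `p_cut` are flagged overrepresented.
#' Rows are sorted by significance, descending.
#'
#' @param promoters Foreground `promoter_set`.
#' @param matrices List of `motif_matrix` objects.
#' @param expected An `expected_freq` table covering every matrix.
#' @param bg,prior,strands Scan parameters.
#' @param p_cut Flagging threshold on the raw probability (default 0.05).
#' @return data.frame of class `enrichment_table`: matrix_id, n, genes_hit,
#'   rate, probability, significance, overrepresented; run metadata in
#'   attributes prior, background_label, n_matrices.
#' @export
enrich_table <- function(promoters, matrices, expected, bg, prior = 0.1,
                         strands = "both", p_cut = 0.05) {
  if (!length(matrices)) {
    out <- data.frame(matrix_id = character(), n = integer(),
                      genes_hit = integer(), rate = numeric(),
                      probability = numeric(), significance = numeric(),
                      overrepresented = logical(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  ids <- vapply(matrices, function(m) m$id, character(1))
  missing <- setdiff(ids, expected$matrix_id)
  if (length(missing)) {
    stop("matrices missing from expected-frequency table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- count_feature_hits(promoters, matrices, bg, prior, strands)
  g <- nrow(promoters)
  fg_bp <- if (g) as.integer(stats::median(nchar(promoters$seq))) else 0L
  idx <- match(counts$matrix_id, expected$matrix_id)
  widths <- vapply(matrices, function(m) m$width, integer(1))
  widths <- widths[match(counts$matrix_id, ids)]
  rate <- expected$rate[idx]
  bg_bp <- expected$window_bp[idx]
  scale_needed <- fg_bp > 0 & bg_bp > 0 & fg_bp != bg_bp
  rate[scale_needed] <- rate[scale_needed] * fg_bp / bg_bp[scale_needed]
  windows <- pmax(2L * (fg_bp - widths + 1L), 1L)
  prob <- mapply(function(n, r, w) {
    if (g == 0L) return(1)
    binomial_overrep(n, g, r, windows = w)
  }, counts$n, rate, windows)
  out <- data.frame(matrix_id = counts$matrix_id, n = counts$n,
                    genes_hit = counts$genes_hit, rate = rate,
                    probability = prob,
                    significance = significance_score(pmax(prob, 1e-300),
                                                      length(matrices)),
                    overrepresented = prob < p_cut,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$significance, out$matrix_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  attr(out, "background_label") <- expected$source_label[1]
  attr(out, "n_matrices") <- length(matrices)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("motif enrichment: %d matrices, prior %.3g, background '%s'\n",
              attr(x, "n_matrices"), attr(x, "prior"),
              attr(x, "background_label")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write/read an expected-frequency table as TSV
#'
#' @param expected An `expected_freq` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_expected_freq <- function(expected, path) {
  utils::write.table(expected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expected_freq
#' @export
read_expected_freq <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("matrix_id", "rate", "window_bp", "source_label")
  if (!all(needed %in% names(out))) {
    stop("expected-frequency TSV must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("expected_freq", "data.frame")
  out
}
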