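# Differential-expression filter cascade and two-cell-line cross-comparison.
#
# The calling cascade applies, in order: the raw screen (two-sided t-test
# p <= p_raw_max AND |linear fold change| >= fc_min), then a
# Benjamini-Hochberg adjustment of the screened genes' p-values with a
# q <= q_max gate. Applying BH to the screened set follows the stated
# analysis order (exclusion first, corrected test second); applying it to
# all genes instead would make the corrected gate vastly more stringent
# than either printed threshold at triplicate sample sizes.

#' Per-gene two-sample t-test
#'
#' Two-sided Student's t with pooled variance (df = n1 + n2 - 2) by
#' default; Welch's unequal-variance form by flag. Genes with zero
#' within-group variance and zero mean difference get p = 1.
#'
#' @param mat Numeric genes x samples matrix of log2 intensities with gene
#'   ids as rownames.
#' @param condition Character/factor of length `ncol(mat)` with two levels;
#'   the first level is the control group. At least 2 replicates per
#'   condition are required.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) variance.
#' @return data.frame: gene_id, mean_diff (treated - control, log2),
#'   t, df, p_raw.
#' @export
ttest_per_gene <- function(mat, condition, var_equal = TRUE) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L || length(condition) != ncol(mat)) {
    stop("'condition' must assign each column to one of two groups",
         call. = FALSE)
  }
  a <- mat[, condition == levels(condition)[1], drop = FALSE]
  b <- mat[, condition == levels(condition)[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 replicates per condition", call. = FALSE)
  }
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  d <- m2 - m1
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  t[degenerate & d == 0] <- 0
  p[degenerate & d == 0] <- 1
  # zero variance but nonzero difference: infinitely strong evidence
  t[degenerate & d != 0] <- sign(d[degenerate & d != 0]) * Inf
  p[degenerate & d != 0] <- 0
  data.frame(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             mean_diff = d, t = t, df = df, p_raw = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over the standard step-up FDR adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes with the filter cascade
#'
#' A gene is called DE iff `|linear fold change| >= fc_min` and
#' `p_raw <= p_raw_max` and, among genes passing those two screens, BH
#' `q <= q_max`. Fold changes are reported in the signed-reciprocal
#' convention (ratios below 1 as the negative reciprocal, e.g. 0.61 as
#' -1.64) so `|fc_signed| >= 1` always.
#'
#' @inheritParams ttest_per_gene
#' @param fc_min Minimum linear fold change (>= 1); default 1.2.
#' @param p_raw_max Raw p-value exclusion threshold; default 0.01.
#' @param q_max BH q-value threshold applied within the screened set;
#'   default 0.05.
#' @return data.frame of class `de_result`: gene_id, mean_diff, fc_signed,
#'   p_raw, q_bh (NA for genes failing the raw screen), direction
#'   (up/down/ns).
#' @export
call_de <- function(mat, condition, fc_min = 1.2, p_raw_max = 0.01,
                    q_max = 0.05, var_equal = TRUE) {
  if (fc_min < 1) stop("'fc_min' must be >= 1", call. = FALSE)
  if (p_raw_max <= 0 || p_raw_max > 1 || q_max <= 0 || q_max > 1) {
    stop("p/q thresholds must lie in (0, 1]", call. = FALSE)
  }
  tt <- ttest_per_gene(mat, condition, var_equal)
  ratio <- 2^tt$mean_diff
  fc_signed <- ifelse(ratio >= 1, ratio, -1 / ratio)
  screened <- abs(fc_signed) >= fc_min & tt$p_raw <= p_raw_max
  q <- rep(NA_real_, nrow(tt))
  q[screened] <- bh_adjust(tt$p_raw[screened])
  pass <- screened & !is.na(q) & q <= q_max
  direction <- ifelse(!pass, "ns", ifelse(tt$mean_diff > 0, "up", "down"))
  out <- data.frame(gene_id = tt$gene_id, mean_diff = tt$mean_diff,
                    fc_signed = fc_signed, p_raw = tt$p_raw, q_bh = q,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(fc_min = fc_min, p_raw_max = p_raw_max,
                               q_max = q_max)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("de_result: %d genes, %d up / %d down (fc >= %.2g, p <= %.2g, q <= %.2g)\n",
              nrow(x), sum(x$direction == "up"), sum(x$direction == "down"),
              th["fc_min"], th["p_raw_max"], th["q_max"]))
  invisible(x)
}

#' Median-center expression ratios per gene
#'
#' Subtracts each gene's median across analyses so the per-gene median of
#' the centered values is 0. Genes that are entirely missing are dropped
#' with a warning.
#'
#' @param mat Numeric genes x analyses matrix (log ratios).
#' @return Centered matrix.
#' @export
median_center <- function(mat) {
  all_na <- apply(mat, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    warning(sum(all_na), " all-missing gene(s) dropped")
    mat <- mat[!all_na, , drop = FALSE]
  }
  med <- apply(mat, 1, stats::median, na.rm = TRUE)
  sweep(mat, 1, med, "-")
}

#' One-way F-test screen across experimental groups
#'
#' A per-gene one-way ANOVA F-test across >= 2 groups with BH adjustment;
#' used as a multi-group significance screen (e.g. two cell lines, each
#' with and without treatment). The screen behind published multi-group
#' feature counts is not uniquely identifiable, so this is offered as a
#' stand-in, not a replication.
#'
#' @param mat Numeric genes x samples matrix.
#' @param groups Factor of length `ncol(mat)`.
#' @param q_max BH threshold for the `significant` flag (default 0.05).
#' @return data.frame: gene_id, f, df1, df2, p_raw, q_bh, significant.
#' @export
ftest_screen <- function(mat, groups, q_max = 0.05) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(mat) || nlevels(groups) < 2L) {
    stop("'groups' must assign each column to one of >= 2 groups",
         call. = FALSE)
  }
  k <- nlevels(groups)
  n <- ncol(mat)
  gm <- rowMeans(mat)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    sub <- mat[, groups == lev, drop = FALSE]
    ni <- ncol(sub)
    mi <- rowMeans(sub)
    ssb <- ssb + ni * (mi - gm)^2
    ssw <- ssw + rowSums((sub - mi)^2)
  }
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  q <- bh_adjust(p)
  data.frame(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             f = f, df1 = df1, df2 = df2, p_raw = p, q_bh = q,
             significant = q <= q_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-compare differential-expression calls from two cell lines
#'
#' Decomposes the two responsive sets into exclusive-to-A, exclusive-to-B,
#' and shared; the shared set splits disjointly into co-upregulated,
#' co-downregulated and opposite-direction genes.
#'
#' @param de_a,de_b `de_result` tables sharing a gene-id namespace.
#' @return Object of class `cross_comparison`: member sets (exclusive_a,
#'   exclusive_b, shared, co_up, co_down, opposite) plus a `counts` vector.
#' @export
cross_compare <- function(de_a, de_b) {
  dir_a <- stats::setNames(de_a$direction, de_a$gene_id)
  dir_b <- stats::setNames(de_b$direction, de_b$gene_id)
  resp_a <- names(dir_a)[dir_a != "ns"]
  resp_b <- names(dir_b)[dir_b != "ns"]
  shared <- intersect(resp_a, resp_b)
  co_up <- shared[dir_a[shared] == "up" & dir_b[shared] == "up"]
  co_down <- shared[dir_a[shared] == "down" & dir_b[shared] == "down"]
  opposite <- setdiff(shared, c(co_up, co_down))
  out <- list(exclusive_a = sort(setdiff(resp_a, shared)),
              exclusive_b = sort(setdiff(resp_b, shared)),
              shared = sort(shared), co_up = sort(co_up),
              co_down = sort(co_down), opposite = sort(opposite))
  out$counts <- vapply(out, length, integer(1))
  class(out) <- "cross_comparison"
  out
}

#' @export
print.cross_comparison <- function(x, ...) {
  cat("cross-comparison of two responsive gene sets\n")
  cat(sprintf("  exclusive A: %d   exclusive B: %d   shared: %d\n",
              x$counts["exclusive_a"], x$counts["exclusive_b"],
              x$counts["shared"]))
  cat(sprintf("  shared = co-up %d + co-down %d + opposite %d\n",
              x$counts["co_up"], x$counts["co_down"], x$counts["opposite"]))
  invisible(x)
}

#' Write a cross-comparison as membership and count TSVs
#'
#' @param cc A `cross_comparison`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_cross_comparison <- function(cc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- c("exclusive_a", "exclusive_b", "co_up", "co_down", "opposite")
  mem <- do.call(rbind, lapply(sets, function(s) {
    if (!length(cc[[s]])) return(NULL)
    data.frame(gene_id = cc[[s]], set = s)
  }))
  p1 <- file.path(dir, "cross_comparison_members.tsv")
  utils::write.table(mem %||% data.frame(gene_id = character(), set = character()),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "cross_comparison_counts.tsv")
  utils::write.table(data.frame(set = names(cc$counts), n = cc$counts),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read/write an expression matrix TSV
#'
#' First column gene_id; header gives sample labels whose prefix up to the
#' first underscore is the condition (e.g. `control_1`, `treated_2`).
#'
#' @param path TSV path.
#' @return List with mat (genes x samples) and condition (character).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  condition <- sub("_.*$", "", colnames(mat))
  if (length(unique(condition)) < 2L) {
    stop("sample labels must encode two conditions as '<condition>_<rep>'",
         call. = FALSE)
  }
  list(mat = mat, condition = condition)
}

#' @rdname read_expression_tsv
#' @param mat Genes x samples matrix with gene rownames and
#'   `<condition>_<rep>` column names.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
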