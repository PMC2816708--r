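# Canonical E-box content and positional distribution relative to the TSS.
#
# Offsets use the site's first base in gene-strand orientation, with the
# TSS at 0 and upstream negative. CACGTG is its own reverse complement, so
# a both-strand scan reports each occurrence once (deduplication is built
# into the consensus scanner).

#' E-box positional profile and per-promoter count distribution
#'
#' Scans a promoter set (typically the -3000/+500 preset) for perfect
#' matches to a canonical E-box and returns, for the whole set and for each
#' direction group, the hit offsets, a histogram density (normalized to
#' integrate to 1), an optional Gaussian kernel density, and the
#' per-promoter count distribution.
#'
#' @param promoters A `promoter_set`.
#' @param pattern Consensus pattern; default the canonical E-box `CACGTG`.
#' @param groups Optional named character vector or two-column data.frame
#'   (gene_id, direction) assigning genes to `"up"`/`"down"`. Genes in the
#'   table but absent from the promoter set are skipped with a warning.
#' @param bin_width Histogram bin width in bp (default 50).
#' @param kernel If `TRUE` (default), also compute a Gaussian kernel
#'   density (Silverman's bandwidth) for plotting.
#' @return Object of class `ebox_profile`: a list with one element per
#'   group (`all`, plus `up`/`down` when groups are given), each holding
#'   offsets, density (data.frame mid/density), kernel (or NULL), counts
#'   (named per-promoter E-box counts) and group_label; bin width recorded
#'   in attribute `bin_width`.
#' @export
ebox_profile <- function(promoters, pattern = "CACGTG", groups = NULL,
                         bin_width = 50, kernel = TRUE) {
  hits <- scan_consensus(promoters, pattern, strands = "both")
  window <- c(-max(promoters$window_up %||% 0L),
              max(promoters$window_down %||% 0L))
  groups_vec <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups_vec <- stats::setNames(as.character(groups[[2]]),
                                    as.character(groups[[1]]))
    } else {
      groups_vec <- groups
    }
    absent <- setdiff(names(groups_vec), promoters$gene_id)
    if (length(absent)) {
      warning(length(absent), " grouped gene(s) absent from promoter set, skipped")
      groups_vec <- groups_vec[!names(groups_vec) %in% absent]
    }
  }
  one_group <- function(gene_ids, label) {
    h <- hits[hits$gene_id %in% gene_ids, , drop = FALSE]
    counts <- stats::setNames(integer(length(gene_ids)), gene_ids)
    tab <- table(h$gene_id)
    counts[names(tab)] <- as.integer(tab)
    offsets <- h$offset
    breaks <- seq(window[1], window[2] + bin_width, by = bin_width)
    dens <- if (length(offsets)) {
      hh <- graphics::hist(offsets, breaks = breaks, plot = FALSE)
      data.frame(mid = hh$mids, density = hh$density)
    } else {
      data.frame(mid = utils::head(breaks, -1) + bin_width / 2,
                 density = 0)
    }
    kd <- if (kernel && length(offsets) >= 2 && stats::sd(offsets) > 0) {
      stats::density(offsets, bw = "nrd0")
    } else NULL
    list(offsets = offsets, density = dens, kernel = kd, counts = counts,
         group_label = label)
  }
  out <- list(all = one_group(promoters$gene_id, "all"))
  if (!is.null(groups_vec)) {
    for (lab in c("up", "down")) {
      ids <- names(groups_vec)[groups_vec == lab]
      out[[lab]] <- one_group(ids, lab)
    }
  }
  attr(out, "bin_width") <- bin_width
  attr(out, "window") <- window
  attr(out, "pattern") <- pattern
  class(out) <- "ebox_profile"
  out
}

#' @export
print.ebox_profile <- function(x, ...) {
  cat(sprintf("E-box profile (%s), window %d..%d, bin %d bp\n",
              attr(x, "pattern"), attr(x, "window")[1], attr(x, "window")[2],
              attr(x, "bin_width")))
  for (g in x) {
    cat(sprintf("  %-5s: %d sites in %d promoters (mean %.2f/promoter)\n",
                g$group_label, length(g$offsets), length(g$counts),
                if (length(g$counts)) mean(g$counts) else 0))
  }
  invisible(x)
}

#' Plot an E-box positional profile
#'
#' @param x An `ebox_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ebox_profile <- function(x, ...) {
  cols <- c(all = "black", up = "red", down = "blue")
  first <- TRUE
  for (g in x) {
    if (is.null(g$kernel)) next
    if (first) {
      graphics::plot(g$kernel, col = cols[[g$group_label]], main = "",
                     xlab = "offset from TSS (bp)", ylab = "density", ...)
      first <- FALSE
    } else {
      graphics::lines(g$kernel, col = cols[[g$group_label]])
    }
  }
  graphics::legend("topleft", legend = names(x), col = cols[names(x)],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Compare E-box count distributions between direction groups
#'
#' Builds the 2x2 table (rows: promoters with >= k E-boxes vs fewer;
#' columns: up vs down) and applies the Fisher exact test.
#'
#' @param counts_up,counts_down Integer vectors of per-promoter E-box
#'   counts for the up- and down-regulated groups (non-empty).
#' @param k Count threshold defining the first row (default 2, the
#'   "promoters with two E-boxes" comparison).
#' @param alternative Passed to [stats::fisher.test()]; default two-sided.
#' @return List with elements table (2x2), p, estimate (odds ratio), k.
#' @export
compare_count_distributions <- function(counts_up, counts_down, k = 2,
                                        alternative = "two.sided") {
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  if (!length(counts_up) || !length(counts_down)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  tab <- rbind(`>=k` = c(up = sum(counts_up >= k), down = sum(counts_down >= k)),
               `<k` = c(up = sum(counts_up < k), down = sum(counts_down < k)))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(table = tab, p = ft$p.value, estimate = unname(ft$estimate), k = k)
}

#' Write the offsets and count tables of a profile as TSV
#'
#' @param profile An `ebox_profile`.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_ebox_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  off <- do.call(rbind, lapply(profile, function(g) {
    if (!length(g$offsets)) return(NULL)
    data.frame(offset = g$offsets, group = g$group_label)
  }))
  p1 <- file.path(dir, "ebox_offsets.tsv")
  utils::write.table(off %||% data.frame(offset = integer(), group = character()),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- do.call(rbind, lapply(profile, function(g) {
    if (!length(g$counts)) return(NULL)
    data.frame(gene_id = names(g$counts), count = as.integer(g$counts),
               group = g$group_label)
  }))
  cnt <- cnt %||% data.frame(gene_id = character(), count = integer(),
                             group = character())
  p2 <- file.path(dir, "ebox_counts.tsv")
  utils::write.table(cnt, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
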