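# Overlap of a responsive gene set with a clustered target-gene catalog.
#
# The expectation is the hypergeometric mean over a declared universe:
# expected = |responsive ∩ universe| * |scope| / |universe|. The test is a
# 1-df goodness-of-fit chi-square of the (target, non-target) split of the
# responsive set against that expectation — the only framing consistent
# with reporting (observed, expected, total) triples. The universe is a
# required, logged input; it is never inferred implicitly.

#' Build a clustered target-gene catalog
#'
#' @param clusters Named list of character vectors (cluster id -> gene
#'   ids). Clusters must be pairwise disjoint and contained in the
#'   universe.
#' @param universe Character vector: all genes over which expectations are
#'   computed.
#' @return Object of class `target_catalog` with elements clusters,
#'   universe.
#' @export
target_catalog <- function(clusters, universe) {
  if (length(clusters) &&
      (is.null(names(clusters)) || any(names(clusters) == ""))) {
    stop("clusters must be named", call. = FALSE)
  }
  universe <- unique(as.character(universe))
  all_members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("clusters must be pairwise disjoint", call. = FALSE)
  }
  outside <- setdiff(all_members, universe)
  if (length(outside)) {
    stop(length(outside), " cluster gene(s) outside the universe",
         call. = FALSE)
  }
  structure(list(clusters = lapply(clusters, as.character),
                 universe = universe),
            class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  cat(sprintf("target_catalog: %d clusters, %d target genes, universe %d\n",
              length(x$clusters), length(unlist(x$clusters)),
              length(x$universe)))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %s: %d genes\n", nm, length(x$clusters[[nm]])))
  }
  invisible(x)
}

#' Collapse a probe list to unique gene ids
#'
#' Each gene appears once regardless of probe multiplicity; probes missing
#' from the mapping are dropped (the number dropped is attached as
#' attribute `dropped`).
#'
#' @param probes Character vector of probe ids.
#' @param mapping Named character vector or two-column data.frame
#'   (probe_id, gene_id).
#' @return Character vector of unique gene ids, attribute `dropped`.
#' @export
dedup_to_genes <- function(probes, mapping) {
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping[[2]]),
                               as.character(mapping[[1]]))
  }
  genes <- mapping[as.character(probes)]
  dropped <- sum(is.na(genes))
  out <- unique(unname(genes[!is.na(genes)]))
  attr(out, "dropped") <- dropped
  out
}

#' Expected overlap under independence (hypergeometric mean)
#'
#' `expected = |responsive ∩ universe| * |scope| / |universe|`. Responsive
#' genes outside the universe are dropped (count attached as attribute
#' `outside_universe`).
#'
#' @param responsive Character vector of responsive gene ids.
#' @param catalog A `target_catalog`.
#' @param scope `"total"` (union of all clusters) or a cluster id.
#' @return Expected count (numeric), attribute `outside_universe`.
#' @export
expected_overlap <- function(responsive, catalog, scope = "total") {
  if (!length(catalog$universe)) stop("empty universe", call. = FALSE)
  responsive <- unique(as.character(responsive))
  inside <- intersect(responsive, catalog$universe)
  scope_set <- scope_genes(catalog, scope)
  out <- length(inside) * length(scope_set) / length(catalog$universe)
  attr(out, "outside_universe") <- length(responsive) - length(inside)
  out
}

scope_genes <- function(catalog, scope) {
  if (identical(scope, "total")) {
    unique(unlist(catalog$clusters, use.names = FALSE))
  } else {
    if (!scope %in% names(catalog$clusters)) {
      stop("unknown cluster: ", scope, call. = FALSE)
    }
    catalog$clusters[[scope]]
  }
}

#' 1-df goodness-of-fit chi-square of observed vs expected overlap
#'
#' `chi2 = (o - e)^2 / e + ((t - o) - (t - e))^2 / (t - e)` with no
#' continuity correction; upper-tail p at 1 df.
#'
#' @param observed Observed overlap count.
#' @param expected Expected overlap count, `0 < expected < total`.
#' @param total Size of the responsive set being split.
#' @return List with chi2 and p.
#' @export
chisq_observed_vs_expected <- function(observed, expected, total) {
  if (expected <= 0) stop("'expected' must be > 0", call. = FALSE)
  if (expected >= total) stop("'expected' must be < total", call. = FALSE)
  chi2 <- (observed - expected)^2 / expected +
    (observed - expected)^2 / (total - expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Overlap enrichment analysis of a responsive set against a catalog
#'
#' Runs dedup (optional), expectation and chi-square for the whole catalog
#' and each cluster, splitting each overlap by differential-expression
#' direction when available; a binomial sign test describes the up/down
#' split. Control catalogs get the identical machinery.
#'
#' @param responsive A `de_result` table (direction column used for
#'   splits) or a character vector of responsive gene ids.
#' @param catalog A `target_catalog`.
#' @param control_catalogs Optional named list of `target_catalog` objects
#'   analysed identically.
#' @param mapping Optional probe-to-gene mapping applied to the responsive
#'   ids through [dedup_to_genes()].
#' @return data.frame of class `overlap_result`: catalog, scope, observed,
#'   expected, chi2, p, up_in_overlap, down_in_overlap, p_sign.
#' @export
overlap_analysis <- function(responsive, catalog, control_catalogs = NULL,
                             mapping = NULL) {
  directions <- NULL
  if (inherits(responsive, "de_result") || is.data.frame(responsive)) {
    keep <- responsive$direction != "ns"
    directions <- stats::setNames(responsive$direction[keep],
                                  responsive$gene_id[keep])
    responsive <- responsive$gene_id[keep]
  }
  if (!is.null(mapping)) {
    responsive <- dedup_to_genes(responsive, mapping)
  }
  responsive <- unique(as.character(responsive))
  one_catalog <- function(cat, label) {
    inside <- intersect(responsive, cat$universe)
    total <- length(inside)
    scopes <- c("total", names(cat$clusters))
    rows <- lapply(scopes, function(sc) {
      sg <- scope_genes(cat, sc)
      if (!length(intersect(sg, cat$universe))) {
        warning("cluster ", sc, " absent from universe, skipped")
        return(NULL)
      }
      ov <- intersect(inside, sg)
      e <- length(inside) * length(sg) / length(cat$universe)
      test <- if (e > 0 && e < total) {
        chisq_observed_vs_expected(length(ov), e, total)
      } else list(chi2 = NA_real_, p = NA_real_)
      up <- dn <- NA_integer_
      p_sign <- NA_real_
      if (!is.null(directions)) {
        up <- sum(directions[ov] == "up")
        dn <- sum(directions[ov] == "down")
        if (up + dn > 0) {
          p_sign <- stats::binom.test(up, up + dn, 0.5)$p.value
        }
      }
      data.frame(catalog = label, scope = sc, observed = length(ov),
                 expected = e, chi2 = test$chi2, p = test$p,
                 up_in_overlap = up, down_in_overlap = dn,
                 p_sign = p_sign, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- one_catalog(catalog, "primary")
  for (nm in names(control_catalogs)) {
    out <- rbind(out, one_catalog(control_catalogs[[nm]], nm))
  }
  rownames(out) <- NULL
  attr(out, "n_responsive") <- length(responsive)
  class(out) <- c("overlap_result", "data.frame")
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap analysis: %d responsive genes\n",
              attr(x, "n_responsive")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
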