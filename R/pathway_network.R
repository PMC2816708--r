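# Pathway over-representation and bipartite pathway-gene network
# reconstruction with critical-gene identification.

#' Read a GMT gene-set file
#'
#' One pathway per line: id, description, then members (tab-separated).
#' Duplicate members within a line are removed.
#'
#' @param path GMT path.
#' @return Named list of pathways; each element is a character vector of
#'   members with the description in attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    attr(members, "description") <- fields[2]
    out[[fields[1]]] <- members
  }
  out
}

#' Write a pathway catalog as GMT
#'
#' @param pathways Named list of member vectors (optional `description`
#'   attributes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    desc <- attr(pathways[[nm]], "description") %||% nm
    paste(c(nm, desc, pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher exact enrichment of one pathway
#'
#' One-sided (over-representation) Fisher exact test on the 2x2 table
#' in-pathway x significant over a declared universe. The direction label
#' is the majority sign of the significant in-pathway genes ("mixed" on a
#' tie or when directions are unavailable).
#'
#' @param sig_genes Character vector of significant gene ids, or a
#'   `de_result` table (responsive genes and their directions are taken
#'   from it).
#' @param members Character vector: pathway members.
#' @param universe Character vector: the declared gene universe.
#' @return List: genes_total (pathway members in the universe),
#'   genes_significant, p_fisher, direction.
#' @export
fisher_pathway <- function(sig_genes, members, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  directions <- NULL
  if (is.data.frame(sig_genes)) {
    keep <- sig_genes$direction != "ns"
    directions <- stats::setNames(sig_genes$direction[keep],
                                  sig_genes$gene_id[keep])
    sig_genes <- sig_genes$gene_id[keep]
  }
  universe <- unique(universe)
  sig <- intersect(unique(sig_genes), universe)
  mem <- intersect(unique(members), universe)
  overlap <- intersect(sig, mem)
  # P(X >= |overlap|), X ~ Hypergeom(|mem| in pathway, drawn |sig|)
  p <- stats::phyper(length(overlap) - 1L, length(mem),
                     length(universe) - length(mem), length(sig),
                     lower.tail = FALSE)
  direction <- "mixed"
  if (!is.null(directions) && length(overlap)) {
    nup <- sum(directions[overlap] == "up")
    ndn <- sum(directions[overlap] == "down")
    if (nup > ndn) direction <- "up" else if (ndn > nup) direction <- "down"
  }
  list(genes_total = length(mem), genes_significant = length(overlap),
       p_fisher = p, direction = direction)
}

#' Pathway enrichment table
#'
#' Applies [fisher_pathway()] to every pathway and reports raw and
#' BH-adjusted p-values side by side (the correction method behind
#' published "corrected" pathway p-values is rarely stated, so both are
#' emitted).
#'
#' @param sig_genes Significant genes or a `de_result` table.
#' @param pathways Named list of pathways (as from [read_gmt()]).
#' @param universe Declared gene universe.
#' @return data.frame of class `pathway_enrichment`: pathway_id,
#'   description, direction, genes_total, genes_significant, p_raw, p_bh;
#'   ordered by p_raw.
#' @export
pathway_enrich <- function(sig_genes, pathways, universe) {
  rows <- lapply(names(pathways), function(nm) {
    fp <- fisher_pathway(sig_genes, pathways[[nm]], universe)
    data.frame(pathway_id = nm,
               description = attr(pathways[[nm]], "description") %||% nm,
               direction = fp$direction, genes_total = fp$genes_total,
               genes_significant = fp$genes_significant,
               p_raw = fp$p_fisher, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(), description = character(),
                      direction = character(), genes_total = integer(),
                      genes_significant = integer(), p_raw = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$p_bh <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_enrichment", "data.frame")
  out
}

#' Build the bipartite pathway-gene network
#'
#' Nodes are pathways with at least one significant member gene plus those
#' genes; edges are memberships of significant genes. Pathways are flagged
#' significant at `p_cut` on the raw Fisher p. A gene's hub score is its
#' degree (number of pathways containing it). Node ordering is
#' deterministic (pathways then genes, each sorted).
#'
#' @param enrichments A `pathway_enrichment` table.
#' @param pathways The pathway catalog the enrichment was computed from.
#' @param sig_genes Significant genes or a `de_result` table.
#' @param p_cut Pathway significance flag threshold (default 0.05).
#' @return Object of class `bipartite_network`: graph (igraph, vertex
#'   attribute `type` TRUE for genes), pathways (data.frame with
#'   significance flags), genes (data.frame with hub scores), edges.
#' @export
build_bipartite <- function(enrichments, pathways, sig_genes,
                            p_cut = 0.05) {
  if (is.data.frame(sig_genes)) {
    sig_genes <- sig_genes$gene_id[sig_genes$direction != "ns"]
  }
  sig_genes <- unique(as.character(sig_genes))
  edges <- do.call(rbind, lapply(names(pathways), function(nm) {
    g <- intersect(pathways[[nm]], sig_genes)
    if (!length(g)) return(NULL)
    data.frame(pathway = nm, gene = sort(g), stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(pathway = character(), gene = character(),
                        stringsAsFactors = FALSE)
  }
  pnodes <- sort(unique(edges$pathway))
  gnodes <- sort(unique(edges$gene))
  sig_flag <- stats::setNames(enrichments$p_raw <= p_cut,
                              enrichments$pathway_id)
  pdf <- data.frame(pathway_id = pnodes,
                    significant = unname(sig_flag[pnodes]),
                    p_raw = enrichments$p_raw[match(pnodes,
                                                    enrichments$pathway_id)],
                    stringsAsFactors = FALSE)
  hub <- table(factor(edges$gene, levels = gnodes))
  gdf <- data.frame(gene_id = gnodes, hub_score = as.integer(hub),
                    stringsAsFactors = FALSE)
  graph <- igraph::make_empty_graph(directed = FALSE)
  if (length(pnodes) + length(gnodes) > 0) {
    graph <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = c(pnodes, gnodes),
                            type = c(rep(FALSE, length(pnodes)),
                                     rep(TRUE, length(gnodes)))))
  }
  structure(list(graph = graph, pathways = pdf, genes = gdf,
                 edges = edges, p_cut = p_cut),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d pathways (%d significant), %d genes, %d edges\n",
              nrow(x$pathways), sum(x$pathways$significant, na.rm = TRUE),
              nrow(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Plot a bipartite pathway-gene network
#'
#' Pathways as circles (red when significant, grey otherwise), genes as
#' squares shaded by hub score.
#'
#' @param x A `bipartite_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.bipartite_network <- function(x, ...) {
  g <- x$graph
  if (igraph::vcount(g) == 0) {
    graphics::plot.new(); graphics::title("empty network"); return(invisible(x))
  }
  type <- igraph::V(g)$type
  shape <- ifelse(type, "square", "circle")
  sig <- x$pathways$significant[match(igraph::V(g)$name, x$pathways$pathway_id)]
  hub <- x$genes$hub_score[match(igraph::V(g)$name, x$genes$gene_id)]
  maxhub <- max(hub, 1L, na.rm = TRUE)
  col <- ifelse(type,
                grDevices::rgb(0, 0.35 + 0.6 * (1 - (hub %||% 0) / maxhub), 0),
                ifelse(!is.na(sig) & sig, "red", "grey70"))
  igraph::plot.igraph(g, vertex.shape = shape, vertex.color = col,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Identify critical (hub) genes
#'
#' Genes connected to at least `k` significant pathways, ranked by hub
#' score (ties broken alphabetically for determinism).
#'
#' @param network A `bipartite_network`.
#' @param k Minimum number of significant pathways (default 2).
#' @return data.frame: gene_id, n_significant_pathways, hub_score.
#' @export
critical_genes <- function(network, k = 2) {
  sig_paths <- network$pathways$pathway_id[
    !is.na(network$pathways$significant) & network$pathways$significant]
  e <- network$edges[network$edges$pathway %in% sig_paths, , drop = FALSE]
  nsig <- table(factor(e$gene, levels = network$genes$gene_id))
  out <- data.frame(gene_id = network$genes$gene_id,
                    n_significant_pathways = as.integer(nsig),
                    hub_score = network$genes$hub_score,
                    stringsAsFactors = FALSE)
  out <- out[out$n_significant_pathways >= k, , drop = FALSE]
  out <- out[order(-out$hub_score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a bipartite network
#'
#' Writes an edge-list TSV and a GraphML file.
#'
#' @param network A `bipartite_network`.
#' @param path_tsv Edge-list TSV path.
#' @param path_graphml Optional GraphML path.
#' @return Paths written, invisibly.
#' @export
write_network <- function(network, path_tsv, path_graphml = NULL) {
  utils::write.table(network$edges, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_graphml)) {
    igraph::write_graph(network$graph, path_graphml, format = "graphml")
  }
  invisible(c(path_tsv, path_graphml))
}
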