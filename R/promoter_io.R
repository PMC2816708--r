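# Genome/TSS input and strand-aware promoter window extraction.
#
# Coordinates are 0-based half-open throughout; BED is consumed natively.
# The TSS base is the first "downstream" base (offset 0), so an up/down
# window has length exactly window_up + window_down when unclipped.

#' Read a FASTA file into a named character vector
#'
#' Sequences are case-folded to upper case. Record names must be unique and
#' sequences must contain only IUPAC nucleotide letters.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(nms[bad], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- nms
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read transcription start sites from a BED6 file
#'
#' The TSS is the 0-based coordinate of the transcription-start base: for
#' `+` strand genes `tss = start`, for `-` strand genes `tss = end - 1`.
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score, strand).
#' @return data.frame with columns gene_id, chrom, tss (0-based), strand.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("BED strand must be '+' or '-' for every record", call. = FALSE)
  }
  gene_id <- gr$name
  if (is.null(gene_id) || anyNA(gene_id)) {
    stop("BED name column (gene id) is required", call. = FALSE)
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene ids in TSS table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  start0 <- BiocGenerics::start(gr) - 1L   # back to 0-based
  end0 <- BiocGenerics::end(gr)            # half-open end
  data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "+", start0, end0 - 1L),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Extract strand-aware promoter windows
#'
#' For a `+` strand gene the genomic half-open interval
#' `[tss - window_up, tss + window_down)` is taken as-is; for a `-` strand
#' gene the interval `[tss - window_down + 1, tss + window_up + 1)` is taken
#' and reverse-complemented, so every returned sequence reads 5' to 3' on
#' the gene's own strand with the TSS base at position `window_up + 1`
#' (1-based) unless left-clipped.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param tss data.frame as returned by [read_tss_bed()].
#' @param window_up,window_down Non-negative window sizes in bp. The two
#'   presets used throughout are (1000, 200) for motif over-representation
#'   and (3000, 500) for E-box positional analysis.
#' @param clip If `TRUE`, windows are truncated at chromosome ends; if
#'   `FALSE` an out-of-bounds window is an error.
#' @return A `promoter_set`: data.frame with columns gene_id, seq,
#'   tss_offset (signed offset of the first base of seq relative to the
#'   TSS), window_up, window_down.
#' @export
extract_promoters <- function(genome, tss, window_up, window_down,
                              clip = FALSE) {
  if (window_up < 0 || window_down < 0) {
    stop("window sizes must be non-negative", call. = FALSE)
  }
  missing_chrom <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("chromosomes absent from genome: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  chrom_len <- nchar(genome)[tss$chrom]
  plus <- tss$strand == "+"
  gstart <- ifelse(plus, tss$tss - window_up, tss$tss - window_down + 1L)
  gend <- ifelse(plus, tss$tss + window_down, tss$tss + window_up + 1L)
  oob <- gstart < 0L | gend > chrom_len
  if (any(oob) && !clip) {
    stop("promoter window outside chromosome for gene(s): ",
         paste(tss$gene_id[oob], collapse = ", "),
         " (set clip = TRUE to truncate)", call. = FALSE)
  }
  cstart <- pmax(gstart, 0L)
  cend <- pmin(gend, chrom_len)
  cend <- pmax(cend, cstart)  # fully out-of-range -> empty
  seq <- substr(genome[tss$chrom], cstart + 1L, cend)
  # offset of the first returned base relative to the TSS, gene orientation:
  # + strand: cstart - tss; - strand: first base is the genomic end - 1.
  offset <- ifelse(plus, cstart - tss$tss, tss$tss - (cend - 1L))
  seq[!plus] <- revcomp(seq[!plus])
  out <- data.frame(
    gene_id = tss$gene_id,
    seq = unname(seq),
    tss_offset = as.integer(offset),
    window_up = as.integer(window_up),
    window_down = as.integer(window_down),
    stringsAsFactors = FALSE
  )
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Write a promoter set as FASTA
#'
#' Headers carry the window metadata as
#' `gene_id|tss_offset|window_up|window_down` so a promoter set round-trips.
#'
#' @param promoters A `promoter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- promoters$seq
  names(seqs) <- sprintf("%s|%d|%d|%d", promoters$gene_id,
                         promoters$tss_offset, promoters$window_up,
                         promoters$window_down)
  write_fasta(seqs, path)
}

#' Read a promoter set written by [write_promoters()]
#'
#' @param path Path to a promoter FASTA with structured headers.
#' @return A `promoter_set` data.frame.
#' @export
read_promoters <- function(path) {
  set <- Biostrings::readBStringSet(path)
  fields <- strsplit(names(set), "|", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop("promoter FASTA headers must be gene_id|tss_offset|window_up|window_down",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    gene_id = m[, 1],
    seq = toupper(as.character(set)),
    tss_offset = as.integer(m[, 2]),
    window_up = as.integer(m[, 3]),
    window_down = as.integer(m[, 4]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters, window -%d/+%d\n",
              nrow(x), x$window_up[1] %||% 0L, x$window_down[1] %||% 0L))
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    show$seq <- paste0(substr(show$seq, 1, 30),
                       ifelse(nchar(show$seq) > 30, "...", ""))
    print.data.frame(show)
    if (nrow(x) > 5L) cat("... and", nrow(x) - 5L, "more\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
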