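# Motif matrix parsing and occurrence scanning.
#
# Scanning follows the MotifScanner convention: a width-w window is a hit
# when the log-odds of the window under the motif versus an order-0
# background exceeds log((1 - prior)/prior), i.e. when the posterior odds
# of "motif" versus "background" exceed 1 given a prior site probability
# per window. The prior is the single tunable knob (0.1 in the settings
# this package mirrors).

#' Construct a motif matrix
#'
#' Builds a position frequency matrix from counts or frequencies. Counts
#' are regularized with a pseudocount distributed proportionally to the
#' background frequencies: `freq[j, b] = (count[j, b] + pc * bg[b]) /
#' (sum(count[j, ]) + pc)`.
#'
#' @param id Matrix identifier (e.g. `"M00119-V$MAX_01"`).
#' @param counts Numeric width x 4 matrix of base counts or probabilities,
#'   columns in A, C, G, T order.
#' @param pseudocount Total pseudocount mass per position (default 0.01).
#' @param bg 4-vector of background base probabilities used to distribute
#'   the pseudocount (default uniform).
#' @return An object of class `motif_matrix` with elements id, width,
#'   freqs (width x 4, rows summing to 1) and pseudocount.
#' @export
motif_matrix <- function(id, counts, pseudocount = 0.01,
                         bg = rep(0.25, 4)) {
  bg <- stopifnot_prob_vector(bg, "bg")
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L || nrow(counts) < 1L) {
    stop("'counts' must be a width x 4 matrix with width >= 1", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("'counts' must be finite and non-negative", call. = FALSE)
  }
  freqs <- sweep(counts + outer(rep(1, nrow(counts)), bg) * pseudocount,
                 1, rowSums(counts) + pseudocount, "/")
  dimnames(freqs) <- list(NULL, DNA_BASES)
  if (any(abs(rowSums(freqs) - 1) > 1e-9)) {
    stop("matrix rows failed to normalize", call. = FALSE)
  }
  structure(list(id = id, width = nrow(freqs), freqs = freqs,
                 pseudocount = pseudocount),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix %s: width %d, consensus %s\n",
              x$id, x$width, consensus(x)))
  invisible(x)
}

#' Consensus string of a motif matrix (argmax base per position)
#'
#' @param motif A `motif_matrix`.
#' @return Character scalar.
#' @export
consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$freqs, 1, which.max)], collapse = "")
}

#' Parse TRANSFAC flat-format count matrices
#'
#' Recognizes `AC`, `ID`, `P0`/`PO` and numbered count rows; blocks end at
#' `//`. The matrix id is `"<AC>-<ID>"` when both are present.
#'
#' @param text Character scalar (whole file) or vector of lines; a path to
#'   an existing file is also accepted.
#' @param pseudocount,bg Passed to [motif_matrix()].
#' @return List of `motif_matrix` objects.
#' @export
parse_transfac <- function(text, pseudocount = 0.01, bg = rep(0.25, 4)) {
  lines <- as_lines(text)
  out <- list()
  ac <- id <- NA_character_
  rows <- list()
  flush <- function() {
    if (length(rows)) {
      mid <- if (!is.na(ac) && !is.na(id)) paste0(ac, "-", id)
             else if (!is.na(ac)) ac else id
      counts <- do.call(rbind, rows)
      out[[length(out) + 1L]] <<- motif_matrix(mid, counts, pseudocount, bg)
    }
    ac <<- NA_character_; id <<- NA_character_; rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^AC\\s", ln)) { ac <- sub("^AC\\s+", "", ln); next }
    if (grepl("^ID\\s", ln)) { id <- sub("^ID\\s+", "", ln); next }
    if (grepl("^P[O0]\\s", ln)) next
    if (grepl("^[0-9]+\\s", ln)) {
      fields <- strsplit(ln, "\\s+")[[1]][-1]
      num <- suppressWarnings(as.numeric(fields))
      num <- num[!is.na(num)]
      if (length(num) != 4L) {
        stop(sprintf("line %d: expected 4 count values, got %d",
                     i, length(num)), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- num
    }
  }
  flush()
  out
}

#' Parse JASPAR PFM format
#'
#' Accepts the bracketed 4-line layout (`A [ 4 19 0 ]` ...) with or without
#' base-letter prefixes, one matrix per `>` header.
#'
#' @inheritParams parse_transfac
#' @return List of `motif_matrix` objects.
#' @export
parse_jaspar_pfm <- function(text, pseudocount = 0.01, bg = rep(0.25, 4)) {
  lines <- as_lines(text)
  out <- list()
  id <- NA_character_
  rows <- list()
  flush_at <- function(line_no) {
    if (!length(rows)) return(invisible())
    if (length(rows) != 4L) {
      stop(sprintf("line %d: JASPAR block for '%s' must have 4 base rows",
                   line_no, id), call. = FALSE)
    }
    if (length(unique(lengths(rows))) != 1L) {
      stop(sprintf("line %d: ragged JASPAR rows for '%s'", line_no, id),
           call. = FALSE)
    }
    counts <- t(do.call(rbind, rows))  # positions x 4
    out[[length(out) + 1L]] <<- motif_matrix(id, counts, pseudocount, bg)
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, ">")) {
      flush_at(i)
      id <- trimws(sub("^>", "", ln))
      id <- gsub("\\s+", " ", id)
      next
    }
    ln <- sub("^[ACGTacgt]\\s*", "", ln)
    ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num) || !length(num)) {
      stop(sprintf("line %d: cannot parse JASPAR count row", i),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- num
  }
  flush_at(length(lines))
  out
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

#' Construct an order-0 background model
#'
#' @param x Either a 4-vector of base probabilities (A, C, G, T) or a
#'   character vector of sequences from which base frequencies are counted
#'   (N and other ambiguity codes are ignored).
#' @param label Free-text provenance label.
#' @return Object of class `background_model` with elements freqs, label.
#' @export
background_model <- function(x, label = "user") {
  if (is.numeric(x)) {
    freqs <- stopifnot_prob_vector(x, "background freqs")
  } else {
    tab <- table(factor(strsplit(paste(x, collapse = ""), "")[[1]],
                        levels = DNA_BASES))
    if (sum(tab) == 0L) stop("no A/C/G/T bases to count", call. = FALSE)
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- DNA_BASES
  }
  if (any(freqs <= 0)) {
    stop("background frequencies must all be positive", call. = FALSE)
  }
  structure(list(freqs = freqs, label = label), class = "background_model")
}

empty_hits <- function() {
  data.frame(gene_id = character(), matrix_id = character(),
             offset = integer(), strand = character(),
             site_seq = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan promoters for exact (IUPAC) consensus matches
#'
#' Reports all and only exact matches of the pattern, IUPAC ambiguity codes
#' expanded. Windows containing N never match. With `strands = "both"`,
#' minus-strand hits are reported at the offset of the site's first base in
#' promoter orientation; when the pattern equals its own reverse complement
#' (as CACGTG does) the strand duplicates are collapsed to one `+` hit.
#'
#' @param promoters A `promoter_set`.
#' @param pattern IUPAC consensus string.
#' @param strands `"both"` or `"forward"`.
#' @return data.frame of hits: gene_id, matrix_id (the pattern), offset
#'   (signed bp of the site's first base relative to the TSS), strand,
#'   site_seq (as read on the hit strand), score (NA for consensus hits).
#' @export
scan_consensus <- function(promoters, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) stop("'pattern' must be non-empty", call. = FALSE)
  letters_p <- strsplit(pattern, "")[[1]]
  if (any(!letters_p %in% names(IUPAC_MAP))) {
    stop("invalid IUPAC letter(s) in pattern: ",
         paste(setdiff(letters_p, names(IUPAC_MAP)), collapse = ", "),
         call. = FALSE)
  }
  rc <- revcomp(pattern)
  palindrome <- identical(rc, pattern)
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    seq <- promoters$seq[i]
    w <- nchar(pattern)
    if (nchar(seq) < w) return(NULL)
    fwd <- consensus_positions(seq, pattern)
    hits <- if (length(fwd)) {
      data.frame(pos = fwd, strand = "+", stringsAsFactors = FALSE)
    } else NULL
    if (strands == "both" && !palindrome) {
      rev_pos <- consensus_positions(seq, rc)
      if (length(rev_pos)) {
        hits <- rbind(hits, data.frame(pos = rev_pos, strand = "-",
                                       stringsAsFactors = FALSE))
      }
    }
    if (is.null(hits) || !nrow(hits)) return(NULL)
    site <- substr(rep(seq, nrow(hits)), hits$pos, hits$pos + w - 1L)
    site[hits$strand == "-"] <- revcomp(site[hits$strand == "-"])
    data.frame(gene_id = promoters$gene_id[i], matrix_id = pattern,
               offset = promoters$tss_offset[i] + hits$pos - 1L,
               strand = hits$strand, site_seq = site, score = NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty_hits() else res[order(res$gene_id, res$offset), ]
}

# 1-based start positions of exact IUPAC matches; subject letters literal,
# so N in the subject never matches an A/C/G/T pattern letter. Windows
# containing N are excluded outright (even against an N pattern letter).
consensus_positions <- function(seq, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = "subject")
  pos <- BiocGenerics::start(m)
  if (length(pos)) {
    site <- substr(rep(seq, length(pos)), pos, pos + nchar(pattern) - 1L)
    pos <- pos[!grepl("N", site, fixed = TRUE)]
  }
  pos
}

#' Scan promoters with a PWM under a posterior-odds prior threshold
#'
#' A window `w` is a hit iff
#' `log(P(w | motif) / P(w | background)) > log((1 - prior)/prior)`
#' (natural log). Both strands are scanned when requested, the minus strand
#' by scoring the reverse-complemented window against the same matrix; a
#' self-reverse-complementary window that passes on both strands is one
#' physical site and is reported once. Windows containing N are skipped;
#' the number skipped per promoter is attached as attribute `skipped`.
#'
#' @param promoters A `promoter_set`.
#' @param motif A `motif_matrix`.
#' @param bg A `background_model`.
#' @param prior Prior window probability of a site, in (0, 1); default 0.1.
#' @param strands `"both"` or `"forward"`.
#' @return data.frame of hits (as in [scan_consensus()]) with log-odds
#'   scores.
#' @export
scan_pwm <- function(promoters, motif, bg, prior = 0.1,
                     strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif_matrix"), inherits(bg, "background_model"))
  if (!(prior > 0 && prior < 1)) {
    stop("'prior' must be strictly between 0 and 1", call. = FALSE)
  }
  if (any(bg$freqs <= 0)) stop("zero background frequency", call. = FALSE)
  threshold <- log((1 - prior) / prior)
  lodds <- log(motif$freqs) - matrix(log(bg$freqs), nrow = motif$width,
                                     ncol = 4L, byrow = TRUE)
  w <- motif$width
  skipped <- integer(nrow(promoters))
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    seq <- promoters$seq[i]
    L <- nchar(seq)
    if (L < w) return(NULL)
    enc <- encode_dna(seq)
    fwd <- window_scores(enc, lodds)
    rows <- NULL
    ok <- !is.na(fwd) & fwd > threshold
    if (any(ok)) {
      rows <- data.frame(pos = which(ok), strand = "+",
                         score = fwd[ok], stringsAsFactors = FALSE)
    }
    if (strands == "both") {
      enc_rc <- rev(5L - enc)  # A<->T, C<->G on reversed sequence
      rev_sc <- window_scores(enc_rc, lodds)
      okr <- !is.na(rev_sc) & rev_sc > threshold
      if (any(okr)) {
        p <- which(okr)
        rows <- rbind(rows, data.frame(pos = L - p - w + 2L, strand = "-",
                                       score = rev_sc[okr],
                                       stringsAsFactors = FALSE))
      }
    }
    skipped[i] <<- sum(is.na(fwd))
    if (is.null(rows)) return(NULL)
    fwd_window <- substr(rep(seq, nrow(rows)), rows$pos, rows$pos + w - 1L)
    # a self-reverse-complementary window hit on both strands is one
    # physical site: keep the + copy only
    dup <- rows$strand == "-" & fwd_window == revcomp(fwd_window) &
      rows$pos %in% rows$pos[rows$strand == "+"]
    if (any(dup)) {
      rows <- rows[!dup, , drop = FALSE]
      fwd_window <- fwd_window[!dup]
    }
    site <- fwd_window
    site[rows$strand == "-"] <- revcomp(site[rows$strand == "-"])
    data.frame(gene_id = promoters$gene_id[i], matrix_id = motif$id,
               offset = promoters$tss_offset[i] + rows$pos - 1L,
               strand = rows$strand, site_seq = site, score = rows$score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- if (is.null(res)) empty_hits() else res[order(res$gene_id, res$offset), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- stats::setNames(skipped, promoters$gene_id)
  res
}

# Log-odds score of every width-w window of an encoded sequence; windows
# overlapping an ambiguous base (NA code) score NA.
window_scores <- function(enc, lodds) {
  w <- nrow(lodds)
  n <- length(enc) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    v <- lodds[j, ][enc[j:(j + n - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Count PWM hits per matrix across a promoter set
#'
#' `n` counts hit instances (one promoter may contribute several);
#' `genes_hit` counts promoters with at least one hit. Rows are ordered by
#' matrix id for determinism.
#'
#' @param promoters A `promoter_set`.
#' @param matrices List of `motif_matrix` objects.
#' @param bg A `background_model`.
#' @param prior Prior passed to [scan_pwm()].
#' @param strands Strand mode passed to [scan_pwm()].
#' @return data.frame with columns matrix_id, n, genes_hit.
#' @export
count_feature_hits <- function(promoters, matrices, bg, prior = 0.1,
                               strands = "both") {
  rows <- lapply(matrices, function(m) {
    hits <- scan_pwm(promoters, m, bg, prior, strands)
    data.frame(matrix_id = m$id, n = nrow(hits),
               genes_hit = length(unique(hits$gene_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(matrix_id = character(), n = integer(),
                      genes_hit = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$matrix_id), , drop = FALSE]
}

#' Write motif hits as TSV (and optionally BED6 in genomic coordinates)
#'
#' @param hits Hit data.frame from a scan.
#' @param path Output TSV path.
#' @param tss Optional TSS table; when given, a BED6 file of genomic hit
#'   coordinates is written next to `path` with extension `.bed`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, tss = NULL) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tss)) {
    idx <- match(hits$gene_id, tss$gene_id)
    plus <- tss$strand[idx] == "+"
    width <- nchar(hits$site_seq)
    gstart <- ifelse(plus, tss$tss[idx] + hits$offset,
                     tss$tss[idx] - hits$offset - width + 1L)
    bed <- data.frame(tss$chrom[idx], gstart, gstart + width,
                      paste0(hits$gene_id, ":", hits$matrix_id),
                      0L, ifelse(plus, hits$strand,
                                 ifelse(hits$strand == "+", "-", "+")))
    utils::write.table(bed, sub("\\.[^.]*$", ".bed", path), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
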