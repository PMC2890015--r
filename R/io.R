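#' Read a FASTA file of insert or contig sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences and enforces the `{A,C,G,T,N}` alphabet used throughout the
#' pipeline.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) stop("read_fasta: empty file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("read_fasta: no records in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  .check_alphabet(seqs, names(seqs))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read protein-homology hits in 12(+1)-column BLAST tabular format
#'
#' Expects the standard tabular columns (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore), with an
#' optional 13th free-text column read as a subject description.
#' Minus-strand hits -- rows where `qstart > qend`, or with a negative frame
#' if a `frame` is encoded -- are normalized to `query_start <= query_end`
#' with `strand = "-"`, so orientation is carried by the strand field, never
#' by coordinate order.
#'
#' @param path tab-separated hit table.
#' @return data.frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `query_start`, `query_end`, `strand`, `e_value`,
#'   `bit_score`, `description`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("read_blast_tab: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols != 12L & ncols != 13L)
  if (length(bad))
    stop(sprintf("read_blast_tab: expected 12 or 13 columns, got %d at line %d",
                 ncols[bad[1]], bad[1]))
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", i)))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("read_blast_tab: non-numeric %s at line %d", what, j))
    }
    v
  }
  qs <- num(7L, "qstart"); qe <- num(8L, "qend")
  strand <- ifelse(qs > qe, "-", "+")
  hits <- data.frame(
    query_id = vapply(parts, `[[`, "", 1L),
    subject_id = vapply(parts, `[[`, "", 2L),
    pct_identity = num(3L, "pident"),
    aln_length = as.integer(num(4L, "length")),
    query_start = as.integer(pmin(qs, qe)),
    query_end = as.integer(pmax(qs, qe)),
    strand = strand,
    e_value = num(11L, "evalue"),
    bit_score = num(12L, "bitscore"),
    description = vapply(parts, function(p)
      if (length(p) >= 13L) p[[13L]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  if (any(hits$e_value < 0)) stop("read_blast_tab: negative e-value")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             query_start = integer(0), query_end = integer(0),
             strand = character(0), e_value = numeric(0),
             bit_score = numeric(0), description = character(0),
             stringsAsFactors = FALSE)
}

#' Write hits back to 12(+1)-column tabular format
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path output file.
#' @export
write_blast_tab <- function(hits, path) {
  qs <- ifelse(hits$strand == "-", hits$query_end, hits$query_start)
  qe <- ifelse(hits$strand == "-", hits$query_start, hits$query_end)
  lines <- sprintf("%s\t%s\t%g\t%d\t0\t0\t%d\t%d\t1\t%d\t%s\t%g%s",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_length, qs, qe,
                   as.integer(ceiling(hits$aln_length / 3)),
                   format(hits$e_value, scientific = TRUE, trim = TRUE),
                   hits$bit_score,
                   ifelse(is.na(hits$description), "",
                          paste0("\t", hits$description)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 feature track
#'
#' `kind = "prediction"` expects `gene` rows with `CDS` (or `exon`) children
#' and returns a prediction track; `kind = "est"` expects `match` rows with
#' `match_part` children and returns a tidy EST alignment table.  Parsing is
#' done by [rtracklayer::import()]; this function only groups children under
#' their parents and checks referential integrity.
#'
#' @param path GFF3 file.
#' @param kind `"prediction"` or `"est"`.
#' @param model_name for predictions, the ab initio model label.
#' @param seq_length optional; when given, coordinates beyond it are an error.
#' @return For predictions, a `prediction_track` (see [prediction_track()]);
#'   for ESTs, a data.frame with one row per alignment segment (`est_id`,
#'   `source_genus`, `pct_identity`, `strand`, `seg_start`, `seg_end`).
#' @export
read_gff_track <- function(path, kind = c("prediction", "est"),
                           model_name = NA_character_, seq_length = NULL) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$Parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  if (!is.null(seq_length) && any(df$end > seq_length))
    stop("read_gff_track: coordinate beyond sequence length in ", path)
  if (kind == "prediction") {
    genes <- df[df$type == "gene", , drop = FALSE]
    mrnas <- df[df$type == "mRNA", , drop = FALSE]
    kids <- df[df$type %in% c("CDS", "exon"), , drop = FALSE]
    if (nrow(kids) && any(duplicated(paste(kids$Parent1, kids$type, kids$start))))
      kids <- kids[!duplicated(paste(kids$Parent1, kids$type, kids$start)), ]
    # resolve child -> gene through mRNA when present
    mrna2gene <- stats::setNames(mrnas$Parent1, mrnas$ID)
    parent_gene <- ifelse(kids$Parent1 %in% names(mrna2gene),
                          mrna2gene[kids$Parent1], kids$Parent1)
    orphan <- !(parent_gene %in% genes$ID)
    if (any(orphan))
      stop("read_gff_track: orphan child feature '", kids$ID[orphan][1], "'")
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      k <- kids[parent_gene == g$ID, , drop = FALSE]
      ex <- if (nrow(k)) k[order(k$start), c("start", "end")] else
        data.frame(start = g$start, end = g$end)
      sc <- suppressWarnings(as.integer(g$start_codon))
      pc <- suppressWarnings(as.integer(g$stop_codon))
      list(gene_id = g$ID, start = g$start, end = g$end,
           strand = as.character(g$strand),
           start_codon = if (!is.null(g$start_codon)) sc else NA_integer_,
           stop_codon = if (!is.null(g$stop_codon)) pc else NA_integer_,
           exons = ex)
    })
    genes_df <- data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      start = vapply(rows, function(r) as.integer(r$start), 1L),
      end = vapply(rows, function(r) as.integer(r$end), 1L),
      strand = vapply(rows, `[[`, "", "strand"),
      start_codon = vapply(rows, function(r) r$start_codon %||% NA_integer_, 1L),
      stop_codon = vapply(rows, function(r) r$stop_codon %||% NA_integer_, 1L),
      stringsAsFactors = FALSE
    )
    genes_df <- genes_df[order(genes_df$start), , drop = FALSE]
    rownames(genes_df) <- NULL
    genes_df$exons <- I(lapply(rows, `[[`, "exons")[order(
      vapply(rows, function(r) as.integer(r$start), 1L))])
    prediction_track(model_name %||% "track", genes_df)
  } else {
    matches <- df[df$type == "match", , drop = FALSE]
    parts <- df[df$type == "match_part", , drop = FALSE]
    orphan <- !(parts$Parent1 %in% matches$ID)
    if (any(orphan))
      stop("read_gff_track: orphan match_part '", parts$ID[orphan][1], "'")
    out <- lapply(seq_len(nrow(matches)), function(i) {
      m <- matches[i, ]
      p <- parts[parts$Parent1 == m$ID, , drop = FALSE]
      if (nrow(p) == 0L) p <- m
      p <- p[order(p$start), , drop = FALSE]
      data.frame(est_id = m$ID,
                 source_genus = (m$source_genus %||% NA_character_),
                 pct_identity = as.numeric(m$pct_identity %||% NA_real_),
                 strand = as.character(m$strand),
                 seg_start = as.integer(p$start), seg_end = as.integer(p$end),
                 stringsAsFactors = FALSE)
    })
    ests <- do.call(rbind, c(out, list(empty_ests())))
    .validate_est_segments(ests)
    ests
  }
}

empty_ests <- function() {
  data.frame(est_id = character(0), source_genus = character(0),
             pct_identity = numeric(0), strand = character(0),
             seg_start = integer(0), seg_end = integer(0),
             stringsAsFactors = FALSE)
}

.validate_est_segments <- function(ests) {
  if (any(ests$seg_start > ests$seg_end))
    stop("EST segment with start > end")
  for (id in unique(ests$est_id)) {
    s <- ests[ests$est_id == id, ]
    s <- s[order(s$seg_start), ]
    if (nrow(s) > 1L && any(s$seg_start[-1] <= s$seg_end[-nrow(s)]))
      stop("overlapping segments in EST '", id, "'")
  }
  invisible(TRUE)
}

#' Write a prediction track or EST table as GFF3
#' @param x a `prediction_track` or a tidy EST table.
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @export
write_gff_track <- function(x, path, seqid = "insert") {
  lines <- "##gff-version 3"
  if (inherits(x, "prediction_track")) {
    g <- x$genes
    for (i in seq_len(nrow(g))) {
      attrs <- sprintf("ID=%s", g$gene_id[i])
      if (!is.na(g$start_codon[i]))
        attrs <- paste0(attrs, ";start_codon=", g$start_codon[i],
                        ";stop_codon=", g$stop_codon[i])
      lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                                seqid, x$model_name, g$start[i], g$end[i],
                                g$strand[i], attrs))
      ex <- g$exons[[i]]
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                                  seqid, x$model_name, ex$start[j], ex$end[j],
                                  g$strand[i], g$gene_id[i], j, g$gene_id[i]))
    }
  } else {
    for (id in unique(x$est_id)) {
      s <- x[x$est_id == id, , drop = FALSE]
      s <- s[order(s$seg_start), , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\test\tmatch\t%d\t%d\t.\t%s\t.\tID=%s;pct_identity=%g;source_genus=%s",
        seqid, min(s$seg_start), max(s$seg_end), s$strand[1], id,
        s$pct_identity[1], s$source_genus[1]))
      for (j in seq_len(nrow(s)))
        lines <- c(lines, sprintf(
          "%s\test\tmatch_part\t%d\t%d\t.\t%s\t.\tID=%s.%d;Parent=%s",
          seqid, s$seg_start[j], s$seg_end[j], s$strand[1], id, j, id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
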