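#' Assemble ordered contigs into a single-insert coordinate frame
#'
#' Multi-contig fosmid inserts are analyzed in one concatenated coordinate
#' frame: contigs are joined in their given order with `gap_pad` `N`
#' characters between consecutive contigs, and each inter-contig junction is
#' recorded as a gap sentinel.  Downstream feature calls never span a gap
#' sentinel.  `total_length` is the sum of contig lengths and excludes the
#' `N` padding.
#'
#' @param contigs named character vector of contig sequences (names are
#'   contig ids), or a list of such sequences, in assembly order.
#' @param gap_pad integer, number of `N` characters inserted between
#'   consecutive contigs (nominal gap size; the true gap size is unknown).
#' @param insert_id identifier for the insert.
#' @param accession optional GenBank-style accession.
#' @return A `fosmid_record`: list with `insert_id`, `accession`,
#'   `contigs` (named character vector), `gap_positions` (data.frame with
#'   `pos`, the 1-based position in the concatenated frame of the first
#'   padding base, and `pad`), `total_length` (bp, padding excluded),
#'   `sequence` (the concatenated, padded sequence).
#' @examples
#' rec <- assemble_insert(c(c1 = "ACGT", c2 = "GGCC"), gap_pad = 2)
#' rec$total_length   # 8
#' rec$sequence       # "ACGTNNGGCC"
#' @export
assemble_insert <- function(contigs, gap_pad = 100L, insert_id = "insert",
                            accession = NA_character_) {
  if (is.list(contigs)) contigs <- unlist(contigs)
  if (length(contigs) == 0L) stop("assemble_insert: empty contig list")
  if (gap_pad < 0L) stop("assemble_insert: gap_pad must be >= 0")
  contigs <- toupper(as.character(contigs))
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    names(contigs) <- paste0("contig", seq_along(contigs))
  .check_alphabet(contigs, names(contigs))
  lens <- nchar(contigs)
  n <- length(contigs)
  if (n > 1L) {
    # first padding base after contig i sits at cum(len + pad) of the prefix
    starts <- cumsum(c(0L, lens[-n] + gap_pad)) + 1L   # contig starts in frame
    gap_pos <- starts[-1L] - gap_pad
    gaps <- data.frame(pos = as.integer(gap_pos), pad = as.integer(gap_pad))
    if (gap_pad == 0L) gaps <- data.frame(pos = as.integer(gap_pos), pad = 0L)
  } else {
    gaps <- data.frame(pos = integer(0), pad = integer(0))
  }
  seqc <- paste(contigs, collapse = strrep("N", gap_pad))
  structure(list(
    insert_id = insert_id,
    accession = accession,
    contigs = contigs,
    gap_positions = gaps,
    total_length = as.integer(sum(lens)),
    sequence = seqc
  ), class = "fosmid_record")
}

#' @export
print.fosmid_record <- function(x, ...) {
  cat(sprintf("<fosmid_record> %s%s: %d contig(s), %s bp (padded frame %s bp)\n",
              x$insert_id,
              if (!is.na(x$accession)) paste0(" [", x$accession, "]") else "",
              length(x$contigs),
              format(x$total_length, big.mark = ","),
              format(nchar(x$sequence), big.mark = ",")))
  invisible(x)
}

#' Length of the concatenated (padded) coordinate frame
#' @param record a `fosmid_record`.
#' @return integer bp including inter-contig `N` padding.
#' @export
frame_length <- function(record) nchar(record$sequence)

#' Does an interval intersect an inter-contig gap sentinel?
#' @param record a `fosmid_record`.
#' @param start,end 1-based inclusive interval in the concatenated frame.
#' @return logical.
#' @export
spans_gap <- function(record, start, end) {
  g <- record$gap_positions
  if (nrow(g) == 0L) return(FALSE)
  any(g$pos <= end & (g$pos + pmax(g$pad, 1L) - 1L) >= start)
}

.check_alphabet <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      ch <- substr(seqs[[i]], bad, bad)
      stop(sprintf("illegal character '%s' at position %d in record '%s'",
                   ch, bad, ids[[i]]))
    }
  }
  invisible(TRUE)
}
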