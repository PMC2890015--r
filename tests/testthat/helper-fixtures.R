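# Shared fixtures and independent oracles, built in code at test time.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Brute-force SSR oracle: examines every (position, unit length) pair.
# A tract is reported at position i with unit length k when i starts a
# maximal periodic region (the base before i breaks the period), the k-mer
# at i is N-free and primitive, and at least min_repeats whole units of it
# follow.  Independent of the run-length encoding the scanner uses.
brute_force_ssrs <- function(sequence, min_unit = 2L, max_unit = 5L,
                             min_repeats = 5L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- list()
  for (i in seq_len(n)) {
    for (k in min_unit:max_unit) {
      if (i + k * min_repeats - 1L > n) next
      # region-start (left-maximality) condition at base level
      if (i > 1L && !is.na(chars[i - 1L]) && chars[i - 1L] != "N" &&
          i - 1L + k <= n && chars[i - 1L] == chars[i - 1L + k]) next
      motif <- paste(chars[i:(i + k - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!fosmidann::is_primitive_motif(motif)) next
      r <- 1L
      while (i + (r + 1L) * k - 1L <= n &&
             paste(chars[(i + r * k):(i + (r + 1L) * k - 1L)],
                   collapse = "") == motif) r <- r + 1L
      if (r < min_repeats) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, end = i + r * k - 1L, motif = motif,
        unit_length = k, repeat_count = r, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit_length = integer(0),
                      repeat_count = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# a single-contig record around an explicit gene sequence
make_record_with_gene <- function(upstream, gene_seq, downstream,
                                  insert_id = "fix") {
  assemble_insert(stats::setNames(paste0(upstream, gene_seq, downstream),
                                  paste0(insert_id, "_c1")),
                  insert_id = insert_id)
}

# plus-strand single-exon CDS: ATG + sense codons + stop
make_cds <- function(aa = 20L, stop_codon = "TAA") {
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, aa - 1L, TRUE), collapse = ""), stop_codon)
}

# minimal gene-site row in the pipeline's representation
make_site <- function(site_id = "s1", insert_id = "fix", start, end,
                      strand = "+", category = "known",
                      subject = "SUBJ", desc = "conserved protein",
                      evalue = 1e-30, start_codon = NA_integer_,
                      stop_codon = NA_integer_, anchor3 = NA_integer_) {
  data.frame(site_id = site_id, insert_id = insert_id, start = start,
             end = end, strand = strand, category = category,
             best_subject = subject, best_description = desc,
             best_evalue = evalue, n_hits = 1L,
             frame_anchor3 = anchor3, tier = "strict",
             start_codon = start_codon, stop_codon = stop_codon,
             truncation = "", stringsAsFactors = FALSE)
}

# one-row tidy EST table (single segment)
make_est <- function(id, start, end, identity = 97, strand = "+",
                     genus = "Fragaria") {
  data.frame(est_id = id, source_genus = genus, pct_identity = identity,
             strand = strand, seg_start = start, seg_end = end,
             stringsAsFactors = FALSE)
}

# a bare prediction track from vectors
make_track <- function(model, start, end, strand = "+",
                       start_codon = NA_integer_, stop_codon = NA_integer_,
                       ids = NULL) {
  n <- length(start)
  prediction_track(model, data.frame(
    gene_id = ids %||% sprintf("%s_p%d", model, seq_len(n)),
    start = start, end = end,
    strand = rep_len(strand, n),
    start_codon = rep_len(start_codon, n),
    stop_codon = rep_len(stop_codon, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_tracts_for_test <- function() {
  data.frame(insert_id = character(0), start = integer(0), end = integer(0),
             motif = character(0), canonical_motif = character(0),
             unit_length = integer(0), repeat_count = integer(0),
             stringsAsFactors = FALSE)
}

study_inventory <- function() {
  utils::read.delim(system.file("extdata", "fosmid_inventory.tsv",
                                package = "fosmidann"))
}
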