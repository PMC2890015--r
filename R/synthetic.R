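#' Simulation configuration for fosmid-like synthetic data
#'
#' Defaults emulate the study conditions of a 20-clone fosmid survey of a
#' gene-dense plant genome: insert lengths 29-45 kb, about one gene per
#' 5.9 kb (mean 6.6 genes per 39 kb insert), intron counts 0-9 with mean
#' near 2.9 and lengths 84-933 bp, about 8 SSR tracts per insert (one per
#' 4.5 kb) with dinucleotide-dominated motif weights, TE-related sites on
#' roughly 13/20 inserts, multi-contig assemblies for 7/20 inserts (2 or 3
#' contigs in ratio 2:5), a 25% tandem-duplication rate for targeted genes,
#' and EST coverage classes in proportions 15/131 complete, 40/131 partial,
#' 76/131 none.
#'
#' @param seed integer seed; identical (seed, config) gives byte-identical
#'   output.
#' @param n_inserts number of inserts.
#' @param insert_length_range,genes_per_insert,intron_count_range,intron_length_range
#'   see description.
#' @param ssr_per_insert mean planted SSR tracts per insert.
#' @param ssr_motif_weights named weights per canonical motif class.
#' @param repeat_count_range inclusive range of repeat counts.
#' @param p_ssr_pair probability a planted tract gets a close (< 100 bp)
#'   companion tract forming one operational locus.
#' @param te_site_rate probability an insert carries a TE-related gene.
#' @param p_contig_break probability an insert is multi-contig.
#' @param tandem_dup_rate probability the targeted gene is tandemly
#'   duplicated.
#' @param p_est_only probability an insert carries an intergenic
#'   transcribed (EST-only) site.
#' @param est_class_probs named probabilities for complete/partial/none
#'   EST coverage per gene.
#' @param p_merge,p_split,p_miss,p_codon_jitter,spurious_per_insert
#'   prediction-corruption rates (per model; `model_names` lists the
#'   models).
#' @param gap_pad nominal `N` padding between ordered contigs.
#' @param model_names ab initio model labels.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_inserts = 20L,
                       insert_length_range = c(29000L, 45000L),
                       genes_per_insert = 6.6,
                       intron_count_range = c(0L, 9L),
                       intron_length_range = c(84L, 933L),
                       ssr_per_insert = 8,
                       ssr_motif_weights = c(AG = 58, AT = 48, AC = 17,
                                             GAA = 14, AGG = 5, ATT = 4,
                                             GTT = 4, ACT = 4, AGT = 2,
                                             ACC = 2),
                       repeat_count_range = c(5L, 38L),
                       p_ssr_pair = 0.15,
                       te_site_rate = 0.65,
                       p_contig_break = 0.35,
                       tandem_dup_rate = 0.25,
                       p_est_only = 0.1,
                       est_class_probs = c(complete = 15 / 131,
                                           partial = 40 / 131,
                                           none = 76 / 131),
                       p_merge = 0.15, p_split = 0.1, p_miss = 0.05,
                       p_codon_jitter = 0.25, spurious_per_insert = 1.0,
                       gap_pad = 100L,
                       model_names = c("At", "Mt", "Mo", "Nt", "Le", "Vv")) {
  stopifnot(all(c(p_ssr_pair, te_site_rate, p_contig_break, tandem_dup_rate,
                  p_est_only, p_merge, p_split, p_miss,
                  p_codon_jitter) >= 0),
            all(c(p_merge, p_split, p_miss, p_codon_jitter) <= 1),
            insert_length_range[1] <= insert_length_range[2],
            intron_length_range[1] <= intron_length_range[2],
            repeat_count_range[1] >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

.SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.rand_bases <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                 collapse = "")

# concrete repeat-unit variant for a canonical class (dinucleotides fold
# over rotations and reverse complements, longer units over rotations only)
.motif_variant <- function(canon) {
  k <- nchar(canon)
  v <- .rotations(canon)
  if (k <= 2L) v <- c(v, .rotations(revcomp(canon)))
  sample(unique(v), 1L)
}

# Independent SSR finder used for background scrubbing (PCRE backreference
# search, a different mechanism from the run-length scanner under test).
.regex_find_ssrs <- function(sequence, min_unit = 2L, max_unit = 5L,
                             min_repeats = 5L) {
  out <- list()
  for (k in min_unit:max_unit) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_repeats - 1L)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      motif <- substr(sequence, m[i], m[i] + k - 1L)
      if (!is_primitive_motif(motif)) next
      count <- len[i] %/% k
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m[i]), end = as.integer(m[i] + count * k - 1L),
        motif = motif, unit_length = k, repeat_count = count,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit_length = integer(0),
                      repeat_count = integer(0)))
  do.call(rbind, out)
}

# --- one planted gene -------------------------------------------------------

.make_gene <- function(cfg, subject, description, category, strand = NULL) {
  aa_len <- sample(80:300, 1L)
  lam <- 2.87
  ic <- cfg$intron_count_range
  n_intr <- sample(ic[1]:ic[2], 1L,
                   prob = stats::dpois(ic[1]:ic[2], lam) + 1e-9)
  n_intr <- min(n_intr, aa_len - 4L)
  intron_lens <- if (n_intr > 0L)
    sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], n_intr,
           TRUE) else integer(0)
  body <- paste(sample(.SENSE_CODONS, aa_len - 1L, TRUE), collapse = "")
  stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
  cds <- paste0("ATG", body, stopc)               # (aa_len + 1) codons
  # intron insertion points at internal codon boundaries (codon index 2..aa_len-2)
  bnd <- if (n_intr > 0L) sort(sample(2:(aa_len - 2L), n_intr)) else integer(0)
  # exon lengths in bp within the cds (stop codon lives in the last exon)
  cuts <- c(0L, bnd * 3L, (aa_len + 1L) * 3L)
  exon_lens <- diff(cuts)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  list(subject = subject, description = description, category = category,
       strand = strand, aa_len = aa_len, cds = cds,
       exon_lens = exon_lens, intron_lens = intron_lens,
       glen = nchar(cds) + sum(intron_lens))
}

# transcript-frame gene sequence with introns interleaved
.gene_sequence <- function(gene) {
  pieces <- character(0)
  pos <- 0L
  for (i in seq_along(gene$exon_lens)) {
    pieces <- c(pieces, substr(gene$cds, pos + 1L, pos + gene$exon_lens[i]))
    pos <- pos + gene$exon_lens[i]
    if (i < length(gene$exon_lens))
      pieces <- c(pieces, .rand_bases(gene$intron_lens[i]))
  }
  paste(pieces, collapse = "")
}

# --- insert generation ------------------------------------------------------

#' Generate one synthetic fosmid-like insert with ground truth
#'
#' Plants non-overlapping multi-exon genes (>= 500 bp apart; same-subject
#' tandem pairs > 2 kb apart so evidence chaining keeps them distinct), SSR
#' tracts with flank-breaking bases, optional TE-related and EST-only
#' sites, then fills the background with random sequence scrubbed of
#' accidental qualifying SSRs, so the planted tracts are provably the only
#' ones.  Optionally splits the insert into 2-3 ordered contigs at
#' feature-free positions.  Caller is responsible for seeding the RNG (see
#' [simulate_study()]).
#'
#' @param cfg a [sim_config()].
#' @param insert_id identifier.
#' @return list with `record` (a `fosmid_record`) and `truth` (planted
#'   genes, SSR tracts, expected operational loci, EST-only regions).
#' @export
generate_insert <- function(cfg, insert_id = "ins01") {
  L <- sample(cfg$insert_length_range[1]:cfg$insert_length_range[2], 1L)
  # ---- decide feature units
  n_genes <- max(1L, stats::rpois(1L, cfg$genes_per_insert))
  genes <- list()
  g1 <- .make_gene(cfg, paste0(insert_id, "_PROBE"),
                   "targeted probe gene product", "targeted")
  genes[[1]] <- g1
  dup <- stats::runif(1) < cfg$tandem_dup_rate
  if (dup) {
    g1b <- .make_gene(cfg, g1$subject, g1$description, "targeted",
                      strand = g1$strand)   # head-to-tail duplicate
    genes[[2]] <- g1b
  }
  while (length(genes) < n_genes + dup) {
    i <- length(genes) + 1L
    genes[[i]] <- .make_gene(cfg, sprintf("%s_SYN%02d", insert_id, i),
                             sprintf("synthetic conserved protein %02d", i),
                             "known")
  }
  if (stats::runif(1) < cfg$te_site_rate)
    genes[[length(genes) + 1L]] <- .make_gene(
      cfg, paste0(insert_id, "_TE"), "retrotransposon polyprotein, putative",
      "te_related")
  n_ssr <- stats::rpois(1L, cfg$ssr_per_insert)
  ssr_units <- list()
  classes <- names(cfg$ssr_motif_weights)
  for (s in seq_len(n_ssr)) {
    canon <- sample(classes, 1L, prob = cfg$ssr_motif_weights)
    unit <- .motif_variant(canon)
    rc <- cfg$repeat_count_range
    count <- sample(rc[1]:rc[2], 1L, prob = 0.85 ^ (0:(rc[2] - rc[1])))
    tracts <- list(list(unit = unit, count = count))
    if (stats::runif(1) < cfg$p_ssr_pair) {
      canon2 <- sample(classes, 1L, prob = cfg$ssr_motif_weights)
      tracts[[2]] <- list(unit = .motif_variant(canon2),
                          count = sample(rc[1]:min(rc[2], 12L), 1L),
                          gap = sample(10:90, 1L))
    }
    ssr_units[[s]] <- tracts
  }
  est_only <- stats::runif(1) < cfg$p_est_only
  # ---- lay units out left to right in shuffled order
  units <- c(lapply(seq_along(genes), function(i) list(type = "gene", i = i)),
             lapply(seq_along(ssr_units), function(i) list(type = "ssr", i = i)),
             if (est_only) list(list(type = "estonly", i = 1L)))
  units <- units[sample(length(units))]
  # keep the tandem pair adjacent and in order
  if (dup) {
    gi <- vapply(units, function(u) u$type == "gene" && u$i %in% 1:2, TRUE)
    others <- units[!gi]
    at <- sample(length(others) + 1L, 1L)
    units <- append(others, list(list(type = "gene", i = 1L),
                                 list(type = "gene", i = 2L)), after = at - 1L)
  }
  placed <- list()
  pos <- sample(400:900, 1L)
  prev <- NULL
  for (u in units) {
    gap_min <- if (!is.null(prev) && prev$type == "gene" && u$type == "gene")
      600L else 180L
    same_subj <- !is.null(prev) && prev$type == "gene" && u$type == "gene" &&
      genes[[prev$i]]$subject == genes[[u$i]]$subject
    gap <- if (same_subj) sample(2100:2600, 1L)
           else if (gap_min == 600L) sample(600:1600, 1L)
           else sample(180:420, 1L)
    span <- switch(u$type,
      gene = genes[[u$i]]$glen,
      ssr = {
        tr <- ssr_units[[u$i]]
        sum(vapply(tr, function(t)
          nchar(t$unit) * t$count + (t$gap %||% 0L), 1)) },
      estonly = sample(400:900, 1L))
    if (pos + gap + span > L - 400L) next   # unit does not fit; drop it
    u$start <- pos + gap
    u$end <- u$start + span - 1L
    if (u$type == "estonly") u$span <- span
    placed[[length(placed) + 1L]] <- u
    pos <- u$end
    prev <- u
  }
  # ---- write sequence
  chars <- strsplit(.rand_bases(L), "", fixed = TRUE)[[1]]
  truth_genes <- list(); truth_ssrs <- list(); truth_eo <- list()
  exon_mask <- rep(NA_integer_, L)   # index into truth_genes, for scrubbing
  for (u in placed) {
    if (u$type == "gene") {
      g <- genes[[u$i]]
      gseq <- .gene_sequence(g)
      if (g$strand == "-") gseq <- revcomp(gseq)
      substrs <- strsplit(gseq, "", fixed = TRUE)[[1]]
      chars[u$start:u$end] <- substrs
      # exon coordinates in genomic frame
      ex_t <- cumsum(c(0L, head(as.vector(rbind(g$exon_lens,
                c(g$intron_lens, 0L))), -1L)))
      ex_start_t <- ex_t[seq(1L, by = 2L, length.out = length(g$exon_lens))]
      ex <- data.frame(start = u$start + ex_start_t,
                       end = u$start + ex_start_t + g$exon_lens - 1L)
      if (g$strand == "-")
        ex <- data.frame(start = u$start + (u$end - u$start) - (ex$end - u$start),
                         end = u$start + (u$end - u$start) - (ex$start - u$start))
      ex <- ex[order(ex$start), , drop = FALSE]
      gi <- length(truth_genes) + 1L
      for (r in seq_len(nrow(ex))) exon_mask[ex$start[r]:ex$end[r]] <- gi
      truth_genes[[gi]] <- list(
        gene_id = sprintf("%s_g%02d", insert_id, gi),
        start = u$start, end = u$end, strand = g$strand,
        exons = ex, subject = g$subject, description = g$description,
        category = g$category, aa_len = g$aa_len,
        start_codon = if (g$strand == "+") u$start else u$end,
        stop_codon = if (g$strand == "+") u$end - 2L else u$start + 2L)
    } else if (u$type == "ssr") {
      p <- u$start
      for (t in ssr_units[[u$i]]) {
        if (!is.null(t$gap)) p <- p + t$gap
        k <- nchar(t$unit)
        tract <- strrep(t$unit, t$count)
        chars[p:(p + nchar(tract) - 1L)] <- strsplit(tract, "")[[1]]
        # flank breaks: the base before must differ from the periodic
        # continuation (unit's last char), the base after from chars[pos-k+1]
        lastc <- substr(t$unit, k, k)
        chars[p - 1L] <- sample(setdiff(c("A","C","G","T"), lastc), 1L)
        after <- p + nchar(tract)
        chars[after] <- sample(setdiff(c("A","C","G","T"),
                                       chars[after - k]), 1L)
        truth_ssrs[[length(truth_ssrs) + 1L]] <- data.frame(
          insert_id = insert_id, start = p, end = p + nchar(tract) - 1L,
          motif = t$unit, unit_length = k, repeat_count = t$count,
          stringsAsFactors = FALSE)
        p <- p + nchar(tract)
      }
    } else {
      truth_eo[[length(truth_eo) + 1L]] <-
        data.frame(start = u$start, end = u$end, stringsAsFactors = FALSE)
    }
  }
  # ---- scrub accidental SSRs from background/introns/exons
  planted_key <- if (length(truth_ssrs))
    paste(vapply(truth_ssrs, function(t) t$start, 1),
          vapply(truth_ssrs, function(t) t$end, 1)) else character(0)
  planted_cov <- rep(FALSE, L)
  for (t in truth_ssrs) planted_cov[t$start:t$end] <- TRUE
  for (iter in seq_len(200L)) {
    seqs <- paste(chars, collapse = "")
    found <- .regex_find_ssrs(seqs)
    extras <- found[!(paste(found$start, found$end) %in% planted_key), ,
                    drop = FALSE]
    if (nrow(extras) == 0L) break
    if (iter == 200L) stop("generate_insert: SSR scrubbing did not converge")
    for (r in seq_len(nrow(extras))) {
      span <- extras$start[r]:extras$end[r]
      span <- span[!planted_cov[span]]       # never touch planted tracts
      gi <- exon_mask[span]
      in_exon <- !is.na(gi)
      if (any(in_exon)) {
        # resample whole interior codons of the affected exonic stretch
        g <- truth_genes[[gi[in_exon][1]]]
        for (p in span[in_exon]) chars[p] <- NA   # mark
        .resample_codons(g, chars) -> chars
      }
      for (p in span[!in_exon])
        chars[p] <- sample(c("A","C","G","T"), 1L)
    }
  }
  seqs <- paste(chars, collapse = "")
  # ---- contig breaks at feature-free positions
  contigs <- stats::setNames(seqs, paste0(insert_id, "_c1"))
  shift_at <- integer(0)
  if (stats::runif(1) < cfg$p_contig_break) {
    n_contig <- sample(2:3, 1L, prob = c(2, 5))
    feat_cov <- planted_cov
    for (g in truth_genes) feat_cov[max(1, g$start - 200L):
                                    min(L, g$end + 200L)] <- TRUE
    for (e in truth_eo) feat_cov[e$start:e$end] <- TRUE
    free <- which(!feat_cov)
    free <- free[free > 1500L & free < L - 1500L]
    if (length(free) >= n_contig - 1L) {
      shift_at <- sort(sample(free, n_contig - 1L))
      # require breaks well separated
      if (any(diff(c(0L, shift_at, L)) < 1000L)) shift_at <- shift_at[1]
      pieces <- substring(seqs, c(1L, shift_at + 1L), c(shift_at, L))
      contigs <- stats::setNames(pieces,
                   sprintf("%s_c%d", insert_id, seq_along(pieces)))
    }
  }
  record <- assemble_insert(contigs, gap_pad = cfg$gap_pad,
                            insert_id = insert_id)
  shift <- function(p)
    as.integer(p + cfg$gap_pad * findInterval(p - 0.5, shift_at))
  truth_genes <- lapply(truth_genes, function(g) {
    g$start <- shift(g$start); g$end <- shift(g$end)
    g$start_codon <- shift(g$start_codon); g$stop_codon <- shift(g$stop_codon)
    g$exons$start <- shift(g$exons$start); g$exons$end <- shift(g$exons$end)
    g
  })
  truth_ssrs <- lapply(truth_ssrs, function(t) {
    t$start <- shift(t$start); t$end <- shift(t$end); t
  })
  truth_eo <- lapply(truth_eo, function(e) {
    e$start <- shift(e$start); e$end <- shift(e$end); e
  })
  ssr_df <- do.call(rbind, c(truth_ssrs, list(empty_tracts()[
    , c("insert_id", "start", "end", "motif", "unit_length",
        "repeat_count")])))
  # expected operational loci by the distance rule, from planted positions
  exp_loci <- if (nrow(ssr_df)) {
    o <- order(ssr_df$start)
    gaps <- ssr_df$start[o][-1L] - ssr_df$end[o][-nrow(ssr_df)] - 1L
    cumsum(c(TRUE, gaps >= 100L))
  } else integer(0)
  list(record = record,
       truth = list(insert_id = insert_id,
                    genes = truth_genes,
                    ssr_tracts = ssr_df[order(ssr_df$start), , drop = FALSE],
                    expected_locus_group = exp_loci,
                    est_only = truth_eo,
                    gap_positions = record$gap_positions))
}

# rewrite NA-marked exonic positions of gene g with fresh sense codons,
# preserving the ATG, the stop codon, and the reading frame
.resample_codons <- function(g, chars) {
  ex <- g$exons
  tpos <- unlist(lapply(seq_len(nrow(ex)), function(r) ex$start[r]:ex$end[r]))
  if (g$strand == "-") tpos <- rev(tpos)       # transcript order
  n_codon <- length(tpos) %/% 3L
  for (ci in seq_len(n_codon)) {
    idx <- tpos[(3L * ci - 2L):(3L * ci)]
    if (!anyNA(chars[idx])) next
    if (ci == 1L || ci == n_codon) {           # ATG / stop: restore
      orig <- if (ci == 1L) "ATG" else NA
      cd <- if (ci == 1L) "ATG" else sample(c("TAA", "TAG", "TGA"), 1L)
    } else cd <- sample(.SENSE_CODONS, 1L)
    cdc <- strsplit(cd, "")[[1]]
    if (g$strand == "-") cdc <- rev(chartr("ACGT", "TGCA", cdc))
    chars[idx] <- cdc
  }
  chars
}

#' Ground-truth gene sites as a gene-site table
#'
#' Converts planted genes into the same representation
#' [cluster_hits_to_sites()] produces, with codons determined, for
#' truth-vs-pipeline comparisons.
#'
#' @param truth one insert's truth (from [generate_insert()]).
#' @param tiers optional named character vector of per-gene evidence tiers.
#' @return gene-site data.frame.
#' @export
truth_sites <- function(truth, tiers = NULL) {
  gs <- truth$genes
  if (length(gs) == 0L) return(empty_sites())
  rows <- lapply(seq_along(gs), function(i) {
    g <- gs[[i]]
    data.frame(site_id = g$gene_id, insert_id = truth$insert_id,
               start = g$start, end = g$end, strand = g$strand,
               category = g$category, best_subject = g$subject,
               best_description = g$description,
               best_evalue = NA_real_, n_hits = nrow(g$exons),
               frame_anchor3 = NA_integer_,
               tier = if (!is.null(tiers)) tiers[[g$gene_id]] else "strict",
               start_codon = g$start_codon, stop_codon = g$stop_codon,
               truncation = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}
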