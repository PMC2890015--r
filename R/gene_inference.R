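#' Evidence parameters for homology-based gene-site inference
#'
#' @param e_strict conservative E-value cutoff; sites whose best hit passes
#'   it are `strict`-tier.
#' @param e_relaxed permissive cutoff; hits above it are discarded, sites
#'   admitted only between the two cutoffs are `relaxed`-tier.
#' @param max_chain_gap maximum query-coordinate gap (bp) bridged when
#'   chaining same-subject, same-strand hits into one site.  The default
#'   2 kb comfortably spans introns (observed up to 933 bp) without
#'   bridging distinct neighboring genes.
#' @param same_site_overlap two sites from different subjects are merged
#'   when their intervals overlap by at least this fraction of the shorter
#'   (paralogous subjects hitting one physical site must not double-count).
#' @param boundary_margin distance (bp) from an insert end within which a
#'   site edge is called artifactually truncated.
#' @param biological_truncation_ratio predicted/homolog length ratio below
#'   which an interior site is flagged as biologically truncated
#'   (pseudogene-like shortening).
#' @param te_keywords description keywords that classify a site as
#'   TE-related.
#' @return an `evidence_params` list.
#' @export
evidence_params <- function(e_strict = 1e-10, e_relaxed = 1e-5,
                            max_chain_gap = 2000L, same_site_overlap = 0.5,
                            boundary_margin = 50L,
                            biological_truncation_ratio = 0.7,
                            te_keywords = c("reverse transcriptase",
                                            "transposase", "polyprotein",
                                            "retrotransposon", "retroelement",
                                            "transposon", "gag", "pol\\b")) {
  stopifnot(e_strict <= e_relaxed, same_site_overlap > 0,
            same_site_overlap <= 1)
  structure(list(e_strict = e_strict, e_relaxed = e_relaxed,
                 max_chain_gap = as.integer(max_chain_gap),
                 same_site_overlap = same_site_overlap,
                 boundary_margin = as.integer(boundary_margin),
                 biological_truncation_ratio = biological_truncation_ratio,
                 te_keywords = te_keywords),
            class = "evidence_params")
}

empty_sites <- function() {
  data.frame(site_id = character(0), insert_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             category = character(0), best_subject = character(0),
             best_description = character(0), best_evalue = numeric(0),
             n_hits = integer(0), frame_anchor3 = integer(0),
             tier = character(0),
             start_codon = integer(0), stop_codon = integer(0),
             truncation = character(0), stringsAsFactors = FALSE)
}

#' Cluster protein-homology hits into gene sites
#'
#' Hits are filtered at the relaxed cutoff, grouped by subject and strand,
#' and chained along the query when consecutive hits are separated by at
#' most `max_chain_gap` bp (exons of one gene separated by introns).
#' Chains from different subjects that cover the same physical site --
#' interval overlap at least `same_site_overlap` of the shorter chain, same
#' strand -- are merged, so paralogous database subjects do not inflate the
#' site count.  Each site carries its best (lowest-E) hit and a confidence
#' tier: `strict` when the best E-value passes `e_strict`, otherwise
#' `relaxed`.
#'
#' @param hits data.frame from [read_blast_tab()], one insert.
#' @param params an [evidence_params()].
#' @param insert_id recorded in output; defaults to the hits' `query_id`.
#' @return gene-site data.frame (see [empty_sites()] for columns);
#'   `start_codon`/`stop_codon` are `NA` until [infer_start_stop()] runs.
#' @export
cluster_hits_to_sites <- function(hits, params = evidence_params(),
                                  insert_id = NULL) {
  if (nrow(hits) == 0L) return(empty_sites())
  if (is.null(insert_id)) insert_id <- hits$query_id[1]
  hits <- hits[hits$e_value <= params$e_relaxed, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_sites())
  hits <- hits[order(hits$query_start), , drop = FALSE]
  # chain within (subject, strand)
  key <- paste(hits$subject_id, hits$strand)
  chains <- list()
  for (k in unique(key)) {
    h <- hits[key == k, , drop = FALSE]
    gap <- h$query_start[-1L] - h$query_end[-nrow(h)] - 1L
    grp <- cumsum(c(TRUE, gap > params$max_chain_gap))
    for (g in split(seq_len(nrow(h)), grp)) {
      chains[[length(chains) + 1L]] <- h[g, , drop = FALSE]
    }
  }
  # merge chains that occupy the same physical site on the same strand
  repeat {
    merged <- FALSE
    for (i in seq_along(chains)) {
      for (j in seq_along(chains)) {
        if (j <= i) next
        a <- chains[[i]]; b <- chains[[j]]
        if (a$strand[1] != b$strand[1]) next
        sa <- min(a$query_start); ea <- max(a$query_end)
        sb <- min(b$query_start); eb <- max(b$query_end)
        ov <- min(ea, eb) - max(sa, sb) + 1L
        shorter <- min(ea - sa + 1L, eb - sb + 1L)
        if (ov >= params$same_site_overlap * shorter) {
          chains[[i]] <- rbind(a, b)
          chains[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  rows <- lapply(chains, function(ch) {
    best <- ch[order(ch$e_value, -ch$bit_score), ][1L, ]
    # genomic coordinate of the transcript-oriented first base of the
    # 3'-terminal hit: anchors the reading frame for the stop-codon scan
    # (introns shift the frame relative to the 5' end)
    a3 <- if (ch$strand[1] == "+")
      ch$query_start[which.max(ch$query_end)]
    else ch$query_end[which.min(ch$query_start)]
    data.frame(insert_id = insert_id,
               start = min(ch$query_start), end = max(ch$query_end),
               strand = ch$strand[1],
               category = NA_character_,
               best_subject = best$subject_id,
               best_description = best$description,
               best_evalue = best$e_value,
               n_hits = nrow(ch),
               frame_anchor3 = as.integer(a3),
               tier = if (best$e_value <= params$e_strict) "strict" else "relaxed",
               start_codon = NA_integer_, stop_codon = NA_integer_,
               truncation = "", stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  sites <- sites[order(sites$start, sites$end), , drop = FALSE]
  sites$site_id <- sprintf("%s_s%02d", insert_id, seq_len(nrow(sites)))
  rownames(sites) <- NULL
  sites[, names(empty_sites())]
}

#' Categorize a gene site from its best subject description
#'
#' Keyword-driven classification mirroring manual curation practice:
#' `te_related` when the description matches a transposable-element keyword,
#' `unknown` for "unknown protein"/"hypothetical" subjects, `targeted` when
#' the site corresponds to one of the hybridization probes used to select
#' the clone (matched by probe subject id or by >= `min_probe_identity`
#' nucleotide identity when identities are supplied), otherwise `known`.
#'
#' @param sites gene-site data.frame.
#' @param target_probes optional data.frame with columns `probe` and
#'   `subject_id` (and optionally `pct_identity`) naming probe-matching
#'   subjects.
#' @param params an [evidence_params()] (supplies the TE keyword list).
#' @param min_probe_identity percent identity needed for a `targeted` call.
#' @return the sites with `category` filled in.
#' @export
categorize_sites <- function(sites, target_probes = NULL,
                             params = evidence_params(),
                             min_probe_identity = 98) {
  if (nrow(sites) == 0L) return(sites)
  desc <- tolower(ifelse(is.na(sites$best_description), "",
                         sites$best_description))
  te_re <- paste(tolower(params$te_keywords), collapse = "|")
  is_te <- grepl(te_re, desc)
  is_unknown <- grepl("unknown protein|hypothetical", desc)
  is_target <- rep(FALSE, nrow(sites))
  if (!is.null(target_probes) && nrow(target_probes)) {
    ok <- if ("pct_identity" %in% names(target_probes))
      target_probes$pct_identity >= min_probe_identity else TRUE
    is_target <- sites$best_subject %in% target_probes$subject_id[ok]
  }
  sites$category <- ifelse(is_te, "te_related",
                    ifelse(is_target, "targeted",
                    ifelse(is_unknown, "unknown", "known")))
  sites
}

# translate one codon starting at 1-based position p of a plus-oriented string
.codon <- function(seq, p) substr(seq, p, p + 2L)
.STOPS <- c("TAA", "TAG", "TGA")

#' Infer start and stop codon positions for a gene site
#'
#' Works in transcript orientation (the minus strand is handled by
#' reverse-complementing the frame).  The reading frame is anchored at the
#' homology region's 5' end.  The stop codon is the first in-frame
#' TAA/TAG/TGA at or 3' of the homology 3' end; the start codon is the
#' anchor ATG itself when the homology region begins with one, otherwise
#' the farthest in-frame upstream ATG reachable without crossing an
#' in-frame stop (the ATG opening the longest open stretch into the
#' homology region).  When a top-tier EST overlaps the site, the scans are
#' confined to the transcribed extent the EST implies.  Scans that run off
#' the insert, or sites intersecting a contig-gap sentinel, leave the codon
#' undetermined.
#'
#' Positions are reported as the transcript-oriented first base of the
#' codon in insert coordinates (for a minus-strand gene the start codon
#' coordinate is numerically the larger end of its codon).
#'
#' @param site one row of a gene-site data.frame.
#' @param record the [assemble_insert()] record.
#' @param ests optional tidy EST table (only top-tier rows are used).
#' @param params an [evidence_params()].
#' @param top_tier_min identity threshold for an EST to constrain the scan.
#' @return the site row with `start_codon`, `stop_codon`, and `truncation`
#'   updated.
#' @export
infer_start_stop <- function(site, record, ests = NULL,
                             params = evidence_params(), top_tier_min = 95) {
  if (spans_gap(record, site$start, site$end)) {
    site$truncation <- .add_flag(site$truncation, "contig_break")
    return(site)
  }
  L <- frame_length(record)
  minus <- site$strand == "-"
  seqF <- if (minus) revcomp(record$sequence) else record$sequence
  flip <- function(p) if (minus) L - p + 1L else p
  h5 <- if (minus) flip(site$end) else site$start
  h3 <- if (minus) flip(site$start) else site$end
  # EST-implied transcribed extent (transcript orientation)
  lim5 <- 1L; lim3 <- L
  if (!is.null(ests) && nrow(ests)) {
    tt <- ests[!is.na(ests$pct_identity) & ests$pct_identity >= top_tier_min, ,
               drop = FALSE]
    if (nrow(tt)) {
      o5 <- if (minus) flip(tt$seg_end) else tt$seg_start
      o3 <- if (minus) flip(tt$seg_start) else tt$seg_end
      keep <- pmin(o3, h3) >= pmax(o5, h5)  # EST overlaps the homology span
      if (any(keep)) {
        if (min(o5[keep]) < h5) lim5 <- min(o5[keep])
        if (max(o3[keep]) > h3) lim3 <- max(o3[keep])
      }
    }
  }
  # gap sentinels bound the scan: never read across padding
  gaps <- record$gap_positions
  if (nrow(gaps)) {
    gp5 <- if (minus) flip(gaps$pos + pmax(gaps$pad, 1L) - 1L) else gaps$pos
    gp3 <- if (minus) flip(gaps$pos) else gaps$pos + pmax(gaps$pad, 1L) - 1L
    up <- gp3[gp3 < h5]; down <- gp5[gp5 > h3]
    if (length(up)) lim5 <- max(lim5, max(up) + 1L)
    if (length(down)) lim3 <- min(lim3, min(down) - 1L)
  }
  # ---- stop codon: first in-frame stop at/after the homology 3' end.
  # The frame is anchored at the 3'-terminal hit when known (introns shift
  # the frame relative to the 5' anchor), else at the homology 5' end.
  a3 <- if (!is.null(site$frame_anchor3) && !is.na(site$frame_anchor3))
    flip(site$frame_anchor3) else h5
  p <- a3 + 3L * ((h3 - 2L - a3) %/% 3L)      # in-frame codon containing h3
  if (p < a3) p <- a3
  stop_pos <- NA_integer_
  while (p + 2L <= lim3) {
    if (.codon(seqF, p) %in% .STOPS) { stop_pos <- p; break }
    p <- p + 3L
  }
  # ---- start codon
  start_pos <- NA_integer_
  if (.codon(seqF, h5) == "ATG") {
    start_pos <- h5
  } else {
    p <- h5 - 3L
    while (p >= lim5) {
      cd <- .codon(seqF, p)
      if (cd %in% .STOPS) break
      if (cd == "ATG") start_pos <- p   # keep farthest
      p <- p - 3L
    }
  }
  site$start_codon <- if (is.na(start_pos)) NA_integer_ else flip(start_pos)
  site$stop_codon <- if (is.na(stop_pos)) NA_integer_ else flip(stop_pos)
  site
}

.add_flag <- function(flags, flag) {
  cur <- setdiff(strsplit(flags, ";")[[1]], "")
  paste(union(cur, flag), collapse = ";")
}

#' Flag artifactual, contig-break, and biological truncation
#'
#' A site edge within `boundary_margin` of the insert boundary (in
#' transcript orientation) is `artifactual_5p`/`artifactual_3p`; a site
#' intersecting a contig-gap sentinel is `contig_break`; an interior site
#' whose predicted protein is substantially shorter than its homolog
#' (`predicted_len / homolog_len` below the configured ratio) with no
#' artifactual explanation is `biological` (pseudogene-like truncation).
#'
#' @param site one gene-site row.
#' @param record the insert record.
#' @param homolog_len,predicted_len protein lengths in amino acids
#'   (optional; `NA` skips the biological test).
#' @param params an [evidence_params()].
#' @return the site row with `truncation` updated (semicolon-joined flags).
#' @export
flag_truncation <- function(site, record, homolog_len = NA,
                            predicted_len = NA, params = evidence_params()) {
  L <- frame_length(record)
  m <- params$boundary_margin
  near_left <- site$start <= m
  near_right <- (L - site$end) < m
  if (site$strand == "+") {
    if (near_left) site$truncation <- .add_flag(site$truncation, "artifactual_5p")
    if (near_right) site$truncation <- .add_flag(site$truncation, "artifactual_3p")
  } else {
    if (near_right) site$truncation <- .add_flag(site$truncation, "artifactual_5p")
    if (near_left) site$truncation <- .add_flag(site$truncation, "artifactual_3p")
  }
  if (spans_gap(record, site$start, site$end))
    site$truncation <- .add_flag(site$truncation, "contig_break")
  artifactual <- nzchar(site$truncation)
  if (!artifactual && !is.na(homolog_len) && !is.na(predicted_len) &&
      homolog_len > 0 &&
      predicted_len / homolog_len < params$biological_truncation_ratio)
    site$truncation <- .add_flag(site$truncation, "biological")
  site
}

#' Detect tandemly duplicated gene sites
#'
#' Reports pairs of non-overlapping sites on one insert with the same best
#' subject (or, with `subject_match = "same_family"`, the same family label
#' derived by stripping a trailing `-digit` suffix), separated by at most
#' `max_intervening` other sites.  Orientation is classified from the
#' strand pattern in insert order: same strand is `head_to_tail`; minus
#' then plus is `head_to_head` (divergent, 5' ends facing); plus then minus
#' is `tail_to_tail` (convergent).
#'
#' @param sites gene-site data.frame from one insert, sorted by start.
#' @param max_intervening maximum number of sites between the pair.
#' @param subject_match `"same_subject"` or `"same_family"`.
#' @return data.frame with `siteA`, `siteB`, `subject`, `orientation`,
#'   `intervening`.
#' @export
detect_tandem_duplicates <- function(sites, max_intervening = 1L,
                                     subject_match = c("same_subject",
                                                       "same_family")) {
  subject_match <- match.arg(subject_match)
  out <- data.frame(siteA = character(0), siteB = character(0),
                    subject = character(0), orientation = character(0),
                    intervening = integer(0), stringsAsFactors = FALSE)
  if (nrow(sites) < 2L) return(out)
  sites <- sites[order(sites$start), , drop = FALSE]
  lab <- sites$best_subject
  if (subject_match == "same_family") lab <- sub("-\\d+$", "", lab)
  for (i in seq_len(nrow(sites) - 1L)) {
    for (j in (i + 1L):nrow(sites)) {
      if ((j - i - 1L) > max_intervening) break
      if (is.na(lab[i]) || is.na(lab[j]) || lab[i] != lab[j]) next
      if (sites$start[j] <= sites$end[i]) next  # overlapping, not a pair
      ori <- if (sites$strand[i] == sites$strand[j]) "head_to_tail"
             else if (sites$strand[i] == "-") "head_to_head"
             else "tail_to_tail"
      out <- rbind(out, data.frame(
        siteA = sites$site_id[i], siteB = sites$site_id[j],
        subject = lab[i], orientation = ori,
        intervening = j - i - 1L, stringsAsFactors = FALSE))
    }
  }
  out
}
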