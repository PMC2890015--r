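#' EST identity tier parameters
#'
#' Top-tier matches (conspecific transcripts) require at least
#' `top_tier_min` percent identity; second-tier matches (transcripts of
#' related species or of paralogous loci) fall in
#' `[second_tier_min, top_tier_min)`.  The bands partition: 95.00 is top
#' tier, 94.999 is second tier, 84.9 is unclassified.
#'
#' @param top_tier_min,second_tier_min percent-identity thresholds.
#' @return a `tier_params` list.
#' @export
tier_params <- function(top_tier_min = 95, second_tier_min = 85) {
  stopifnot(second_tier_min < top_tier_min)
  structure(list(top_tier_min = top_tier_min,
                 second_tier_min = second_tier_min), class = "tier_params")
}

#' Tier an EST match by percent identity
#' @param pct_identity numeric vector in `[0, 100]`.
#' @param params a [tier_params()].
#' @return character vector: `"top"`, `"second"`, or `"unclassified"`.
#' @examples
#' tier_est(c(95.08, 94, 84.9))  # top, second, unclassified
#' @export
tier_est <- function(pct_identity, params = tier_params()) {
  if (any(pct_identity < 0 | pct_identity > 100, na.rm = TRUE))
    stop("tier_est: identity outside [0, 100]")
  ifelse(pct_identity >= params$top_tier_min, "top",
         ifelse(pct_identity >= params$second_tier_min, "second",
                "unclassified"))
}

# union of intervals as a 2-column matrix, input need not be sorted
.interval_union <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- start[1]; ue <- end[1]
  out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ue + 1L) ue <- max(ue, end[i])
    else { out[[length(out) + 1L]] <- c(us, ue); us <- start[i]; ue <- end[i] }
  }
  out[[length(out) + 1L]] <- c(us, ue)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

#' Classify EST coverage of a coding extent
#'
#' Coverage is assessed at base level against top-tier EST evidence,
#' treating spliced alignments correctly: a base counts as covered when it
#' lies in an aligned segment or within a splice gap internal to a single
#' EST (an intron the transcript necessarily spans; gaps longer than
#' `max_intron` are not credited).  `complete` means every base of
#' `[cds_start, cds_end]` is covered, with multiple ESTs pooling their
#' coverage; `partial` means some aligned segment overlaps the extent;
#' `none` otherwise.  A gap between two different ESTs is never credited,
#' so ESTs touching only the 5' and 3' ends classify as partial.  Adding
#' an EST can never demote the classification.
#'
#' @param cds_start,cds_end coding extent in insert coordinates (falls back
#'   to the homology extent when codons are undetermined).
#' @param ests tidy EST table (one row per segment).
#' @param params a [tier_params()].
#' @param max_intron longest within-EST gap credited as an intron (bp).
#' @return `"complete"`, `"partial"`, or `"none"`.
#' @export
classify_coverage <- function(cds_start, cds_end, ests,
                              params = tier_params(), max_intron = 2000L) {
  span <- c(min(cds_start, cds_end), max(cds_start, cds_end))
  tt <- ests[tier_est(ests$pct_identity, params) == "top", , drop = FALSE]
  if (nrow(tt) == 0L) return("none")
  ov <- pmin(tt$seg_end, span[2]) - pmax(tt$seg_start, span[1]) + 1L
  if (all(ov <= 0L)) return("none")
  cs <- tt$seg_start; ce <- tt$seg_end
  for (id in unique(tt$est_id)) {
    s <- tt[tt$est_id == id, , drop = FALSE]
    s <- s[order(s$seg_start), , drop = FALSE]
    if (nrow(s) < 2L) next
    gs <- s$seg_end[-nrow(s)] + 1L
    ge <- s$seg_start[-1L] - 1L
    keep <- (ge - gs + 1L) <= max_intron
    cs <- c(cs, gs[keep]); ce <- c(ce, ge[keep])
  }
  u <- .interval_union(cs, ce)
  covered <- sum(pmax(pmin(u[, "end"], span[2]) -
                        pmax(u[, "start"], span[1]) + 1L, 0L))
  if (covered >= span[2] - span[1] + 1L) "complete" else "partial"
}

#' Detect gene sites supported only by EST evidence
#'
#' Top-tier ESTs whose segments overlap no homology-inferred site and no
#' ab initio predicted gene mark transcribed sites invisible to protein
#' homology (e.g. fast-evolving or UTR-only loci).  Overlapping qualifying
#' ESTs are pooled into one site; a site whose envelope lies within
#' `boundary_margin` of an insert end is flagged `artifactual` (likely the
#' UTR of a gene continuing off the insert).
#'
#' @param ests tidy EST table.
#' @param sites homology-inferred gene sites.
#' @param tracks list of prediction tracks (may be empty).
#' @param record the insert record (for boundary flags); optional.
#' @param params a [tier_params()].
#' @param boundary_margin bp.
#' @return gene-site data.frame rows with `category = "est_only"`.
#' @export
find_est_only_sites <- function(ests, sites, tracks = list(), record = NULL,
                                params = tier_params(),
                                boundary_margin = 50L) {
  out <- empty_sites()
  tt_ids <- unique(ests$est_id[tier_est(ests$pct_identity, params) == "top"])
  if (length(tt_ids) == 0L) return(out)
  occupied_s <- sites$start; occupied_e <- sites$end
  for (tr in tracks) {
    occupied_s <- c(occupied_s, tr$genes$start)
    occupied_e <- c(occupied_e, tr$genes$end)
  }
  env <- do.call(rbind, lapply(tt_ids, function(id) {
    s <- ests[ests$est_id == id, ]
    data.frame(est_id = id, start = min(s$seg_start), end = max(s$seg_end),
               strand = s$strand[1], stringsAsFactors = FALSE)
  }))
  free <- vapply(seq_len(nrow(env)), function(i) {
    if (length(occupied_s) == 0L) return(TRUE)
    !any(env$start[i] <= occupied_e & env$end[i] >= occupied_s)
  }, TRUE)
  env <- env[free, , drop = FALSE]
  if (nrow(env) == 0L) return(out)
  u <- .interval_union(env$start, env$end)
  insert_id <- if (!is.null(record)) record$insert_id else
    if (nrow(sites)) sites$insert_id[1] else "insert"
  L <- if (!is.null(record)) frame_length(record) else NA_integer_
  rows <- lapply(seq_len(nrow(u)), function(i) {
    members <- env[env$start <= u[i, "end"] & env$end >= u[i, "start"], ]
    boundary <- !is.na(L) &&
      (u[i, "start"] <= boundary_margin || (L - u[i, "end"]) < boundary_margin)
    data.frame(site_id = sprintf("%s_e%02d", insert_id, i),
               insert_id = insert_id,
               start = as.integer(u[i, "start"]), end = as.integer(u[i, "end"]),
               strand = members$strand[1], category = "est_only",
               best_subject = members$est_id[1],
               best_description = NA_character_, best_evalue = NA_real_,
               n_hits = nrow(members), frame_anchor3 = NA_integer_,
               tier = NA_character_,
               start_codon = NA_integer_, stop_codon = NA_integer_,
               truncation = if (boundary) "artifactual_boundary" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a gene model from spliced EST alignments
#'
#' Requires complete top-tier coverage of the coding extent and determined
#' start/stop codons.  Exons are the union of the spliced segments clipped
#' to the coding span; introns are the gaps between consecutive exons.
#' Splice conflicts between ESTs -- one EST's exon segment covering another
#' EST's implied intron within the coding span -- are an error, never
#' silently resolved.
#'
#' @param site a gene-site row with determined `start_codon`/`stop_codon`.
#' @param ests tidy EST table of spliced alignments overlapping the site.
#' @param params a [tier_params()].
#' @return a `gene_model` list: `site_id`, `strand`, `cds_start`,
#'   `cds_end`, `exons` and `introns` (data.frames), `intron_count`,
#'   `intron_lengths`.
#' @export
build_gene_model <- function(site, ests, params = tier_params()) {
  if (is.na(site$start_codon) || is.na(site$stop_codon))
    stop("build_gene_model: undetermined start/stop codon for ", site$site_id)
  cds <- sort(c(site$start_codon, site$stop_codon))
  cds_start <- cds[1]
  cds_end <- cds[2] + if (site$strand == "+") 2L else 0L
  if (site$strand == "-") cds_start <- cds_start - 2L
  tt <- ests[tier_est(ests$pct_identity, params) == "top", , drop = FALSE]
  cov <- classify_coverage(cds_start, cds_end, tt, params)
  if (cov != "complete")
    stop("build_gene_model: coverage is '", cov, "', not complete, for ",
         site$site_id)
  cs <- pmax(tt$seg_start, cds_start)
  ce <- pmin(tt$seg_end, cds_end)
  keep <- cs <= ce
  u <- .interval_union(cs[keep], ce[keep])
  exons <- data.frame(start = as.integer(u[, "start"]),
                      end = as.integer(u[, "end"]))
  introns <- if (nrow(exons) > 1L)
    data.frame(start = exons$end[-nrow(exons)] + 1L,
               end = exons$start[-1L] - 1L)
  else data.frame(start = integer(0), end = integer(0))
  # splice-conflict check: an EST's implied intron (within the coding span)
  # must survive into the union; if another EST's segment covers it, the
  # ESTs disagree about the splice structure
  for (id in unique(tt$est_id)) {
    s <- tt[tt$est_id == id, ]
    s <- s[order(s$seg_start), ]
    if (nrow(s) < 2L) next
    gs <- s$seg_end[-nrow(s)] + 1L
    ge <- s$seg_start[-1L] - 1L
    for (g in seq_along(gs)) {
      if (ge[g] < cds_start || gs[g] > cds_end) next
      in_union <- nrow(introns) > 0L &&
        any(introns$start <= gs[g] & introns$end >= ge[g])
      if (!in_union)
        stop("build_gene_model: conflicting splice boundaries between ESTs at ",
             site$site_id, " (intron ", gs[g], "-", ge[g], " of '", id,
             "' covered by another EST)")
    }
  }
  structure(list(site_id = site$site_id, strand = site$strand,
                 cds_start = cds_start, cds_end = cds_end,
                 exons = exons, introns = introns,
                 intron_count = nrow(introns),
                 intron_lengths = as.integer(introns$end - introns$start + 1L)),
            class = "gene_model")
}

#' Summarize intron statistics over gene models
#'
#' @param models list of `gene_model` objects.
#' @param length_threshold bp; introns strictly shorter are counted as
#'   "short" (conventionally 150 bp).
#' @return list with `n_genes`, `total_introns`, `mean_per_gene`
#'   (2 decimals), `min_per_gene`, `max_per_gene`, `mean_length` (integer
#'   bp; `NA` with no introns), `n_below_threshold`, `n_below_mean`.
#' @export
intron_stats <- function(models, length_threshold = 150L) {
  if (length(models) == 0L) stop("intron_stats: empty model list")
  counts <- vapply(models, function(m) m$intron_count, 1L)
  lens <- unlist(lapply(models, function(m) m$intron_lengths))
  mean_len <- if (length(lens)) as.integer(round(mean(lens))) else NA_integer_
  list(n_genes = length(models),
       total_introns = sum(counts),
       mean_per_gene = round(sum(counts) / length(models), 2),
       min_per_gene = min(counts), max_per_gene = max(counts),
       mean_length = mean_len,
       n_below_threshold = sum(lens < length_threshold),
       n_below_mean = if (length(lens)) sum(lens < mean(lens)) else 0L)
}
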