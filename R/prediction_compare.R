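#' Construct a prediction track
#'
#' One ab initio model's predicted genes for one insert (or one
#' concatenated study frame), with exon structures and predicted
#' translation boundaries.
#'
#' @param model_name model label (e.g. At, Mt, Mo, Nt, Le, Vv).
#' @param genes data.frame with `gene_id`, `start`, `end`, `strand`,
#'   `start_codon`, `stop_codon` and an `exons` list-column of
#'   `start`/`end` data.frames.
#' @return a `prediction_track`.
#' @export
prediction_track <- function(model_name, genes) {
  if (is.null(genes$exons))
    genes$exons <- I(lapply(seq_len(nrow(genes)), function(i)
      data.frame(start = genes$start[i], end = genes$end[i])))
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(model_name = model_name, genes = genes),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  cat(sprintf("<prediction_track> %s: %d predicted gene(s)\n",
              x$model_name, nrow(x$genes)))
  invisible(x)
}

#' Assign predicted genes to evidence-based gene sites
#'
#' Support requires same-strand overlap of at least `min_overlap` bp
#' between a predicted gene's extent and a site's extent.  Each prediction
#' is classified into exactly one of: `unsupported` (no overlapping site),
#' `merger` (spans two or more countable sites; merger takes precedence
#' over split), `split` (shares one site with another prediction), or
#' `simple`.  EST-only sites count as support (transcription evidence) but,
#' like TE-related sites unless `count_te = TRUE`, do not count toward
#' merger tallies.
#'
#' @param track a `prediction_track`.
#' @param sites gene-site data.frame in the same coordinate frame.
#' @param min_overlap minimum overlap in bp (default 1, the most
#'   permissive reading).
#' @param count_te should TE-related sites count in merger tallies?
#' @param frame_len optional; predictions beyond it are an error.
#' @return list with `per_gene` (data.frame: `gene_id`, `class`,
#'   `n_sites`, `n_countable`, `sites` list-column of overlapped site ids)
#'   and `per_site` (data.frame: `site_id`, `n_predictions`).
#' @export
assign_predictions <- function(track, sites, min_overlap = 1L,
                               count_te = FALSE, frame_len = NULL) {
  g <- track$genes
  if (!is.null(frame_len) && nrow(g) && any(g$end > frame_len))
    stop("assign_predictions: prediction beyond insert length (frame mismatch)")
  countable <- !(sites$category %in% c("est_only",
                                       if (!count_te) "te_related"))
  ov_sites <- lapply(seq_len(nrow(g)), function(i) {
    hit <- sites$strand == g$strand[i] &
      pmin(sites$end, g$end[i]) - pmax(sites$start, g$start[i]) + 1L >=
        min_overlap
    which(hit)
  })
  n_pred_per_site <- vapply(seq_len(nrow(sites)), function(s)
    sum(vapply(ov_sites, function(v) s %in% v, TRUE)), 1L)
  classes <- vapply(seq_len(nrow(g)), function(i) {
    v <- ov_sites[[i]]
    if (length(v) == 0L) return("unsupported")
    if (sum(countable[v]) >= 2L) return("merger")
    if (any(n_pred_per_site[v] >= 2L)) return("split")
    "simple"
  }, "")
  per_gene <- data.frame(gene_id = g$gene_id, class = classes,
                         n_sites = lengths(ov_sites),
                         n_countable = vapply(ov_sites, function(v)
                           sum(countable[v]), 1L),
                         stringsAsFactors = FALSE)
  per_gene$sites <- I(lapply(ov_sites, function(v) sites$site_id[v]))
  per_site <- data.frame(site_id = sites$site_id,
                         n_predictions = n_pred_per_site,
                         countable = countable, stringsAsFactors = FALSE)
  list(per_gene = per_gene, per_site = per_site)
}

#' Validate predicted start/stop codons against inferred codons
#'
#' A predicted start (stop) is validated when its coordinate exactly
#' equals (within `tolerance` bp, default 0) the homology-inferred start
#' (stop) codon of a same-strand site its gene overlaps.  Sites with
#' undetermined codons contribute nothing.  Each predicted gene is counted
#' at most once per boundary.
#'
#' @param track a `prediction_track`.
#' @param sites gene-site data.frame with inferred codons.
#' @param tolerance bp; 0 means exact agreement.
#' @return list with `validated_starts` and `validated_stops`.
#' @export
validate_codons <- function(track, sites, tolerance = 0L) {
  g <- track$genes
  vs <- 0L; vp <- 0L
  for (i in seq_len(nrow(g))) {
    hit <- sites$strand == g$strand[i] &
      sites$start <= g$end[i] & sites$end >= g$start[i]
    if (!any(hit)) next
    s <- sites[hit, , drop = FALSE]
    if (!is.na(g$start_codon[i]) &&
        any(!is.na(s$start_codon) &
            abs(s$start_codon - g$start_codon[i]) <= tolerance))
      vs <- vs + 1L
    if (!is.na(g$stop_codon[i]) &&
        any(!is.na(s$stop_codon) &
            abs(s$stop_codon - g$stop_codon[i]) <= tolerance))
      vp <- vp + 1L
  }
  list(validated_starts = vs, validated_stops = vp)
}

#' Reconcile prediction tracks against evidence-based sites
#'
#' One report row per ab initio model: predicted gene count, unsupported
#' predictions, gene mergers and total genes merged, splits, and validated
#' start/stop codons.
#'
#' @param tracks list of `prediction_track` objects.
#' @param sites gene-site data.frame.
#' @param ... passed to [assign_predictions()] and [validate_codons()].
#' @param min_overlap,count_te,tolerance see the underlying operations.
#' @return data.frame with columns `model_name`, `predicted_genes`,
#'   `unsupported`, `mergers`, `genes_merged`, `splits`,
#'   `validated_starts`, `validated_stops`, `validated_total`, in the
#'   order the tracks were given.
#' @export
summarize_models <- function(tracks, sites, min_overlap = 1L,
                             count_te = FALSE, tolerance = 0L) {
  if (length(tracks) == 0L) stop("summarize_models: no tracks")
  rows <- lapply(tracks, function(tr) {
    asg <- assign_predictions(tr, sites, min_overlap = min_overlap,
                              count_te = count_te)
    merger_rows <- asg$per_gene$class == "merger"
    genes_merged <- sum(asg$per_gene$n_countable[merger_rows])
    # a split is a site tiled by >=2 predictions none of which is a merger
    split_sites <- 0L
    for (s in seq_len(nrow(asg$per_site))) {
      if (asg$per_site$n_predictions[s] < 2L) next
      preds <- which(vapply(asg$per_gene$sites, function(v)
        asg$per_site$site_id[s] %in% v, TRUE))
      if (all(asg$per_gene$class[preds] != "merger")) split_sites <- split_sites + 1L
    }
    val <- validate_codons(tr, sites, tolerance = tolerance)
    data.frame(model_name = tr$model_name,
               predicted_genes = nrow(tr$genes),
               unsupported = sum(asg$per_gene$class == "unsupported"),
               mergers = sum(merger_rows),
               genes_merged = genes_merged,
               splits = split_sites,
               validated_starts = val$validated_starts,
               validated_stops = val$validated_stops,
               validated_total = val$validated_starts + val$validated_stops,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
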