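#' Annotate one insert end to end
#'
#' Runs the per-insert stages in order: SSR scan and operational-locus
#' merging, homology-hit clustering and categorization, codon inference
#' and truncation flagging, EST tiering, coverage classification and
#' EST-only site detection, gene-model building where coverage is
#' complete, tandem-duplicate detection, and (when tracks are given)
#' prediction reconciliation.
#'
#' @param record a `fosmid_record`.
#' @param hits homology-hit data.frame (may be empty).
#' @param ests tidy EST table (may be empty).
#' @param tracks named list of `prediction_track` objects (may be empty).
#' @param target_probes optional probe table for [categorize_sites()].
#' @param eparams,sparams,tparams parameter objects.
#' @return list with `record`, `tracts`, `loci`, `sites` (homology +
#'   EST-only), `coverage` (named per-site class), `models` (gene models
#'   for complete-coverage sites), `tandem`, `reconciliation` (or `NULL`).
#' @export
annotate_insert <- function(record, hits = empty_hits(), ests = empty_ests(),
                            tracks = list(), target_probes = NULL,
                            eparams = evidence_params(),
                            sparams = ssr_params(),
                            tparams = tier_params()) {
  tracts <- scan_ssrs(record$sequence, sparams, insert_id = record$insert_id)
  loci <- merge_operational_loci(tracts, sparams$merge_gap)
  sites <- cluster_hits_to_sites(hits, eparams, insert_id = record$insert_id)
  sites <- categorize_sites(sites, target_probes, eparams)
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      sites[i, ] <- infer_start_stop(sites[i, ], record, ests, eparams,
                                     tparams$top_tier_min)
      sites[i, ] <- flag_truncation(sites[i, ], record, params = eparams)
    }
  }
  eo <- find_est_only_sites(ests, sites, tracks, record, tparams,
                            eparams$boundary_margin)
  all_sites <- rbind(sites, eo)
  coverage <- character(0)
  models <- list()
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      cds <- if (!is.na(s$start_codon) && !is.na(s$stop_codon)) {
        r <- sort(c(s$start_codon, s$stop_codon))
        if (s$strand == "+") c(r[1], r[2] + 2L) else c(r[1] - 2L, r[2])
      } else c(s$start, s$end)
      coverage[s$site_id] <- classify_coverage(cds[1], cds[2], ests, tparams)
      if (coverage[s$site_id] == "complete" &&
          !is.na(s$start_codon) && !is.na(s$stop_codon)) {
        ov <- ests[ests$seg_start <= cds[2] & ests$seg_end >= cds[1], ,
                   drop = FALSE]
        models[[s$site_id]] <- tryCatch(build_gene_model(s, ov, tparams),
                                        error = function(e) e)
      }
    }
  }
  recon <- if (length(tracks))
    summarize_models(tracks, all_sites) else NULL
  list(record = record, tracts = tracts, loci = loci, sites = all_sites,
       coverage = coverage,
       models = Filter(function(m) inherits(m, "gene_model"), models),
       model_errors = Filter(function(m) inherits(m, "error"), models),
       tandem = detect_tandem_duplicates(sites),
       reconciliation = recon)
}

#' Run the full study-level pipeline over many inserts
#'
#' Applies [annotate_insert()] per insert (an error in one insert is
#' recorded and the run continues), then assembles the study tables: an
#' insert inventory, a pooled SSR summary, a prediction-reconciliation
#' table summed over inserts, intron statistics over all gene models, and
#' the density summary.  Deterministic given its inputs.
#'
#' @param records list of `fosmid_record`.
#' @param hits,ests,tracks per-insert named lists (defaults: none).
#' @param ctx a [genome_context()]; `total_analyzed_bp` is replaced by the
#'   observed total.
#' @param out_dir optional directory; when given, the tables and
#'   per-insert five-panel summaries are written as TSV/text files.
#' @param ... passed through to [annotate_insert()].
#' @return a `neighborhood_report` list: `per_insert`, `inventory`,
#'   `ssr_summary`, `reconciliation`, `intron_summary`, `density`,
#'   `failures`.
#' @export
run_pipeline <- function(records, hits = NULL, ests = NULL, tracks = NULL,
                         ctx = genome_context(), out_dir = NULL, ...) {
  ids <- vapply(records, function(r) r$insert_id, "")
  names(records) <- ids
  per_insert <- list(); failures <- list()
  for (id in ids) {
    res <- tryCatch(
      annotate_insert(records[[id]],
                      hits = hits[[id]] %||% empty_hits(),
                      ests = ests[[id]] %||% empty_ests(),
                      tracks = tracks[[id]] %||% list(), ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else per_insert[[id]] <- res
  }
  inventory <- data.frame(
    insert_id = names(per_insert),
    accession = vapply(per_insert, function(x) x$record$accession, ""),
    length_bp = vapply(per_insert, function(x) x$record$total_length, 1L),
    n_contigs = vapply(per_insert, function(x) length(x$record$contigs), 1L),
    n_gene_sites = vapply(per_insert, function(x) nrow(x$sites), 1L),
    n_ssr_tracts = vapply(per_insert, function(x) nrow(x$tracts), 1L),
    n_ssr_loci = vapply(per_insert, function(x) nrow(x$loci), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  all_tracts <- do.call(rbind, c(lapply(per_insert, `[[`, "tracts"),
                                 list(empty_tracts())))
  all_loci_n <- sum(inventory$n_ssr_loci)
  all_sites <- do.call(rbind, c(lapply(per_insert, `[[`, "sites"),
                                list(empty_sites())))
  rownames(all_tracts) <- rownames(all_sites) <- NULL
  ctx$total_analyzed_bp <- sum(inventory$length_bp)
  ssr_summary <- summarize_ssrs(all_tracts,
                                data.frame(locus = seq_len(all_loci_n)), ctx)
  recon <- NULL
  recon_list <- Filter(Negate(is.null),
                       lapply(per_insert, `[[`, "reconciliation"))
  if (length(recon_list)) {
    recon <- recon_list[[1]]
    num <- setdiff(names(recon), "model_name")
    for (r in recon_list[-1]) recon[, num] <- recon[, num] + r[, num]
  }
  models <- unlist(lapply(per_insert, `[[`, "models"), recursive = FALSE)
  intron_summary <- if (length(models)) intron_stats(models) else NULL
  density <- build_density_summary(all_sites, ssr_summary,
                                   inventory$length_bp, ctx)
  report <- structure(list(per_insert = per_insert, inventory = inventory,
                           ssr_summary = ssr_summary, reconciliation = recon,
                           intron_summary = intron_summary, density = density,
                           failures = failures),
                      class = "neighborhood_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat(sprintf("<neighborhood_report> %d insert(s), %d gene site(s), %d SSR tract(s) in %d locus/loci\n",
              nrow(x$inventory), sum(x$inventory$n_gene_sites),
              x$ssr_summary$total_tracts, x$ssr_summary$n_loci))
  if (length(x$failures))
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  print(x$density)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the study tables as TSV, a per-insert five-panel text summary
#' (predictions, homology sites, EST support, annotated site table, SSR
#' loci), and a density summary as JSON.  Re-running on identical inputs
#' reproduces identical files.
#'
#' @param report a `neighborhood_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(report$inventory, "inventory.tsv")
  wtsv(report$ssr_summary$classes, "ssr_classes.tsv")
  if (!is.null(report$reconciliation))
    wtsv(report$reconciliation, "reconciliation.tsv")
  sites <- do.call(rbind, lapply(report$per_insert, `[[`, "sites"))
  if (!is.null(sites)) wtsv(sites, "gene_sites.tsv")
  jsonlite::write_json(unclass(report$density), file.path(out_dir, "density.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(report$per_insert)) {
    x <- report$per_insert[[id]]
    con <- file.path(out_dir, paste0(id, "_neighborhood.txt"))
    lines <- c(sprintf("## insert %s (%d bp, %d contigs)", id,
                       x$record$total_length, length(x$record$contigs)),
               "# gene sites (category, tier, codons, truncation):",
               sprintf("  %s %d-%d %s %s/%s start=%s stop=%s %s",
                       x$sites$site_id, x$sites$start, x$sites$end,
                       x$sites$strand, x$sites$category, x$sites$tier,
                       x$sites$start_codon, x$sites$stop_codon,
                       x$sites$truncation),
               "# EST coverage:",
               sprintf("  %s: %s", names(x$coverage), x$coverage),
               "# SSR loci:",
               sprintf("  %s %d-%d (%d tract(s))", x$loci$locus_id,
                       x$loci$start, x$loci$end, x$loci$n_tracts))
    writeLines(lines, con)
  }
  invisible(out_dir)
}

#' Sum per-insert reconciliation reports into a study-level table
#' @param reports list of per-insert report data.frames with identical
#'   model rows.
#' @return one data.frame with summed counts.
#' @export
sum_reconciliation <- function(reports) {
  out <- reports[[1]]
  num <- setdiff(names(out), "model_name")
  for (r in reports[-1]) out[, num] <- out[, num] + r[, num]
  out
}
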