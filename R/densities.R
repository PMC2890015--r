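#' Insert-length totals
#'
#' @param records list of `fosmid_record` objects, or a numeric vector of
#'   insert lengths in bp.
#' @return list with `total_bp` (exact integer sum), `n_inserts`, and
#'   `mean_insert_bp` (rounded to the nearest integer).
#' @examples
#' insert_totals(c(30000, 40000))  # total 70000, mean 35000
#' @export
insert_totals <- function(records) {
  lens <- if (is.numeric(records)) records else
    vapply(records, function(r) as.numeric(r$total_length), 1)
  if (length(lens) == 0L) stop("insert_totals: empty record list")
  list(total_bp = sum(lens), n_inserts = length(lens),
       mean_insert_bp = round(sum(lens) / length(lens)))
}

#' Mean spacing between gene sites, in kb
#'
#' @param n_sites_non_te number of protein-coding gene/pseudogene sites
#'   (TE-related and EST-only sites excluded).
#' @param total_bp total analyzed sequence.
#' @return kb per gene site, rounded to 1 decimal.
#' @examples
#' gene_spacing_kb(120, 708363)  # 5.9
#' @export
gene_spacing_kb <- function(n_sites_non_te, total_bp) {
  if (n_sites_non_te <= 0) stop("gene_spacing_kb: zero sites")
  stopifnot(total_bp > 0)
  round(total_bp / n_sites_non_te / 1000, 1)
}

#' Study-level density summary
#'
#' Pools the headline arithmetic: insert totals, gene spacing (TE-related
#' and EST-only sites excluded from the numerator), SSR densities, and the
#' physical-to-genetic map extrapolation.
#'
#' @param sites combined gene-site data.frame over all inserts.
#' @param ssr_summary result of [summarize_ssrs()].
#' @param records list of `fosmid_record` objects (or lengths).
#' @param ctx a [genome_context()].
#' @return a `density_summary` list: `total_bp`, `n_inserts`,
#'   `mean_insert_bp`, `n_gene_sites_non_te`, `kb_per_gene`, `ssr_per_Mb`,
#'   `kb_per_ssr_locus` (`NA` when no loci), `kb_per_cM`, `loci_per_cM`.
#' @export
build_density_summary <- function(sites, ssr_summary, records,
                                  ctx = genome_context()) {
  tot <- insert_totals(records)
  if (tot$total_bp != ctx$total_analyzed_bp)
    ctx$total_analyzed_bp <- tot$total_bp
  n_gene <- sum(!(sites$category %in% c("te_related", "est_only")))
  n_loci <- ssr_summary$n_loci
  percm <- if (!is.na(n_loci) && n_loci > 0)
    loci_per_cM(n_loci, tot$total_bp, ctx) else
    list(loci_per_cM = NA_real_,
         kb_per_cM = as.integer(round(ctx$genome_size_bp /
                                        ctx$map_length_cM / 1000)))
  structure(list(
    total_bp = tot$total_bp,
    n_inserts = tot$n_inserts,
    mean_insert_bp = tot$mean_insert_bp,
    n_gene_sites_non_te = n_gene,
    kb_per_gene = if (n_gene > 0) gene_spacing_kb(n_gene, tot$total_bp)
                  else NA_real_,
    ssr_per_Mb = ssr_summary$total_per_Mb,
    kb_per_ssr_locus = ssr_summary$kb_per_locus,
    kb_per_cM = percm$kb_per_cM,
    loci_per_cM = percm$loci_per_cM
  ), class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat("<density_summary>\n")
  cat(sprintf("  %d insert(s), %s bp total (mean %s bp)\n", x$n_inserts,
              format(x$total_bp, big.mark = ","),
              format(x$mean_insert_bp, big.mark = ",")))
  cat(sprintf("  %d non-TE gene sites: 1 per %.1f kb\n",
              x$n_gene_sites_non_te, x$kb_per_gene))
  cat(sprintf("  SSR: %d per Mb, 1 locus per %.1f kb\n",
              x$ssr_per_Mb, x$kb_per_ssr_locus))
  cat(sprintf("  map: %d kb/cM, %.1f SSR loci per cM\n",
              x$kb_per_cM, x$loci_per_cM))
  invisible(x)
}
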