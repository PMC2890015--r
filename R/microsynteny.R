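#' Parse an AGI-style locus code
#'
#' Arabidopsis Genome Initiative codes (`At3g54340`) encode chromosome and
#' an ordered five-digit position whose nominal spacing between consecutive
#' loci is 10, so gene order along a chromosome can be recovered from the
#' code alone.
#'
#' @param locus character vector of codes.
#' @return data.frame with `locus`, `chromosome`, `numeric_code`.
#' @examples
#' parse_agi("At3g54340")
#' @export
parse_agi <- function(locus) {
  m <- regmatches(locus, regexec("^At([1-5CM])g(\\d{5})$", locus))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("parse_agi: malformed AGI locus code '", locus[bad][1], "'")
  data.frame(locus = locus,
             chromosome = vapply(m, `[[`, "", 2L),
             numeric_code = as.integer(vapply(m, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Build a reference gene order from locus codes or an explicit table
#'
#' With only codes, ordering within a chromosome follows the numeric code
#' at nominal step 10.  An explicit table (columns `locus`, `chromosome`,
#' `ordinal`) overrides code-derived ordering when supplied.
#'
#' @param loci character vector of AGI-style codes, or a data.frame with an
#'   explicit order.
#' @return data.frame with `locus`, `chromosome`, `numeric_code`,
#'   `ordinal` (rank within chromosome).
#' @export
reference_gene_order <- function(loci) {
  if (is.data.frame(loci) && "ordinal" %in% names(loci)) {
    ord <- loci
    if (!"numeric_code" %in% names(ord))
      ord$numeric_code <- parse_agi(ord$locus)$numeric_code
    return(ord[, c("locus", "chromosome", "numeric_code", "ordinal")])
  }
  tab <- parse_agi(unique(loci))
  tab <- tab[order(tab$chromosome, tab$numeric_code), ]
  tab$ordinal <- stats::ave(tab$numeric_code, tab$chromosome,
                            FUN = seq_along)
  rownames(tab) <- NULL
  tab
}

#' Detect micro-colinearity and conserved microsynteny
#'
#' Walks site pairs in insert order (TE-related and EST-only sites are
#' skipped) and reports every pair, at most `max_intervening` retained
#' sites apart, whose best reference loci share a chromosome with a locus
#' step (numeric code difference / 10) between 1 and `max_step`.  A pair of
#' strictly adjacent sites matching strictly consecutive loci (step 1, no
#' intervening gene) is `colinear`; any other qualifying pair is
#' `conserved_microsynteny` (order locally preserved but interrupted).
#' Pairs in which either site shares its best locus with another site are
#' annotated `family_cluster` (proximal multigene families, e.g. NBS-LRR
#' clusters, are weak evidence of synteny).
#'
#' @param sites gene-site data.frame from one insert, sorted by start,
#'   with a `ref_locus` column of best-match AGI-style codes (`NA`
#'   allowed; such sites still count as intervening genes).
#' @param order a [reference_gene_order()] table; loci absent from it are
#'   an error.
#' @param max_step maximum locus step (default 3, i.e. numeric code
#'   difference up to 30).
#' @param max_intervening maximum number of retained sites between the
#'   pair (default 2).
#' @return data.frame with `siteA`, `siteB`, `locusA`, `locusB`,
#'   `intervening`, `locus_step`, `klass`, `family_cluster`.
#' @export
detect_synteny <- function(sites, order = NULL, max_step = 3L,
                           max_intervening = 2L) {
  out <- data.frame(siteA = character(0), siteB = character(0),
                    locusA = character(0), locusB = character(0),
                    intervening = integer(0), locus_step = integer(0),
                    klass = character(0), family_cluster = logical(0),
                    stringsAsFactors = FALSE)
  keep <- !(sites$category %in% c("te_related", "est_only"))
  s <- sites[keep, , drop = FALSE]
  s <- s[order(s$start), , drop = FALSE]
  if (nrow(s) < 2L) return(out)
  have <- !is.na(s$ref_locus)
  if (is.null(order)) order <- reference_gene_order(s$ref_locus[have])
  missing <- setdiff(s$ref_locus[have], order$locus)
  if (length(missing))
    stop("detect_synteny: locus absent from reference order: ", missing[1])
  idx <- match(s$ref_locus, order$locus)
  shared <- have & duplicated(s$ref_locus) | have &
    duplicated(s$ref_locus, fromLast = TRUE)
  for (i in seq_len(nrow(s) - 1L)) {
    if (!have[i]) next
    for (j in (i + 1L):nrow(s)) {
      if ((j - i - 1L) > max_intervening) break
      if (!have[j]) next
      ca <- order$chromosome[idx[i]]; cb <- order$chromosome[idx[j]]
      if (ca != cb) next
      step <- abs(order$numeric_code[idx[i]] - order$numeric_code[idx[j]]) %/% 10L
      if (step < 1L || step > max_step) next
      interv <- j - i - 1L
      klass <- if (interv == 0L && step == 1L) "colinear"
               else "conserved_microsynteny"
      out <- rbind(out, data.frame(
        siteA = s$site_id[i], siteB = s$site_id[j],
        locusA = s$ref_locus[i], locusB = s$ref_locus[j],
        intervening = interv, locus_step = as.integer(step), klass = klass,
        family_cluster = shared[i] || shared[j],
        stringsAsFactors = FALSE))
    }
  }
  out
}
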