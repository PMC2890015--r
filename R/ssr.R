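#' SSR scan parameters
#'
#' Defaults reproduce an SSRIT-style search: perfect repeats only, unit
#' length 2-5 bp (mononucleotide runs excluded), at least five repeat units,
#' and tracts closer than 100 bp merged into one operational locus
#' (strictly less than; a 100 bp gap does not merge).
#'
#' @param min_unit,max_unit unit-length bounds in bp.
#' @param min_repeats minimum number of uninterrupted repeat units.
#' @param merge_gap exclusive inter-tract distance below which tracts form
#'   one operational locus.
#' @param canonical_mode how motifs are folded into classes; see
#'   [canonical_motif()].  The default `per_unit_length` folds dinucleotides
#'   over rotations and reverse complements (AG = AG/GA/CT/TC) but
#'   trinucleotides over rotations only (so ACT and AGT stay distinct
#'   classes).
#' @return an `ssr_params` list.
#' @export
ssr_params <- function(min_unit = 2L, max_unit = 5L, min_repeats = 5L,
                       merge_gap = 100L,
                       canonical_mode = c("per_unit_length", "rotation",
                                          "rotation_rc")) {
  canonical_mode <- match.arg(canonical_mode)
  stopifnot(min_unit >= 1L, min_unit <= max_unit, max_unit <= 5L,
            min_repeats >= 2L, merge_gap >= 0L)
  structure(list(min_unit = as.integer(min_unit),
                 max_unit = as.integer(max_unit),
                 min_repeats = as.integer(min_repeats),
                 merge_gap = as.integer(merge_gap),
                 canonical_mode = canonical_mode),
            class = "ssr_params")
}

#' Is a repeat motif primitive?
#'
#' A motif is primitive when it is not itself a repetition of a shorter
#' unit (AT is primitive, ATAT is not).  Only primitive motifs are reported
#' by the scanner, so an (AT)10 tract is never double-counted as (ATAT)5.
#'
#' @param motif character string.
#' @return logical.
#' @export
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k <= 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(motif, 1L, d), k %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonicalize a repeat motif into its class representative
#'
#' `rotation` takes the lexicographically smallest cyclic rotation (GAA,
#' AGA, AAG all map to AAG).  `rotation_rc` additionally folds over the
#' reverse complement (CT maps to AG).  `per_unit_length` applies
#' `rotation_rc` to units of length <= 2 and `rotation` to longer units,
#' reproducing the mixed grouping conventional for SSR marker tables.
#'
#' @param motif primitive motif, length 1-5.
#' @param mode one of `rotation`, `rotation_rc`, `per_unit_length`.
#' @return canonical motif string.
#' @examples
#' canonical_motif("CT", "rotation_rc")   # "AG"
#' canonical_motif("GAA", "rotation")     # "AAG"
#' @export
canonical_motif <- function(motif, mode = c("per_unit_length", "rotation",
                                            "rotation_rc")) {
  mode <- match.arg(mode)
  k <- nchar(motif)
  if (k < 1L || k > 5L) stop("canonical_motif: motif length must be 1-5")
  if (!is_primitive_motif(motif))
    stop("canonical_motif: non-primitive motif '", motif, "'")
  if (mode == "per_unit_length") mode <- if (k <= 2L) "rotation_rc" else "rotation"
  cands <- .rotations(motif)
  if (mode == "rotation_rc") cands <- c(cands, .rotations(revcomp(motif)))
  sort(cands)[1L]
}

.rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i)
    paste0(substr(m, i, k), substr(m, 1L, i - 1L)), "")
}

#' Reverse complement of a DNA string (A/C/G/T/N)
#' @param x character string.
#' @return character string.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Scan a sequence for perfect simple sequence repeats
#'
#' Finds every maximal perfect tandem repeat with primitive unit length
#' between `min_unit` and `max_unit` and at least `min_repeats` full units.
#' A tract is anchored at the start of its maximal periodic region and spans
#' whole units only (`end - start + 1 = unit_length * repeat_count`).
#' Tracts never contain `N`: an `N` terminates the periodic region.  An
#' interruption as small as one base splits a repeat into two tracts, so
#' `(TCC)6 TCT (TCC)5` is reported as two tracts 3 bp apart.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @param params an [ssr_params()] object.
#' @param insert_id identifier recorded in the output.
#' @return data.frame with columns `insert_id`, `start`, `end`, `motif`,
#'   `canonical_motif`, `unit_length`, `repeat_count`, sorted by `start`.
#' @export
scan_ssrs <- function(sequence, params = ssr_params(), insert_id = "seq") {
  sequence <- toupper(sequence)
  .check_alphabet(stats::setNames(sequence, insert_id), insert_id)
  n <- nchar(sequence)
  out <- list()
  if (n >= 2L) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    for (k in params$min_unit:params$max_unit) {
      if (n < k * params$min_repeats) next
      a <- chars[seq_len(n - k)]
      b <- chars[seq_len(n - k) + k]
      eq <- a == b & a != "N"
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values & (r$lengths + k) >= k * params$min_repeats)
      for (j in keep) {
        i <- starts[j]
        region_len <- r$lengths[j] + k
        count <- region_len %/% k
        if (count < params$min_repeats) next
        motif <- substr(sequence, i, i + k - 1L)
        if (!is_primitive_motif(motif)) next
        out[[length(out) + 1L]] <- data.frame(
          insert_id = insert_id, start = i, end = i + count * k - 1L,
          motif = motif,
          canonical_motif = canonical_motif(motif, params$canonical_mode),
          unit_length = k, repeat_count = count,
          stringsAsFactors = FALSE)
      }
    }
  }
  tr <- do.call(rbind, c(out, list(empty_tracts())))
  tr <- tr[order(tr$start, tr$unit_length), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

empty_tracts <- function() {
  data.frame(insert_id = character(0), start = integer(0), end = integer(0),
             motif = character(0), canonical_motif = character(0),
             unit_length = integer(0), repeat_count = integer(0),
             stringsAsFactors = FALSE)
}

#' Merge SSR tracts into operational marker loci
#'
#' Single-linkage chaining: consecutive tracts on one insert whose
#' inter-tract distance (`next start - previous end - 1`) is strictly less
#' than `merge_gap` are assigned to the same operational locus, the unit a
#' single primer pair would amplify.  A gap of exactly `merge_gap` keeps
#' the tracts in separate loci.
#'
#' @param tracts data.frame from [scan_ssrs()], all from one insert.
#' @param merge_gap exclusive distance threshold in bp.
#' @return data.frame with one row per locus: `insert_id`, `locus_id`,
#'   `start`, `end` (envelope), `n_tracts`, plus a `members` list-column of
#'   member row indices into `tracts`.
#' @export
merge_operational_loci <- function(tracts, merge_gap = 100L) {
  if (nrow(tracts) == 0L)
    return(data.frame(insert_id = character(0), locus_id = character(0),
                      start = integer(0), end = integer(0),
                      n_tracts = integer(0)))
  if (length(unique(tracts$insert_id)) > 1L)
    stop("merge_operational_loci: tracts from multiple inserts")
  tracts <- tracts[order(tracts$start, tracts$end), , drop = FALSE]
  gap <- tracts$start[-1L] - tracts$end[-nrow(tracts)] - 1L
  new_locus <- c(TRUE, gap >= merge_gap)
  grp <- cumsum(new_locus)
  loci <- do.call(rbind, lapply(split(seq_len(nrow(tracts)), grp), function(idx) {
    data.frame(insert_id = tracts$insert_id[1],
               start = min(tracts$start[idx]), end = max(tracts$end[idx]),
               n_tracts = length(idx), stringsAsFactors = FALSE)
  }))
  loci$locus_id <- sprintf("%s_L%02d", loci$insert_id, seq_len(nrow(loci)))
  loci$members <- I(split(seq_len(nrow(tracts)), grp))
  rownames(loci) <- NULL
  loci[, c("insert_id", "locus_id", "start", "end", "n_tracts", "members")]
}

#' SSR tracts per megabase
#' @param count tract (or class) count.
#' @param total_bp total analyzed sequence, bp.
#' @return integer, `round(count * 1e6 / total_bp)`.
#' @examples
#' ssr_density_per_Mb(158, 708363)  # 223
#' @export
ssr_density_per_Mb <- function(count, total_bp) {
  if (total_bp <= 0) stop("ssr_density_per_Mb: total_bp must be positive")
  as.integer(round(count * 1e6 / total_bp))
}

#' Genome context for map-distance extrapolation
#' @param total_analyzed_bp bp of sequence actually analyzed.
#' @param genome_size_bp genome size in bp (F. vesca: 206 Mb).
#' @param map_length_cM genetic map length in centimorgans (F. vesca: 424).
#' @return a `genome_context` list.
#' @export
genome_context <- function(total_analyzed_bp = 708363,
                           genome_size_bp = 206e6, map_length_cM = 424) {
  stopifnot(total_analyzed_bp > 0, genome_size_bp > 0, map_length_cM > 0)
  structure(list(total_analyzed_bp = total_analyzed_bp,
                 genome_size_bp = genome_size_bp,
                 map_length_cM = map_length_cM), class = "genome_context")
}

#' Extrapolate SSR locus density to loci per centimorgan
#'
#' Combines the observed locus density (loci per bp analyzed) with the
#' genome-wide physical-to-genetic distance ratio
#' `genome_size_bp / map_length_cM`.
#'
#' @param locus_count operational locus count in the analyzed sequence.
#' @param total_bp bp analyzed.
#' @param ctx a [genome_context()].
#' @return list with `loci_per_cM` (real) and `kb_per_cM` (integer,
#'   the physical/genetic ratio rounded to whole kb).
#' @export
loci_per_cM <- function(locus_count, total_bp, ctx = genome_context()) {
  stopifnot(locus_count > 0, total_bp > 0)
  if (ctx$map_length_cM <= 0) stop("loci_per_cM: zero map length")
  bp_per_cM <- ctx$genome_size_bp / ctx$map_length_cM
  list(loci_per_cM = (locus_count / total_bp) * bp_per_cM,
       kb_per_cM = as.integer(round(bp_per_cM / 1000)))
}

#' Summarize SSR content by canonical class
#'
#' Produces a class-by-class summary in the layout conventional for SSR
#' marker surveys: per-class tract counts and per-Mb densities, unit-length
#' subtotals, a grand total, plus operational-locus count and mean spacing.
#'
#' @param tracts combined tract table over all inserts.
#' @param loci combined operational-locus table.
#' @param ctx a [genome_context()]; `total_analyzed_bp` is the denominator.
#' @return list with `classes` (data.frame: `canonical_motif`,
#'   `unit_length`, `n`, `per_Mb`), `subtotals` (per unit length),
#'   `total_tracts`, `total_per_Mb`, `n_loci`, `kb_per_tract`,
#'   `kb_per_locus` (1-decimal kb; `NA` when the count is zero).
#' @export
summarize_ssrs <- function(tracts, loci, ctx = genome_context()) {
  tb <- ctx$total_analyzed_bp
  if (nrow(tracts)) {
    agg <- stats::aggregate(list(n = tracts$start),
                            by = list(canonical_motif = tracts$canonical_motif,
                                      unit_length = tracts$unit_length),
                            FUN = length)
    agg <- agg[order(agg$unit_length, -agg$n, agg$canonical_motif), ]
    agg$per_Mb <- vapply(agg$n, ssr_density_per_Mb, 1L, total_bp = tb)
  } else {
    agg <- data.frame(canonical_motif = character(0), unit_length = integer(0),
                      n = integer(0), per_Mb = integer(0))
  }
  sub <- vapply(2:5, function(k) sum(agg$n[agg$unit_length == k]), 1)
  subtotals <- data.frame(unit_length = 2:5, n = as.integer(sub),
                          per_Mb = vapply(sub, ssr_density_per_Mb, 1L,
                                          total_bp = tb))
  total <- nrow(tracts)
  n_loci <- if (is.null(loci)) NA_integer_ else nrow(loci)
  spacing <- function(n) if (is.na(n) || n == 0L) NA_real_ else
    round(tb / n / 1000, 1)
  list(classes = agg, subtotals = subtotals,
       total_tracts = total,
       total_per_Mb = if (total > 0) ssr_density_per_Mb(total, tb) else 0L,
       n_loci = n_loci,
       kb_per_tract = spacing(total),
       kb_per_locus = spacing(n_loci))
}
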